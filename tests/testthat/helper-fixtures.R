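# Shared, lazily built fixtures. Everything is generated in code at test
# time; heavyweight objects are memoised for the whole run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# elevationally scanned point source at the ring centre (+-15 mm, 1 mm steps)
scan_sinogram <- function() fixture("scan_sinogram", {
  geom <- array_geometry(elevational_positions = seq(-15, 15, by = 1))
  simulate_sinogram(point_sources(0, 0, 0, radius = 0.05), geom,
                    transducer_model(), n_sub = 9)
})

# small template bank (two orientations keep the build affordable; diameter
# refinement needs the full 0.5-2.0 mm grid)
template_bank_small <- function() fixture("template_bank_small", {
  build_template_bank(orientations = c(0, 90))
})

# smooth speckle texture, the elastography test scene
speckle_texture <- function(n, seed = 1) {
  set.seed(seed)
  tex <- matrix(stats::runif(n * n), n, n)
  tex <- EBImage::gblur(tex, 1.5, boundary = "replicate")
  (tex - min(tex)) / diff(range(tex))
}

# compression sequence with a planted stiff inclusion, demons-registered
elasto_case <- function() fixture("elasto_case", {
  n <- 160
  tex <- speckle_texture(n, seed = 1)
  inc <- list(center = c(0, 0), radius = 4.8, factor = 0.5)
  fc <- generate_dynamic_frames(tex, "compression", inclusions = list(inc),
                                frequency = 0.25, amplitude = 0.02,
                                n_frames = 160, noise_sd = 0.01, seed = 3)
  reg <- suppressWarnings(register_nonrigid(fc))
  list(frames = fc, reg = reg, n = n, inclusion = inc)
})

# pulsation scene: one artery among several veins (arteries are a minority
# of the vasculature), SNR 10
artery_case <- function() fixture("artery_case", {
  n <- 96
  base <- matrix(0, n, n)
  base[20:30, 8:88] <- 1          # artery, 1.1 mm wide
  base[45:51, 8:88] <- 0.9        # veins
  base[62:68, 8:88] <- 0.95
  base[80:86, 8:88] <- 0.85
  amask <- matrix(FALSE, n, n); amask[20:30, 8:88] <- TRUE
  fr <- generate_dynamic_frames(base, "pulsation", target_mask = amask,
                                frequency = 1.2, amplitude = 0.2,
                                n_frames = 100, frame_rate = 10,
                                jitter = 0, noise_sd = 0.1, seed = 7)
  list(frames = fr, artery = amask, vessels = base > 0, base = base)
})

expect_warns <- function(expr, pattern) {
  w <- character(0)
  withCallingHandlers(expr, warning = function(x) {
    w <<- c(w, conditionMessage(x))
    invokeRestart("muffleWarning")
  })
  expect_true(any(grepl(pattern, w)),
              info = paste("warnings seen:", paste(w, collapse = " | ")))
}
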