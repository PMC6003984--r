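test_that("vessel tree generation is seeded and plants the diameter law", {
  t1 <- generate_vessel_tree(seed = 1, n_levels = 3)
  t2 <- generate_vessel_tree(seed = 1, n_levels = 3)
  expect_identical(t1, t2)
  # symmetric Murray's law: both daughters at 2^(-1/3) of the parent
  ts <- generate_vessel_tree(seed = 2, n_levels = 1, root_diameter = 1.0,
                             junction_exponent = 3, asymmetry = 1)
  b <- ts$bifurcations
  expect_equal(b$d_daughter_a, 2^(-1 / 3), tolerance = 1e-12)
  expect_equal(b$d_daughter_b, 2^(-1 / 3), tolerance = 1e-12)
  # planted law holds exactly at every bifurcation
  tr <- generate_vessel_tree(seed = 3, n_levels = 4, junction_exponent = 2.63,
                             asymmetry = 0.85)
  with(tr$bifurcations, expect_lt(
    max(abs(d_daughter_a^2.63 + d_daughter_b^2.63 - d_parent^2.63)), 1e-9))
  expect_error(generate_vessel_tree(root_diameter = -1), "root_diameter")
  expect_error(generate_vessel_tree(asymmetry = 0), "asymmetry")
})

test_that("junction exponents measured from generated trees recover the planted value", {
  for (x in c(2.0, 2.63, 3.0)) {
    tr <- generate_vessel_tree(seed = 5, n_levels = 3, junction_exponent = x,
                               asymmetry = 0.9)
    got <- vapply(seq_len(nrow(tr$bifurcations)), function(i) {
      b <- tr$bifurcations[i, ]
      junction_metrics(b$d_parent, b$d_daughter_a, b$d_daughter_b)$x_b
    }, numeric(1))
    expect_lt(max(abs(got - x)), 1e-6)
  }
})

test_that("phantom rasterization reproduces geometry and density", {
  grid <- phantom_grid(nx = 128, ny = 128, dx = 0.1)
  empty <- structure(list(segments = list(), bifurcations = NULL,
                          params = list(seed = 1)), class = "vessel_tree")
  ph0 <- rasterize_phantom(empty, grid)
  expect_true(all(ph0$absorption == 0))
  # a 0.5 mm radius vessel at 0.1 mm pixels is about 10 px across
  seg <- structure(list(segments = list(list(polyline = rbind(c(-5, 0), c(5, 0)),
                                             radius = 0.5, level = 1)),
                        bifurcations = NULL, params = list(seed = 1)),
                   class = "vessel_tree")
  ph <- rasterize_phantom(seg, grid)
  profile <- ph$absorption[64, , 1]
  expect_gte(sum(profile > 0), 9)
  expect_lte(sum(profile > 0), 11)
  # out-of-bounds tree raises unless clipping is requested
  far <- structure(list(segments = list(list(polyline = rbind(c(0, 0), c(50, 0)),
                                             radius = 0.3, level = 1)),
                        bifurcations = NULL, params = list(seed = 1)),
                   class = "vessel_tree")
  expect_error(rasterize_phantom(far, grid), "out of bounds")
  expect_silent(rasterize_phantom(far, grid, clip = TRUE))
})

test_that("planted tumor multiplies the local segment count", {
  bg <- scatter_vessels(seed = 4, density = 0.3, radius = 12)
  grid <- phantom_grid(nx = 280, ny = 280, dx = 0.1)
  tspec <- list(center = c(4, 3), radius = 4.5, multiplier = 3,
                stiffness = 0.5)
  ph <- rasterize_phantom(bg, grid, tumor_spec = tspec, seed = 11)
  mids <- t(vapply(ph$segments, function(s) colMeans(s$polyline), numeric(2)))
  in_disc <- function(ctr, rad)
    sum((mids[, 1] - ctr[1])^2 + (mids[, 2] - ctr[2])^2 <= rad^2)
  n_tum <- in_disc(c(4, 3), 4.5)
  # brute-force counting oracle: average several background discs
  bgd <- mean(vapply(list(c(-6, -5), c(-7, 4), c(5, -6), c(-1, 8)),
                     in_disc, numeric(1), rad = 4.5))
  expect_gte(n_tum / bgd, 2.5)
  expect_lte(n_tum / bgd, 3.5)
  # stiffness grid carries the planted factor inside the disc
  expect_equal(min(ph$stiffness), 0.5)
  expect_true(all(ph$stiffness[ph$labels == 0] == 1))
})

test_that("forward model produces the expected arrivals and waveforms", {
  tm <- transducer_model()
  geom <- array_geometry()
  # no sources -> all-zero sinogram
  s0 <- simulate_sinogram(point_sources(numeric(0), numeric(0)), geom, tm)
  expect_true(all(s0$data == 0))
  # point at the centre arrives at 110 / 1.5 = 73.33 us on every channel
  s1 <- simulate_sinogram(point_sources(0, 0), geom, tm, speed_of_sound = 1.5,
                          n_sub = 1)
  peaks <- apply(abs(s1$data[1, , ]), 1, which.max)
  t_peak <- (peaks - 1) / tm$sampling_rate
  # the band-limited wavelet peaks within a fraction of a cycle of r / c
  expect_lt(max(abs(t_peak - 110 / 1.5)), 0.15)
  expect_equal(length(unique(peaks)), 1)
  # pre-convolution sphere waveform is a bipolar N of duration 2 a / c
  a <- 1.0
  raw <- ringpact:::pa_forward_spheres_cpp(matrix(c(0, 0, 0), 1), 1, a,
                                           element_positions(geom)$xyz[1, , drop = FALSE],
                                           0, 1.5, 40, 4000, 0L, 0, 0)
  nz <- which(raw[1, ] != 0)
  expect_equal(length(nz) / 40, 2 * a / 1.5, tolerance = 0.05)
  expect_gt(raw[1, nz[2]], 0)                 # leading compression
  expect_lt(raw[1, nz[length(nz) - 1]], 0)    # trailing rarefaction
  # invalid speed of sound
  expect_error(simulate_sinogram(point_sources(0, 0), geom, tm,
                                 speed_of_sound = 1.7), "speed_of_sound")
  # source beyond the record window warns about truncation
  expect_warns(simulate_sinogram(point_sources(60, 0), geom, tm, n_sub = 1),
               "truncated")
})

test_that("forward model is linear and ring symmetric", {
  tm <- transducer_model()
  geom <- array_geometry(n_elements = 128, element_pitch = 1.35)
  a <- point_sources(5, 2, 0, radius = 0.05, amplitude = 1)
  b <- point_sources(-3, 4, 0, radius = 0.3, amplitude = 0.7)
  sa <- simulate_sinogram(a, geom, tm, n_sub = 3)$data
  sb <- simulate_sinogram(b, geom, tm, n_sub = 3)$data
  sab <- simulate_sinogram(rbind(a, b), geom, tm, n_sub = 3)$data
  expect_lt(max(abs(sab - (sa + sb))) / max(abs(sab)), 1e-10)
  # rotating the source by one pitch angle permutes channels by one
  phi <- 2 * pi / geom$n_elements
  r <- sqrt(5^2 + 2^2); th <- atan2(2, 5)
  rot <- point_sources(r * cos(th + phi), r * sin(th + phi), 0, radius = 0.05)
  s_rot <- simulate_sinogram(rot, geom, tm, n_sub = 3)$data
  perm <- s_rot[1, c(2:geom$n_elements, 1), ]
  expect_lt(max(abs(perm - sa[1, , ])) / max(abs(sa)), 1e-6)
})

test_that("dynamic frame generator plants the advertised signals", {
  base <- speckle_texture(64, seed = 2)
  mask <- matrix(FALSE, 64, 64); mask[20:30, 10:50] <- TRUE
  # zero amplitude, zero jitter -> identical frames
  f0 <- generate_dynamic_frames(base, "pulsation", target_mask = mask,
                                amplitude = 0, n_frames = 25, jitter = 0,
                                seed = 1)
  expect_equal(max(abs(sweep(f0$frames, c(2, 3), f0$frames[1, , ]))), 0)
  # pulsation at 1.2 Hz peaks at 1.2 Hz in any masked pixel's spectrum
  f1 <- generate_dynamic_frames(base, "pulsation", target_mask = mask,
                                frequency = 1.2, amplitude = 0.2,
                                n_frames = 100, frame_rate = 10, seed = 1)
  px <- f1$frames[, 25, 30]
  sp <- Mod(stats::fft(px - mean(px)))[2:50]
  freq <- (1:49) * 10 / 100
  expect_equal(freq[which.max(sp)], 1.2)
  # seeded determinism
  f2 <- generate_dynamic_frames(base, "pulsation", target_mask = mask,
                                frequency = 1.2, amplitude = 0.2,
                                n_frames = 100, frame_rate = 10, seed = 1)
  expect_identical(f1$frames, f2$frames)
  expect_error(generate_dynamic_frames(base, "pulsation", target_mask = mask,
                                       frequency = 6), "Nyquist")
})

test_that("compression mode scales local area change by the stiffness factor", {
  n <- 128
  base <- matrix(0, n, n)
  # two gaussian blobs: one inside the future inclusion, one outside
  rc <- expand.grid(r = 1:n, c = 1:n)
  blob <- function(cr, cc, s) matrix(exp(-((rc$r - cr)^2 + (rc$c - cc)^2) / (2 * s^2)), n, n)
  base <- blob(64.5, 64.5, 4) + blob(30, 100, 4)
  inc <- list(center = c(0, 0), radius = 2.0, factor = 0.5)
  fr <- generate_dynamic_frames(base, "compression", inclusions = list(inc),
                                frequency = 0.25, amplitude = 0.04,
                                n_frames = 80, frame_rate = 10, noise_sd = 0,
                                seed = 1)
  # integral of a compact blob tracks its local area change
  series <- function(rows, cols)
    apply(fr$frames[, rows, cols], 1, sum)
  amp_at <- function(x) {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_along(x) - 1) / (length(x) - 1))
    sp <- Mod(stats::fft((x / mean(x) - 1) * w))
    bin <- which.min(abs((seq_along(x) - 1) * 10 / length(x) - 0.25))
    sp[bin] / (sum(w) / 2)
  }
  a_in <- amp_at(series(52:77, 52:77))
  a_out <- amp_at(series(18:42, 88:112))
  expect_equal(a_in / a_out, 0.5, tolerance = 0.10)
  expect_equal(a_out, 0.04, tolerance = 0.05)
})
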