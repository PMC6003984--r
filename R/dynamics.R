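#' Dynamics (artery mapping) configuration
#'
#' @param n_subdomains Number of slightly overlapping registration
#'   subdomains; must be a perfect square (default 16, a 4 x 4 grid with 25%
#'   linear overlap).
#' @param overlap Linear overlap fraction between adjacent subdomains.
#' @param smoothing_radius Gaussian spatial smoothing radius (mm) applied to
#'   registered frames before spectral analysis.
#' @param heart_band Heartbeat frequency band (Hz).
#' @param motion_rejection_threshold Frames whose global correlation to the
#'   reference falls below this are removed before registration.
#' @param angle_range,angle_step Rotation search grid (deg) for the rigid
#'   alignment.
#' @param k_artery Artery decision threshold in units of the median band
#'   power over vessel pixels.
#' @return A `dynamics_config`.
#' @export
dynamics_config <- function(n_subdomains = 16, overlap = 0.25,
                            smoothing_radius = 0.2, heart_band = c(1.0, 1.6),
                            motion_rejection_threshold = 0.85,
                            angle_range = 2, angle_step = 1, k_artery = 3) {
  if (round(sqrt(n_subdomains))^2 != n_subdomains)
    stop("n_subdomains must be a perfect square")
  if (heart_band[1] <= 0 || heart_band[2] <= heart_band[1])
    stop("heart_band must be an increasing positive interval")
  structure(list(n_subdomains = n_subdomains, overlap = overlap,
                 smoothing_radius = smoothing_radius, heart_band = heart_band,
                 motion_rejection_threshold = motion_rejection_threshold,
                 angle_range = angle_range, angle_step = angle_step,
                 k_artery = k_artery),
            class = "dynamics_config")
}

# translation by FFT cross-correlation of demeaned, Hann-windowed frames
# (full spectral whitening is brittle on smooth textures with non-circular
# borders), refined to subpixel by a parabolic fit around the peak
phase_correlate <- function(ref, mov) {
  w2 <- outer(hann_window(nrow(ref)), hann_window(ncol(ref)))
  F1 <- stats::fft((ref - mean(ref)) * w2)
  F2 <- stats::fft((mov - mean(mov)) * w2)
  cp <- F1 * Conj(F2)
  r <- Re(stats::fft(cp, inverse = TRUE))
  n <- nrow(r); m <- ncol(r)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  wrap <- function(i, size) ifelse(i - 1 > size / 2, i - 1 - size, i - 1)
  sub <- function(i, size, vals) {
    # parabolic refinement using circular neighbours
    im <- (i - 2) %% size + 1; ip <- i %% size + 1
    y <- c(vals[im], vals[i], vals[ip])
    den <- y[1] - 2 * y[2] + y[3]
    if (is.finite(den) && den < 0) 0.5 * (y[1] - y[3]) / den else 0
  }
  dr <- wrap(pk[1], n) + sub(pk[1], n, r[, pk[2]])
  dc <- wrap(pk[2], m) + sub(pk[2], m, r[pk[1], ])
  c(dr, dc)
}

rotate_image <- function(img, theta_deg) {
  if (theta_deg == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  th <- theta_deg * pi / 180
  rc <- expand.grid(r = seq_len(n), c = seq_len(m))
  cr <- (n + 1) / 2; cc <- (m + 1) / 2
  rr <- cr + cos(th) * (rc$r - cr) - sin(th) * (rc$c - cc)
  ccv <- cc + sin(th) * (rc$r - cr) + cos(th) * (rc$c - cc)
  matrix(bilinear_sample(img, rr, ccv), n, m)
}

shift_image <- function(img, dr, dc) {
  if (dr == 0 && dc == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  rc <- expand.grid(r = seq_len(n), c = seq_len(m))
  matrix(bilinear_sample(img, rc$r - dr, rc$c - dc), n, m)
}

corr_safe <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(as.vector(a), as.vector(b))
}

#' Motion rejection and subdomain rigid registration
#'
#' Frames with strong body motion (global correlation to the reference below
#' the threshold) are removed; the remaining frames are registered to the
#' first retained frame within each of the overlapping subdomains by rigid
#' transformation (translation by phase correlation plus a small rotation
#' search), maximizing the frame-frame correlation. Subdomain results are
#' blended with linear ramp weights.
#'
#' @param frames A `frame_sequence` or a `[frame, row, col]` array.
#' @param config A [dynamics_config()].
#' @return List: `frames` (registered `frame_sequence`), `shifts` (data frame
#'   log per frame and subdomain), `kept` (indices of retained frames).
#' @export
register_subdomains <- function(frames, config = dynamics_config()) {
  fs <- if (inherits(frames, "frame_sequence")) frames else
    structure(list(frames = frames, frame_rate = 10, pixel_size = 0.1,
                   ground_truth = NULL), class = "frame_sequence")
  arr <- fs$frames
  nf <- dim(arr)[1]
  if (nf < 20) stop("need at least 20 frames for registration")
  ref_global <- arr[1, , ]
  # residual correlation after the best global rigid shift: rigid jitter is
  # correctable, so only frames with uncorrectable (non-rigid) motion fail
  gcor <- vapply(seq_len(nf), function(f) {
    d <- phase_correlate(ref_global, arr[f, , ])
    corr_safe(shift_image(arr[f, , ], d[1], d[2]), ref_global)
  }, numeric(1))
  kept <- which(gcor >= config$motion_rejection_threshold)
  if (length(kept) < 10)
    stop("fewer than 10 frames survive motion rejection: insufficient data")
  arr <- arr[kept, , , drop = FALSE]
  nf <- dim(arr)[1]; n <- dim(arr)[2]; m <- dim(arr)[3]
  g <- round(sqrt(config$n_subdomains))
  # subdomain windows with linear overlap
  size_r <- min(n, floor(n / g * (1 + config$overlap)))
  size_c <- min(m, floor(m / g * (1 + config$overlap)))
  starts_r <- round(seq(1, n - size_r + 1, length.out = g))
  starts_c <- round(seq(1, m - size_c + 1, length.out = g))
  ramp <- function(size) {
    w <- pmin(seq_len(size), rev(seq_len(size)))
    w / max(w)
  }
  w2 <- outer(ramp(size_r), ramp(size_c))
  angles <- seq(-config$angle_range, config$angle_range, by = config$angle_step)
  out <- array(0, dim = dim(arr))
  out[1, , ] <- arr[1, , ]
  log <- list()
  for (f in 2:nf) {
    acc <- matrix(0, n, m)
    wacc <- matrix(0, n, m)
    for (si in seq_len(g)) for (sj in seq_len(g)) {
      rr <- starts_r[si] + 0:(size_r - 1)
      cc <- starts_c[sj] + 0:(size_c - 1)
      ref <- arr[1, rr, cc]
      mov <- arr[f, rr, cc]
      best <- list(cor = -Inf)
      for (th in angles) {
        mv <- rotate_image(mov, th)
        d <- phase_correlate(ref, mv)
        al <- shift_image(mv, d[1], d[2])
        cr <- corr_safe(ref, al)
        if (cr > best$cor) best <- list(cor = cr, theta = th, d = d, img = al)
      }
      acc[rr, cc] <- acc[rr, cc] + best$img * w2
      wacc[rr, cc] <- wacc[rr, cc] + w2
      log[[length(log) + 1]] <- data.frame(frame = kept[f], subdomain = (si - 1) * g + sj,
                                           dr = best$d[1], dc = best$d[2],
                                           theta = best$theta, correlation = best$cor)
    }
    out[f, , ] <- ifelse(wacc > 0, acc / pmax(wacc, 1e-12), arr[f, , ])
  }
  reg <- structure(list(frames = out, frame_rate = fs$frame_rate,
                        pixel_size = fs$pixel_size,
                        ground_truth = fs$ground_truth, seed = fs$seed),
                   class = "frame_sequence")
  list(frames = reg, shifts = do.call(rbind, log), kept = kept,
       rejected = setdiff(seq_along(gcor), kept), global_correlation = gcor)
}

#' Heartbeat-band spectral artery map
#'
#' Gaussian-smooths the registered frames, removes each pixel's temporal mean,
#' applies a Hann window and the discrete Fourier transform along time, and
#' integrates the spectral magnitude inside the heartbeat band. Arteries are
#' vessel pixels whose band power exceeds `k_artery` times the median band
#' power over vessel pixels; the heart rate is the frequency of the
#' band-power-weighted global spectral peak.
#'
#' @param frames Registered `frame_sequence` (or raw array).
#' @param config A [dynamics_config()].
#' @param vessel_mask Logical vessel support; defaults to pixels whose mean
#'   intensity exceeds 20% of the maximum mean intensity.
#' @return An `artery_map`: `band_power`, `artery_mask`, `heart_rate` (Hz),
#'   `frequencies`, `vessel_mask`.
#' @export
spectral_artery_map <- function(frames, config = dynamics_config(),
                                vessel_mask = NULL) {
  fs <- if (inherits(frames, "frame_sequence")) frames else
    structure(list(frames = frames, frame_rate = 10, pixel_size = 0.1),
              class = "frame_sequence")
  arr <- fs$frames
  nf <- dim(arr)[1]; n <- dim(arr)[2]; m <- dim(arr)[3]
  duration <- nf / fs$frame_rate
  if (duration < 5)
    warning("record shorter than 5 s: spectral resolution is coarse")
  if (config$heart_band[2] >= fs$frame_rate / 2)
    stop("heart_band exceeds the Nyquist frequency of the frame rate")
  sigma_px <- config$smoothing_radius / fs$pixel_size
  sm <- vapply(seq_len(nf), function(f) gaussian_blur(arr[f, , ], sigma_px),
               matrix(0, n, m))
  X <- matrix(sm, nrow = n * m)  # pixels x frames (vapply binds last dim)
  mean_img <- rowMeans(X)
  X <- X - mean_img
  w <- hann_window(nf)
  Xf <- stats::mvfft(t(X * rep(w, each = n * m)))
  freq <- (seq_len(nf) - 1) * fs$frame_rate / nf
  inband <- freq >= config$heart_band[1] & freq <= config$heart_band[2]
  mag <- Mod(Xf[inband, , drop = FALSE])
  bp <- matrix(colSums(mag), n, m)
  if (is.null(vessel_mask))
    vessel_mask <- matrix(mean_img >= 0.2 * max(mean_img), n, m)
  med <- stats::median(bp[vessel_mask])
  artery <- vessel_mask & bp > config$k_artery * med
  gspec <- rowSums(mag)
  heart_rate <- freq[inband][which.max(gspec)]
  structure(list(band_power = bp, artery_mask = artery,
                 heart_rate = heart_rate, frequencies = freq[inband],
                 band_spectrum = gspec, vessel_mask = vessel_mask,
                 config = config),
            class = "artery_map")
}

#' @export
print.artery_map <- function(x, ...) {
  cat(sprintf("artery map: %d artery pixels of %d vessel pixels, heart rate %.2f Hz\n",
              sum(x$artery_mask), sum(x$vessel_mask), x$heart_rate))
  invisible(x)
}
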