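image_gradient <- function(img) {
  n <- nrow(img); m <- ncol(img)
  gr <- (img[c(2:n, n), ] - img[c(1, 1:(n - 1)), ]) / 2
  gc <- (img[, c(2:m, m)] - img[, c(1, 1:(m - 1))]) / 2
  list(r = gr, c = gc)
}

#' Non-rigid (demons) registration of a frame sequence
#'
#' Registers every frame onto the first frame with an iterative demons
#' scheme: the displacement update at each pixel follows the intensity
#' mismatch along the fixed-image gradient, and the field is regularized by
#' Gaussian smoothing after every iteration. Returns dense per-frame
#' displacement fields mapping reference coordinates into each frame.
#'
#' @param frames A `frame_sequence` or `[frame, row, col]` array (>= 10
#'   frames).
#' @param n_iter Demons iterations per frame.
#' @param sigma Gaussian regularization of the displacement field (px).
#' @param step Update step scale.
#' @param tol Relative residual below which a frame counts as converged.
#' @return List: `displacement` (array `[frame, row, col, 2]`, zero for the
#'   reference), `registered` (frames warped onto the reference),
#'   `residual` (per-frame relative RMS intensity error), `converged`.
#' @export
register_nonrigid <- function(frames, n_iter = 150, sigma = 3, step = 1,
                              tol = 0.5) {
  fs <- if (inherits(frames, "frame_sequence")) frames else
    structure(list(frames = frames, frame_rate = 10, pixel_size = 0.1),
              class = "frame_sequence")
  arr <- fs$frames
  nf <- dim(arr)[1]; n <- dim(arr)[2]; m <- dim(arr)[3]
  if (nf < 10) stop("need at least 10 frames")
  ref <- arr[1, , ]
  gref <- image_gradient(ref)
  g2 <- gref$r^2 + gref$c^2
  rc <- expand.grid(r = seq_len(n), c = seq_len(m))
  disp <- array(0, dim = c(nf, n, m, 2))
  registered <- array(0, dim = dim(arr))
  registered[1, , ] <- ref
  residual <- numeric(nf)
  ref_rms <- sqrt(mean((ref - mean(ref))^2))
  converged <- rep(TRUE, nf)
  for (f in 2:nf) {
    ur <- matrix(0, n, m); uc <- matrix(0, n, m)
    # warm start from the previous frame's field (temporal coherence)
    if (f > 2) { ur <- disp[f - 1, , , 1]; uc <- disp[f - 1, , , 2] }
    mov <- arr[f, , ]
    # fluid-like demons: the update increment is smoothed (box-pair ~
    # Gaussian), not the accumulated field, preserving stiffness contrast at
    # inclusion edges; updates are clamped to 1 px for stability
    w <- max(3, 2 * round(sigma) + 1)
    smooth2 <- function(x) box_mean(box_mean(x, w), w)
    prev_res <- Inf
    for (it in seq_len(n_iter)) {
      warped <- matrix(bilinear_sample(mov, rc$r + ur, rc$c + uc), n, m)
      diff <- warped - ref
      den <- g2 + diff^2
      fac <- ifelse(den > 1e-12, step * diff / den, 0)
      ur <- ur - smooth2(pmin(pmax(fac * gref$r, -1), 1))
      uc <- uc - smooth2(pmin(pmax(fac * gref$c, -1), 1))
      if (it %% 10 == 0) {
        res <- sqrt(mean(diff^2))
        if (res > prev_res * 0.999) break
        prev_res <- res
      }
    }
    ur <- smooth2(ur); uc <- smooth2(uc)
    warped <- matrix(bilinear_sample(mov, rc$r + ur, rc$c + uc), n, m)
    disp[f, , , 1] <- ur
    disp[f, , , 2] <- uc
    registered[f, , ] <- warped
    residual[f] <- sqrt(mean((warped - ref)^2)) / max(ref_rms, 1e-300)
    if (residual[f] > tol) {
      converged[f] <- FALSE
      warning(sprintf("frame %d: demons registration did not converge (relative residual %.2f)",
                      f, residual[f]))
    }
  }
  list(displacement = disp, registered = registered, residual = residual,
       converged = converged, frame_rate = fs$frame_rate,
       pixel_size = fs$pixel_size)
}

#' Stable-pixel selection and triangulation
#'
#' Computes the per-pixel temporal standard deviation of the registered
#' intensities; pixels with relatively small STD are considered stably
#' registered. The field is divided into squares (2 mm x 2 mm by default) and
#' one qualifying pixel is drawn per square (seeded). Triangles are built
#' over the regular grid of selected pixels (two per 2 x 2 block of adjacent
#' squares), their vertices mapped into every original frame through the
#' displacement fields, and signed areas tracked per frame.
#'
#' @param reg Result of [register_nonrigid()].
#' @param square_mm Square size (mm).
#' @param std_cutoff STD cutoff; defaults to the median of the per-pixel STD
#'   distribution. (A low quantile looks natural, but resampling during
#'   registration attenuates sensor noise in proportion to the local
#'   displacement's fractional offset, so a strict cutoff systematically
#'   rejects the least-displaced -- often the stiffest -- tissue.)
#' @param seed Seed for the per-square random pixel choice.
#' @return A `triangle_grid`: selected `points`, `triangles` (index triples),
#'   `areas` (frame x triangle), plus the context needed to redraw pixels
#'   (`std_map`, `qualifiers`, displacement fields).
#' @export
stable_triangulation <- function(reg, square_mm = 2.0, std_cutoff = NULL,
                                 seed = 1) {
  arr <- reg$registered
  nf <- dim(arr)[1]; n <- dim(arr)[2]; m <- dim(arr)[3]
  X <- matrix(arr, nrow = nf)
  std_map <- matrix(apply(X, 2, stats::sd), n, m)
  if (is.null(std_cutoff)) std_cutoff <- stats::quantile(std_map, 0.5)
  w <- max(2, round(square_mm / reg$pixel_size))
  gi <- ceiling(seq_len(n) / w); gj <- ceiling(seq_len(m) / w)
  ni <- max(gi); nj <- max(gj)
  qualifiers <- vector("list", ni * nj)
  for (ii in seq_len(ni)) for (jj in seq_len(nj)) {
    rr <- which(gi == ii); cc <- which(gj == jj)
    sub <- std_map[rr, cc, drop = FALSE]
    ok <- which(sub <= std_cutoff, arr.ind = TRUE)
    if (nrow(ok))
      qualifiers[[(ii - 1) * nj + jj]] <-
        cbind(rr[ok[, 1]], cc[ok[, 2]])
  }
  tg <- structure(list(qualifiers = qualifiers, ni = ni, nj = nj,
                       displacement = reg$displacement,
                       frame_rate = reg$frame_rate,
                       pixel_size = reg$pixel_size, std_map = std_map,
                       std_cutoff = std_cutoff, dims = c(n, m)),
                  class = "triangle_grid")
  draw_triangulation(tg, seed = seed)
}

# draw one random stable pixel per square and rebuild triangles + area series
draw_triangulation <- function(tg, seed = 1) {
  set.seed(seed)
  ni <- tg$ni; nj <- tg$nj
  pts <- matrix(NA_real_, ni * nj, 2)
  for (q in seq_len(ni * nj)) {
    cand <- tg$qualifiers[[q]]
    if (!is.null(cand) && nrow(cand))
      pts[q, ] <- cand[sample.int(nrow(cand), 1), ]
  }
  tri <- list()
  for (ii in seq_len(ni - 1)) for (jj in seq_len(nj - 1)) {
    q11 <- (ii - 1) * nj + jj; q12 <- q11 + 1
    q21 <- ii * nj + jj; q22 <- q21 + 1
    if (any(is.na(pts[c(q11, q12, q21), 1]))) NULL else
      tri[[length(tri) + 1]] <- c(q11, q12, q21)
    if (any(is.na(pts[c(q12, q22, q21), 1]))) NULL else
      tri[[length(tri) + 1]] <- c(q12, q22, q21)
  }
  if (length(tri) < 1 || sum(!is.na(pts[, 1])) < 3)
    stop("fewer than 3 stable pixels selected: cannot triangulate")
  disp <- tg$displacement
  nf <- dim(disp)[1]
  # vertex positions in each original frame = reference position + u_f
  areas <- matrix(0, nf, length(tri))
  vr <- pts[, 1]; vc <- pts[, 2]
  for (f in seq_len(nf)) {
    ur <- disp[f, , , 1]; uc <- disp[f, , , 2]
    fr <- vr + ur[cbind(pmax(1, round(vr)), pmax(1, round(vc)))]
    fc <- vc + uc[cbind(pmax(1, round(vr)), pmax(1, round(vc)))]
    for (t in seq_along(tri)) {
      id <- tri[[t]]
      x <- fr[id]; y <- fc[id]
      areas[f, t] <- 0.5 * ((x[2] - x[1]) * (y[3] - y[1]) -
                              (x[3] - x[1]) * (y[2] - y[1]))
    }
  }
  degenerate <- abs(areas[1, ]) < 1e-9
  tg$points <- pts
  tg$triangles <- tri[!degenerate]
  tg$areas <- areas[, !degenerate, drop = FALSE]
  tg$seed <- seed
  tg
}

#' @export
print.triangle_grid <- function(x, ...) {
  cat(sprintf("triangle grid: %d stable points, %d triangles over %d frames\n",
              sum(!is.na(x$points[, 1])), length(x$triangles), nrow(x$areas)))
  invisible(x)
}

#' Breath/compression deformation map
#'
#' For each triangle of the stable-pixel grid, the relative area series is
#' Fourier transformed (Hann window) and the amplitude at the discrete
#' frequency bin nearest the compression frequency is painted onto the pixels
#' inside the triangle. The procedure is repeated for `n_realizations` random
#' stable-pixel draws and the final map is their mean.
#'
#' @param tg A [stable_triangulation()] result.
#' @param compression_freq Compression (breathing) frequency, Hz. `NULL`
#'   estimates it from the global mean-area spectrum peak in 0.1-0.5 Hz.
#' @param n_realizations Number of random stable-pixel draws averaged.
#' @param seed Seed for the draws.
#' @return A `deformation_map`: `map` (relative area-change amplitude),
#'   `frequency`, `n_realizations`.
#' @export
deformation_map <- function(tg, compression_freq = 0.25, n_realizations = 100,
                            seed = 1) {
  nf <- nrow(tg$areas)
  if (!is.null(compression_freq) && compression_freq >= tg$frame_rate / 2)
    stop("compression frequency must be below the Nyquist frequency")
  freq <- (seq_len(nf) - 1) * tg$frame_rate / nf
  if (is.null(compression_freq)) {
    gl <- rowMeans(tg$areas / rep(tg$areas[1, ], each = nf))
    gw <- (gl - mean(gl)) * hann_window(nf)
    sp <- Mod(stats::fft(gw))
    sel <- freq >= 0.1 & freq <= 0.5
    compression_freq <- freq[sel][which.max(sp[sel])]
  }
  if (nf / tg$frame_rate < 4 / compression_freq)
    warning("record shorter than 4 compression periods; amplitude estimates are coarse")
  bin <- which.min(abs(freq[seq_len(floor(nf / 2))] - compression_freq))
  w <- hann_window(nf)
  gain <- sum(w) / 2
  # out-of-band bins used to estimate (and subtract) each triangle's
  # broadband noise floor, debiasing the magnitude estimate
  offband <- setdiff(2:floor(nf / 2), (bin - 2):(bin + 2))
  n <- tg$dims[1]; m <- tg$dims[2]
  acc <- matrix(0, n, m)
  cnt <- matrix(0, n, m)
  for (rl in seq_len(n_realizations)) {
    g <- if (rl == 1) tg else draw_triangulation(tg, seed = seed + rl - 1)
    rel <- sweep(g$areas, 2, g$areas[1, ], "/") - 1
    spec <- stats::mvfft(rel * w)
    floor_mag <- apply(Mod(spec[offband, , drop = FALSE]), 2, stats::median)
    amp <- pmax(Mod(spec[bin, ]) - floor_mag, 0) / gain
    for (t in seq_along(g$triangles)) {
      v <- g$points[g$triangles[[t]], , drop = FALSE]
      px <- rasterize_triangle(v, n, m)
      if (nrow(px)) {
        acc[px] <- acc[px] + amp[t]
        cnt[px] <- cnt[px] + 1
      }
    }
  }
  map <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  structure(list(map = map, frequency = compression_freq,
                 n_realizations = n_realizations,
                 coverage = cnt / n_realizations),
            class = "deformation_map")
}

#' @export
print.deformation_map <- function(x, ...) {
  cat(sprintf("deformation map: %.3g mean relative area change at %.2f Hz (%d realizations)\n",
              mean(x$map[x$map > 0]), x$frequency, x$n_realizations))
  invisible(x)
}

#' Localize stiff (low-deformation) regions
#'
#' Smooths the deformation map, places a threshold between the stiff floor
#' and the compliant plateau of its amplitude distribution (5th/95th
#' percentiles over covered pixels), and returns the connected
#' low-deformation regions; the largest one marks the stiffest inclusion.
#' When the map shows no meaningful contrast (plateau-floor difference below
#' `min_contrast` of the plateau) no region is reported.
#'
#' @param dmap A [deformation_map()].
#' @param frac Threshold position between floor (0) and plateau (1).
#' @param min_pixels Minimum region size.
#' @param smooth_px Gaussian sigma (px) applied to the map before
#'   thresholding, suppressing triangle-level speckle.
#' @param min_contrast Minimum relative floor-to-plateau contrast.
#' @return List: `mask` (largest stiff region), `labels`, `threshold`.
#' @export
localize_stiff_regions <- function(dmap, frac = 0.4, min_pixels = 25,
                                   smooth_px = 5, min_contrast = 0.2) {
  covered <- dmap$coverage > 0
  # normalized smoothing: do not leak the zero values outside coverage
  sm <- gaussian_blur(dmap$map * covered, smooth_px) /
    pmax(gaussian_blur(covered * 1, smooth_px), 1e-6)
  q <- stats::quantile(sm[covered], c(0.05, 0.95))
  thr <- q[1] + frac * (q[2] - q[1])
  if (q[2] <= 0 || (q[2] - q[1]) / q[2] < min_contrast) {
    empty <- matrix(FALSE, nrow(sm), ncol(sm))
    return(list(mask = empty, labels = empty * 0L, threshold = thr))
  }
  cand <- covered & sm < thr
  lab <- label_components(cand, 8)
  if (max(lab) == 0)
    return(list(mask = cand, labels = lab, threshold = thr))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_pixels)
  if (!length(keep)) keep <- which.max(sizes)
  big <- keep[which.max(sizes[keep])]
  list(mask = lab == big, labels = lab, threshold = thr)
}
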