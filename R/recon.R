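#' Reconstruction configuration
#'
#' @param sos Speed of sound (mm/us).
#' @param nx,ny,nz Output grid size (`nz = 1` for 2D).
#' @param dx In-plane voxel size (mm; system default 0.1).
#' @param dz Elevational voxel size (mm; system default 1).
#' @param center Grid centre (mm), on the ring axis by default.
#' @param half_time Restrict each channel to propagation distances up to the
#'   ring diameter (the minimal early data sufficient for the field of view,
#'   suppressing late-arriving reflections).
#' @param antialias Apply the radius-dependent Nyquist low-pass filter bank.
#' @param n_bins Number of radius bins for the anti-aliasing bank.
#' @param band_edge Upper band edge (MHz) above which channel data carry no
#'   signal; defaults to the transducer's -6 dB upper edge.
#' @param elevational_weight_fwhm FWHM (deg) of the Gaussian
#'   elevational-divergence weight used by the 3D mode.
#' @param elev_cutoff_deg Hard cutoff angle (deg) beyond which 3D
#'   contributions are dropped.
#' @param virtual_transducer Back-project from virtual elements at the
#'   Fresnel-Fraunhofer transition depth `L^2 / (4 lambda)` in front of the
#'   physical elements (3D mode).
#' @return A `recon_config`.
#' @export
recon_config <- function(sos = 1.5, nx = 128, ny = 128, nz = 1, dx = 0.1,
                         dz = 1, center = c(0, 0, 0), half_time = TRUE,
                         antialias = FALSE, n_bins = 16, band_edge = NULL,
                         elevational_weight_fwhm = 9.0, elev_cutoff_deg = 18,
                         virtual_transducer = TRUE) {
  structure(list(sos = sos, nx = nx, ny = ny, nz = nz, dx = dx, dz = dz,
                 center = center, half_time = half_time, antialias = antialias,
                 n_bins = n_bins, band_edge = band_edge,
                 elevational_weight_fwhm = elevational_weight_fwhm,
                 elev_cutoff_deg = elev_cutoff_deg,
                 virtual_transducer = virtual_transducer),
            class = "recon_config")
}

grid_coords <- function(config) {
  list(x = config$center[1] + (seq_len(config$nx) - (config$nx + 1) / 2) * config$dx,
       y = config$center[2] + (seq_len(config$ny) - (config$ny + 1) / 2) * config$dx,
       z = config$center[3] + (seq_len(config$nz) - (config$nz + 1) / 2) * config$dz)
}

# back-projection term b(t) = 2 p(t) - 2 t dp/dt(t); t in us
ubp_term <- function(p_mat, fs) {
  n <- ncol(p_mat)
  t <- (seq_len(n) - 1) / fs
  dp <- (p_mat[, c(2:n, n), drop = FALSE] - p_mat[, c(1, 1:(n - 1)), drop = FALSE]) *
    fs / 2
  2 * p_mat - 2 * sweep(dp, 2, t, `*`)
}

#' Nyquist-limited cutoff frequency at a given radius
#'
#' The full ring samples a source at radius `r` adequately only below
#' `f = N c / (4 pi r)`; inside the radius where this exceeds the transducer
#' band edge the data are left untouched. With the default 512 elements this
#' spatially well-sampled zone is about 37-39 mm in diameter.
#'
#' @param r Radius (mm) from the ring centre (vectorized).
#' @param n_elements Number of ring elements.
#' @param sos Speed of sound (mm/us).
#' @param band_edge Transducer band edge (MHz).
#' @return Cutoff frequencies (MHz), capped at `band_edge`.
#' @export
nyquist_cutoff <- function(r, n_elements = 512, sos = 1.5, band_edge = 3.32) {
  if (any(r < 0)) stop("radius must be non-negative")
  pmin(band_edge, ifelse(r < 1e-9, band_edge,
                         n_elements * sos / (4 * pi * pmax(r, 1e-9))))
}

default_band_edge <- function(transducer)
  transducer$f_center * (1 + transducer$fractional_bandwidth_oneway / 2)

# sharp low-pass with raised-cosine rolloff from fcut to (1 + taper) fcut
lowpass_rows <- function(mat, fcut, fs, taper = 0.15) {
  n <- ncol(mat)
  nfft <- stats::nextn(n, 2)
  f <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * fs / nfft
  af <- abs(f)
  H <- ifelse(af <= fcut, 1,
              ifelse(af >= fcut * (1 + taper), 0,
                     0.5 * (1 + cos(pi * (af - fcut) / (fcut * taper)))))
  X <- stats::mvfft(t(cbind(mat, matrix(0, nrow(mat), nfft - n))))
  Re(t(stats::mvfft(X * H, inverse = TRUE)))[, 1:n, drop = FALSE] / nfft
}

#' Radius-dependent anti-aliasing filter bank
#'
#' Low-pass filters the channel data with cutoffs `f_cut(r) = min(band_edge,
#' N c / (4 pi r))` so that back-projection at radius `r` uses data free of
#' spatial aliasing. Returns one filtered copy per radius bin; the innermost
#' zone (where `f_cut >= band_edge`) keeps the raw data.
#'
#' @param sinogram A `sinogram`.
#' @param r_max Largest pixel radius to be reconstructed (mm).
#' @param n_bins Number of filtered copies.
#' @param band_edge Band edge (MHz); defaults to the transducer's upper edge.
#' @param step Elevational step whose frame is filtered.
#' @return An `aa_bank`: `radius_edges`, `cutoffs` and `data` (list of element
#'   x sample matrices; entry 1 is unfiltered).
#' @export
antialias_lowpass <- function(sinogram, r_max = 50, n_bins = 16,
                              band_edge = NULL, step = 1) {
  if (is.null(band_edge)) band_edge <- default_band_edge(sinogram$transducer)
  geom <- sinogram$geometry
  fs <- sinogram$transducer$sampling_rate
  p <- sinogram$data[step, , ]
  r0 <- geom$n_elements * sinogram$speed_of_sound / (4 * pi * band_edge)
  if (r_max <= r0)
    return(structure(list(radius_edges = c(0, Inf), cutoffs = band_edge,
                          data = list(p)), class = "aa_bank"))
  edges <- c(0, exp(seq(log(r0), log(r_max), length.out = n_bins)))
  edges[length(edges)] <- Inf
  cutoffs <- nyquist_cutoff(pmin(edges[-1], r_max), geom$n_elements,
                            sinogram$speed_of_sound, band_edge)
  data <- vector("list", length(cutoffs))
  data[[1]] <- p
  for (b in 2:length(cutoffs)) data[[b]] <- lowpass_rows(p, cutoffs[b], fs)
  structure(list(radius_edges = edges, cutoffs = cutoffs, data = data),
            class = "aa_bank")
}

new_image_volume <- function(values, config, provenance = list()) {
  g <- grid_coords(config)
  if (any(!is.finite(values))) stop("reconstruction produced non-finite values")
  structure(list(values = values, dx = config$dx, dz = config$dz,
                 x = g$x, y = g$y, z = g$z, provenance = provenance),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("image volume: %s voxels, %.3g mm in-plane\n",
              paste(d, collapse = " x "), x$dx))
  invisible(x)
}

#' 2D half-time universal back-projection
#'
#' For each pixel, sums over elements the filtered back-projection term
#' `b(t) = 2 p(t) - 2 t dp/dt(t)` evaluated at the acoustic delay
#' `|pixel - element| / c`, weighted by the solid angle subtended by the
#' element. Optionally restricts data to half-time propagation distances and
#' applies the radius-dependent anti-aliasing bank.
#'
#' @param sinogram A `sinogram`.
#' @param config A [recon_config()] with `nz = 1`.
#' @param step Which elevational step to reconstruct.
#' @return An `image_volume` with a 2D `values` matrix (nx x ny).
#' @export
reconstruct_2d <- function(sinogram, config = recon_config(), step = 1) {
  if (config$nz != 1) stop("config must describe a single-slice (nz = 1) grid in 2D mode")
  fs <- sinogram$transducer$sampling_rate
  geom <- sinogram$geometry
  ep <- element_positions(geom, z = geom$elevational_positions[step])
  g <- grid_coords(config)
  px <- rep(g$x, times = config$ny)
  py <- rep(g$y, each = config$nx)
  pz <- rep(geom$elevational_positions[step], length(px))
  half_dist <- if (config$half_time) 2 * geom$ring_radius else -1
  acc <- matrix(0, 2, length(px))
  if (config$antialias) {
    r_max <- max(sqrt(px^2 + py^2))
    bank <- antialias_lowpass(sinogram, r_max = r_max, n_bins = config$n_bins,
                              band_edge = config$band_edge, step = step)
    bin <- findInterval(sqrt(px^2 + py^2), bank$radius_edges,
                        rightmost.closed = TRUE)
    for (b in unique(bin)) {
      sel <- bin == b
      B <- ubp_term(bank$data[[b]], fs)
      acc[, sel] <- ubp_backproject_cpp(B, ep$xyz, ep$normal, px[sel], py[sel],
                                        pz[sel], sinogram$speed_of_sound, fs,
                                        half_dist, 0L, 0, 0, 0)
    }
  } else {
    B <- ubp_term(sinogram$data[step, , ], fs)
    acc <- ubp_backproject_cpp(B, ep$xyz, ep$normal, px, py, pz,
                               sinogram$speed_of_sound, fs, half_dist,
                               0L, 0, 0, 0)
  }
  vals <- matrix(acc[1, ] / pmax(acc[2, ], 1e-300), config$nx, config$ny)
  new_image_volume(vals, config, list(mode = "2d", step = step,
                                      half_time = config$half_time,
                                      antialias = config$antialias))
}

#' Reference per-pixel back-projection (naive loops)
#'
#' Direct per-pixel, per-element evaluation of the same universal
#' back-projection sum as [reconstruct_2d()], written as plain loops in R.
#' Used as an independent numerical oracle; no anti-aliasing.
#'
#' @inheritParams reconstruct_2d
#' @return An `image_volume`.
#' @export
reconstruct_2d_reference <- function(sinogram, config = recon_config(), step = 1) {
  fs <- sinogram$transducer$sampling_rate
  geom <- sinogram$geometry
  ep <- element_positions(geom, z = geom$elevational_positions[step])
  B <- ubp_term(sinogram$data[step, , ], fs)
  g <- grid_coords(config)
  half_dist <- if (config$half_time) 2 * geom$ring_radius else Inf
  nsamp <- ncol(B)
  vals <- matrix(0, config$nx, config$ny)
  for (i in seq_len(config$nx)) {
    for (j in seq_len(config$ny)) {
      num <- 0; den <- 0
      for (e in seq_len(geom$n_elements)) {
        dx <- g$x[i] - ep$xyz[e, 1]; dy <- g$y[j] - ep$xyz[e, 2]
        d <- sqrt(dx^2 + dy^2)
        if (d < 1e-9 || d > half_dist) next
        w <- (dx * ep$normal[e, 1] + dy * ep$normal[e, 2]) / d^3
        if (w <= 0) next
        den <- den + w
        s <- d / sinogram$speed_of_sound * fs
        i0 <- floor(s)
        if (i0 < 0 || i0 >= nsamp - 1) next
        f <- s - i0
        num <- num + w * (B[e, i0 + 1] * (1 - f) + B[e, i0 + 2] * f)
      }
      vals[i, j] <- num / max(den, 1e-300)
    }
  }
  new_image_volume(vals, config, list(mode = "2d-reference", step = step))
}

#' 3D universal back-projection with elevational-divergence weighting
#'
#' Back-projects the records of all elevational steps simultaneously into a
#' 3D grid. Each contribution is weighted by a Gaussian profile of the
#' voxel's elevational angle relative to the element (FWHM
#' `elevational_weight_fwhm`, zero beyond `elev_cutoff_deg`). With
#' `virtual_transducer = TRUE` delays and angles are computed from a virtual
#' element at the Fresnel-Fraunhofer transition depth `L^2 / (4 lambda)` in
#' front of the physical element.
#'
#' @inheritParams reconstruct_2d
#' @return An `image_volume` with a 3D `values` array (nx x ny x nz).
#' @export
reconstruct_3d <- function(sinogram, config = recon_config(nz = 31)) {
  geom <- sinogram$geometry
  steps <- geom$elevational_positions
  if (length(steps) < 2)
    stop("3D mode needs >= 2 elevational steps; use reconstruct_2d for single-step data")
  if (config$nz < 2) stop("config grid must be 3D (nz >= 2)")
  fs <- sinogram$transducer$sampling_rate
  g <- grid_coords(config)
  px <- rep(g$x, times = config$ny * config$nz)
  py <- rep(rep(g$y, each = config$nx), times = config$nz)
  pz <- rep(g$z, each = config$nx * config$ny)
  half_dist <- if (config$half_time) 2 * geom$ring_radius else -1
  sigma_rad <- config$elevational_weight_fwhm / (2 * sqrt(2 * log(2))) * pi / 180
  cut_rad <- config$elev_cutoff_deg * pi / 180
  virt_d <- if (config$virtual_transducer)
    geom$element_height^2 / (4 * sinogram$speed_of_sound / sinogram$transducer$f_center)
  else 0
  acc <- matrix(0, 2, length(px))
  for (s in seq_along(steps)) {
    ep <- element_positions(geom, z = steps[s])
    if (config$antialias) {
      r_max <- max(sqrt(px^2 + py^2))
      bank <- antialias_lowpass(sinogram, r_max = r_max, n_bins = config$n_bins,
                                band_edge = config$band_edge, step = s)
      bin <- findInterval(sqrt(px^2 + py^2), bank$radius_edges,
                          rightmost.closed = TRUE)
      for (b in unique(bin)) {
        sel <- bin == b
        B <- ubp_term(bank$data[[b]], fs)
        acc[, sel] <- acc[, sel] +
          ubp_backproject_cpp(B, ep$xyz, ep$normal, px[sel], py[sel], pz[sel],
                              sinogram$speed_of_sound, fs, half_dist, 1L,
                              sigma_rad, cut_rad, virt_d)
      }
    } else {
      B <- ubp_term(sinogram$data[s, , ], fs)
      acc <- acc + ubp_backproject_cpp(B, ep$xyz, ep$normal, px, py, pz,
                                       sinogram$speed_of_sound, fs, half_dist,
                                       1L, sigma_rad, cut_rad, virt_d)
    }
  }
  vals <- array(acc[1, ] / pmax(acc[2, ], 1e-300),
                dim = c(config$nx, config$ny, config$nz))
  new_image_volume(vals, config, list(mode = "3d", virtual = virt_d))
}

#' Full width at half maximum of a 1D profile
#'
#' Width at half of (max - baseline) with linear interpolation between
#' samples; the baseline is the median of the outer 10% of samples.
#'
#' @param profile Numeric vector with a unique interior maximum.
#' @param spacing Sample spacing (defines the returned units).
#' @return FWHM in units of `spacing`.
#' @export
measure_fwhm <- function(profile, spacing = 1) {
  n <- length(profile)
  if (n < 5) stop("profile too short")
  k <- max(1, floor(0.05 * n))
  baseline <- stats::median(c(profile[1:k], profile[(n - k + 1):n]))
  pk <- which.max(profile)
  if (profile[pk] <= baseline + 1e-300 * abs(baseline) ||
      diff(range(profile)) == 0)
    stop("profile is flat: no peak to measure")
  if (pk == 1 || pk == n) stop("peak lies on the profile boundary")
  half <- baseline + (profile[pk] - baseline) / 2
  cross <- function(idx) {
    # first crossing of `half` walking from the peak
    for (i in idx) {
      j <- i + sign(idx[length(idx)] - idx[1])
      if ((profile[i] - half) * (profile[j] - half) <= 0 && profile[i] != profile[j])
        return(i + (half - profile[i]) / (profile[j] - profile[i]) *
                 sign(idx[length(idx)] - idx[1]))
    }
    stop("profile does not fall to half maximum within the sampled range")
  }
  left <- cross(seq(pk, 2))
  right <- cross(seq(pk, n - 1))
  (right - left) * spacing
}

#' Elevational sensitivity profile of the 2D imaging mode
#'
#' Amplitude sensitivity of a single-slice (2D-mode) acquisition to a point
#' source at increasing elevational offsets, measured on an elevationally
#' scanned sinogram of a fixed source. With `method = "divergence"` (default)
#' the per-step peak detected channel amplitude is measured after
#' narrow-band filtering at the centre frequency, isolating the element
#' divergence cone that sets the 2D-mode elevational resolution. With
#' `method = "reconstruction"` each step is reconstructed in 2D and the image
#' peak is taken; this coherent measurement decays faster than the divergence
#' cone because off-plane sources also defocus.
#'
#' @param sinogram A `sinogram` with multiple elevational steps.
#' @param method See above.
#' @param element Element whose record is used for the divergence method.
#' @param fractional_bandwidth Bandwidth of the narrow-band filter.
#' @param config 2D [recon_config()] for the reconstruction method.
#' @return Numeric vector: one sensitivity value per elevational step.
#' @export
elevational_sensitivity_profile <- function(sinogram,
                                            method = c("divergence", "reconstruction"),
                                            element = 1,
                                            fractional_bandwidth = 0.1,
                                            config = recon_config(nx = 41, ny = 41)) {
  method <- match.arg(method)
  steps <- seq_along(sinogram$geometry$elevational_positions)
  if (method == "divergence") {
    tm <- sinogram$transducer
    fs <- tm$sampling_rate
    n <- tm$n_samples
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
    sf <- fractional_bandwidth * tm$f_center / 2 / sqrt(2 * log(2))
    H <- exp(-0.5 * ((abs(f) - tm$f_center) / sf)^2)
    vapply(steps, function(s) {
      x <- sinogram$data[s, element, ]
      max(abs(Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n))
    }, numeric(1))
  } else {
    vapply(steps, function(s) max(reconstruct_2d(sinogram, config, step = s)$values),
           numeric(1))
  }
}
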