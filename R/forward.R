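#' Photoacoustic point/sphere source set
#'
#' @param x,y,z Source centre coordinates (mm), origin on the ring axis.
#' @param radius Source radii (mm). Spheres at or below 0.1 mm are treated as
#'   band-limited point sources (their detected waveform is the derivative of
#'   the element impulse response scaled by the small-sphere moment).
#' @param amplitude Initial pressure amplitudes (arbitrary linear units).
#' @return A `pa_sources` data frame.
#' @export
point_sources <- function(x, y, z = 0, radius = 0.05, amplitude = 1) {
  if (length(x) == 0) {
    d <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    radius = numeric(0), amplitude = numeric(0))
    class(d) <- c("pa_sources", class(d))
    return(d)
  }
  d <- data.frame(x = x, y = y, z = z, radius = radius, amplitude = amplitude)
  if (any(d$radius <= 0)) stop("source radius must be positive")
  class(d) <- c("pa_sources", class(d))
  d
}

#' Convert a phantom's absorbing voxels to point sources
#'
#' @param phantom A [rasterize_phantom()] result.
#' @param threshold Voxels with absorption above this become sources.
#' @return A `pa_sources` data frame (one sub-resolution sphere per voxel).
#' @export
phantom_to_sources <- function(phantom, threshold = 0) {
  idx <- which(phantom$absorption > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(point_sources(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0)))
  g <- phantom$grid
  point_sources(x = g$x[idx[, 1]], y = g$y[idx[, 2]], z = g$z[idx[, 3]],
                radius = g$dx / 2,
                amplitude = phantom$absorption[idx])
}

directivity_params <- function(model, geometry, transducer, sos, n_sub) {
  L <- geometry$element_height
  switch(model,
    aperture = list(code = 0L, sinc_c = 0, sigma_rad = 0,
                    subz = ((seq_len(n_sub) - (n_sub + 1) / 2) / n_sub) * L),
    sinc = list(code = 1L,
                sinc_c = pi * L * transducer$f_center / sos,
                sigma_rad = 0, subz = 0),
    gaussian = list(code = 2L, sinc_c = 0,
                    sigma_rad = transducer$divergence_fwhm / (2 * sqrt(2 * log(2))) * pi / 180,
                    subz = 0))
}

#' Simulate a ring-array photoacoustic sinogram
#'
#' Each channel is the superposition over sources of the spherical-wave
#' photoacoustic solution (a bipolar N-shaped wave of duration `2 a / c` for a
#' uniform sphere of radius `a`), delayed by distance/speed, detected through
#' the band-limited element impulse response, and shaped by the element's
#' elevational aperture. With `directivity = "aperture"` (default) the 5-mm
#' element height is integrated over `n_sub` sub-apertures, which reproduces
#' both the far-field divergence pattern and the near-field time smearing;
#' `"sinc"` and `"gaussian"` are faster amplitude-only point-element models.
#'
#' @param sources A [point_sources()] set or a phantom (voxelized via
#'   [phantom_to_sources()]).
#' @param geometry An [array_geometry()]; one sinogram frame is produced per
#'   elevational position.
#' @param transducer A [transducer_model()].
#' @param speed_of_sound Speed of sound in mm/us, must lie in (1.4, 1.6).
#' @param noise_sd Additive white Gaussian noise standard deviation per sample.
#' @param seed Integer seed for the noise stream.
#' @param directivity Elevational element model (see above).
#' @param n_sub Number of sub-apertures for the `"aperture"` model.
#' @return A `sinogram` object: `data[step, element, sample]` plus metadata.
#' @export
simulate_sinogram <- function(sources, geometry = array_geometry(),
                              transducer = transducer_model(),
                              speed_of_sound = 1.5, noise_sd = 0, seed = NULL,
                              directivity = c("aperture", "sinc", "gaussian"),
                              n_sub = 7) {
  if (inherits(sources, "pact_phantom")) sources <- phantom_to_sources(sources)
  directivity <- match.arg(directivity)
  if (speed_of_sound <= 1.4 || speed_of_sound >= 1.6)
    stop("speed_of_sound must lie in (1.4, 1.6) mm/us")
  fs <- transducer$sampling_rate
  nsamp <- transducer$n_samples
  steps <- geometry$elevational_positions
  data <- array(0, dim = c(length(steps), geometry$n_elements, nsamp))
  dp <- directivity_params(directivity, geometry, transducer, speed_of_sound, n_sub)
  if (nrow(sources) > 0) {
    small <- sources$radius <= 0.1
    src <- as.matrix(sources[, c("x", "y", "z")])
    kern <- impulse_response(transducer)
    for (s in seq_along(steps)) {
      ep <- element_positions(geometry, z = steps[s])
      acc <- matrix(0, geometry$n_elements, nsamp)
      if (any(!small)) {
        raw <- pa_forward_spheres_cpp(src[!small, , drop = FALSE],
                                      sources$amplitude[!small],
                                      sources$radius[!small], ep$xyz, dp$subz,
                                      speed_of_sound, fs, nsamp, dp$code,
                                      dp$sinc_c, dp$sigma_rad)
        acc <- acc + convolve_rows(raw, kern)
      }
      if (any(small)) {
        acc <- acc + pa_forward_points_cpp(src[small, , drop = FALSE],
                                           sources$amplitude[small],
                                           sources$radius[small], ep$xyz,
                                           dp$subz, speed_of_sound, fs, nsamp,
                                           transducer$sigma_t,
                                           2 * pi * transducer$f_center,
                                           dp$code, dp$sinc_c, dp$sigma_rad)
      }
      data[s, , ] <- acc
      # farthest possible arrival for this step
      dmax <- max(sqrt((sqrt(src[, 1]^2 + src[, 2]^2) + geometry$ring_radius)^2 +
                         (src[, 3] - steps[s])^2) + sources$radius)
      if (dmax / speed_of_sound > transducer$record_length)
        warning("some source arrivals fall beyond the record window and are truncated")
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    data <- data + array(stats::rnorm(length(data), sd = noise_sd), dim = dim(data))
  }
  structure(list(data = data, geometry = geometry, transducer = transducer,
                 speed_of_sound = speed_of_sound, noise_seed = seed,
                 directivity_model = directivity, n_sub = n_sub),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("sinogram: %d elevational step(s) x %d elements x %d samples (fs %g MHz, c %.2f mm/us, %s element model)\n",
              d[1], d[2], d[3], x$transducer$sampling_rate, x$speed_of_sound,
              x$directivity_model))
  invisible(x)
}

#' Generate a dynamic 2D frame sequence
#'
#' Emulates the two dynamic acquisition modes of a 10-Hz single-slice scan:
#' `"pulsation"` makes the pixels of `target_mask` (arteries) oscillate
#' sinusoidally with fractional `amplitude` at `frequency`; `"compression"`
#' dilates the whole frame coronally at `frequency` (peak relative area change
#' = `amplitude`), with the dilation inside each stiff inclusion scaled by its
#' stiffness factor. Divergence-consistent displacement fields are used so
#' that the local relative-area-change amplitude equals `amplitude` times the
#' local stiffness factor.
#'
#' @param base_image 2D numeric matrix (a reconstructed slice or phantom).
#' @param mode `"pulsation"` or `"compression"`.
#' @param target_mask Logical matrix of pulsating pixels (pulsation mode).
#' @param inclusions For compression mode: list of `list(center = c(x, y) mm,
#'   radius = mm, factor = relative compliance <= 1)` stiff inclusions.
#' @param frequency Oscillation frequency (Hz), below Nyquist.
#' @param amplitude Fractional amplitude (pulsation) or peak relative area
#'   change (compression).
#' @param n_frames,frame_rate Number of frames and frame rate (Hz).
#' @param pixel_size Pixel size (mm).
#' @param jitter SD of per-frame rigid shifts (px).
#' @param noise_sd Additive white Gaussian noise SD per pixel.
#' @param seed Integer seed.
#' @return A `frame_sequence`: `frames[frame, row, col]`, metadata and ground
#'   truth (planted mask or stiffness map and frequency).
#' @export
generate_dynamic_frames <- function(base_image, mode = c("pulsation", "compression"),
                                    target_mask = NULL, inclusions = list(),
                                    frequency = 1.2, amplitude = 0.2,
                                    n_frames = 100, frame_rate = 10,
                                    pixel_size = 0.1, jitter = 0,
                                    noise_sd = 0, seed = 1) {
  mode <- match.arg(mode)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (frequency >= frame_rate / 2)
    stop("frequency must be below the Nyquist frequency frame_rate / 2")
  set.seed(seed)
  n <- nrow(base_image); m <- ncol(base_image)
  frames <- array(0, dim = c(n_frames, n, m))
  shifts <- matrix(stats::rnorm(2 * n_frames, sd = jitter), n_frames, 2)
  if (jitter == 0) shifts[] <- 0
  tt <- (seq_len(n_frames) - 1) / frame_rate
  rc <- expand.grid(r = seq_len(n), c = seq_len(m))
  x <- (rc$r - (n + 1) / 2) * pixel_size
  y <- (rc$c - (m + 1) / 2) * pixel_size
  stiffness <- matrix(1, n, m)
  ux <- uy <- NULL
  if (mode == "compression") {
    # base dilation about the image centre: div u = amplitude
    ux <- amplitude / 2 * x
    uy <- amplitude / 2 * y
    for (inc in inclusions) {
      dxv <- x - inc$center[1]; dyv <- y - inc$center[2]
      r2 <- dxv^2 + dyv^2
      inside <- r2 <= inc$radius^2
      stiffness[cbind(rc$r, rc$c)[inside, , drop = FALSE]] <- inc$factor
      ds <- (inc$factor - 1) * amplitude
      # divergence-free outside, uniform extra dilation inside
      scale <- ifelse(inside, ds / 2, ds / 2 * inc$radius^2 / pmax(r2, 1e-12))
      ux <- ux + scale * dxv
      uy <- uy + scale * dyv
    }
  }
  for (f in seq_len(n_frames)) {
    ph <- sin(2 * pi * frequency * tt[f])
    if (mode == "pulsation") {
      img <- base_image
      if (!is.null(target_mask)) img[target_mask] <- img[target_mask] * (1 + amplitude * ph)
      if (any(shifts[f, ] != 0))
        img <- matrix(cubic_sample(img, rc$r - shifts[f, 1], rc$c - shifts[f, 2]), n, m)
    } else {
      # first-order backward warp: frame(X) = base(X - u(X) * ph)
      img <- matrix(cubic_sample(base_image,
                                 rc$r - (ux * ph) / pixel_size - shifts[f, 1],
                                 rc$c - (uy * ph) / pixel_size - shifts[f, 2]),
                    n, m)
    }
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(n * m, sd = noise_sd), n, m)
    frames[f, , ] <- img
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size,
                 ground_truth = list(mode = mode, frequency = frequency,
                                     amplitude = amplitude,
                                     target_mask = target_mask,
                                     stiffness = stiffness,
                                     inclusions = inclusions),
                 seed = seed),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame sequence: %d frames of %d x %d px at %g Hz (%.2f mm pixels), mode %s\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size, x$ground_truth$mode))
  invisible(x)
}
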