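#' Ring-array geometry
#'
#' Describes a full-ring ultrasonic transducer array: a circle of uniformly
#' spaced flat-rectangular elements in the imaging (horizontal) plane, scanned
#' along the elevational axis. Defaults correspond to a 512-element,
#' 220-mm-diameter ring with 5-mm-tall elements at 1.35 mm pitch.
#'
#' @param ring_radius Ring radius in mm.
#' @param n_elements Number of elements, uniformly spaced in angle.
#' @param element_height Element size along the elevational axis (mm).
#' @param element_pitch Centre-to-centre element spacing along the ring (mm).
#' @param elevational_positions Strictly increasing scan heights (mm) at which
#'   the ring acquires data; a single 0 for pure 2D work.
#' @return An object of class `array_geometry`.
#' @export
array_geometry <- function(ring_radius = 110, n_elements = 512,
                           element_height = 5, element_pitch = 1.35,
                           elevational_positions = 0) {
  stopifnot(ring_radius > 0, n_elements >= 3, element_height > 0)
  # quoted pitches are rounded; allow a 0.1% slack on the circumference
  if (n_elements * element_pitch > 2 * pi * ring_radius * 1.001)
    stop("elements do not fit on the ring: n_elements * element_pitch > circumference")
  if (any(diff(elevational_positions) <= 0) && length(elevational_positions) > 1)
    stop("elevational_positions must be strictly increasing")
  structure(list(ring_radius = ring_radius, n_elements = n_elements,
                 element_height = element_height, element_pitch = element_pitch,
                 elevational_positions = as.numeric(elevational_positions)),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("ring array: %d elements, radius %.1f mm, element height %.1f mm, %d elevational step(s)\n",
              x$n_elements, x$ring_radius, x$element_height,
              length(x$elevational_positions)))
  invisible(x)
}

#' Element centre positions for one elevational step
#'
#' @param geometry An [array_geometry()].
#' @param z Elevational position of the ring (mm).
#' @return List with `xyz` (n x 3 positions) and `normal` (n x 2 inward
#'   in-plane unit normals).
#' @export
element_positions <- function(geometry, z = 0) {
  phi <- 2 * pi * (seq_len(geometry$n_elements) - 1) / geometry$n_elements
  x <- geometry$ring_radius * cos(phi)
  y <- geometry$ring_radius * sin(phi)
  list(xyz = cbind(x, y, rep(z, length(phi))),
       normal = cbind(-cos(phi), -sin(phi)))
}

#' Far-field elevational directivity of a flat element
#'
#' One-way amplitude sensitivity of a uniform line aperture of the element
#' height versus elevational angle; the `"gaussian"` variant is a fast
#' approximation matched to a given FWHM.
#'
#' @param theta_deg Elevational angle(s) from the imaging plane, degrees.
#' @param element_height Aperture height (mm).
#' @param f_center Frequency (MHz).
#' @param sos Speed of sound (mm/us).
#' @param model `"sinc"` (uniform aperture) or `"gaussian"`.
#' @param fwhm_deg FWHM used by the Gaussian model (defaults to the sinc
#'   pattern's FWHM).
#' @return Amplitude weights in `[ -0.22, 1 ]` (sinc sidelobes can be
#'   slightly negative).
#' @export
elevational_directivity <- function(theta_deg, element_height = 5,
                                    f_center = 2.25, sos = 1.5,
                                    model = c("sinc", "gaussian"),
                                    fwhm_deg = NULL) {
  model <- match.arg(model)
  th <- theta_deg * pi / 180
  if (model == "sinc") {
    lambda <- sos / f_center
    x <- pi * element_height * sin(th) / lambda
    out <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  } else {
    if (is.null(fwhm_deg))
      fwhm_deg <- directivity_fwhm(element_height, f_center, sos)
    sigma <- fwhm_deg / (2 * sqrt(2 * log(2)))
    out <- exp(-0.5 * (theta_deg / sigma)^2)
  }
  out
}

#' FWHM of the elevational directivity pattern
#'
#' Angular full width at half maximum of the one-way far-field sensitivity of
#' a uniform line aperture, found by root bracketing on the sinc pattern.
#'
#' @inheritParams elevational_directivity
#' @return FWHM in degrees.
#' @export
directivity_fwhm <- function(element_height = 5, f_center = 2.25, sos = 1.5) {
  f <- function(th) elevational_directivity(th, element_height, f_center, sos) - 0.5
  # half-power half-angle is below the first null at asin(lambda / L)
  upper <- asin(min(1, sos / f_center / element_height)) * 180 / pi
  2 * stats::uniroot(f, c(1e-6, upper * 0.999), tol = 1e-10)$root
}

#' Transducer element model
#'
#' Band-limited receive characteristics of one array element: a
#' Gaussian-envelope band-pass impulse response centred at `f_center` whose
#' -6 dB one-way fractional bandwidth is `fractional_bandwidth_oneway`, plus
#' the sampling scheme. The elevational divergence FWHM is derived from the
#' element height via the far-field aperture pattern.
#'
#' @param f_center Centre frequency (MHz).
#' @param fractional_bandwidth_oneway One-way -6 dB fractional bandwidth.
#' @param sampling_rate Sampling rate (MHz).
#' @param record_length Record duration after each pulse (us).
#' @param element_height Element height used to derive the divergence (mm).
#' @param sos Speed of sound used for the divergence derivation (mm/us).
#' @return An object of class `transducer_model` with derived fields
#'   `n_samples`, `divergence_fwhm` (deg), `sigma_t` (us) and `sigma_f` (MHz).
#' @export
transducer_model <- function(f_center = 2.25, fractional_bandwidth_oneway = 0.95,
                             sampling_rate = 40, record_length = 100,
                             element_height = 5, sos = 1.5) {
  stopifnot(f_center > 0, sampling_rate > 0, record_length > 0)
  if (fractional_bandwidth_oneway <= 0 || fractional_bandwidth_oneway >= 2)
    stop("fractional_bandwidth_oneway must lie in (0, 2)")
  sigma_f <- fractional_bandwidth_oneway * f_center / 2 / sqrt(2 * log(2))
  structure(list(f_center = f_center,
                 fractional_bandwidth_oneway = fractional_bandwidth_oneway,
                 sampling_rate = sampling_rate, record_length = record_length,
                 element_height = element_height,
                 n_samples = round(sampling_rate * record_length),
                 sigma_f = sigma_f, sigma_t = 1 / (2 * pi * sigma_f),
                 divergence_fwhm = directivity_fwhm(element_height, f_center, sos)),
            class = "transducer_model")
}

#' @export
print.transducer_model <- function(x, ...) {
  cat(sprintf("transducer: %.2f MHz centre, %.0f%% one-way bandwidth, %g MHz sampling, %g us record (%d samples), %.2f deg divergence FWHM\n",
              x$f_center, 100 * x$fractional_bandwidth_oneway, x$sampling_rate,
              x$record_length, x$n_samples, x$divergence_fwhm))
  invisible(x)
}

#' Element impulse response kernel
#'
#' Zero-phase Gaussian-envelope cosine at the centre frequency, sampled at the
#' transducer sampling rate, normalized to unit peak frequency response.
#'
#' @param transducer A [transducer_model()].
#' @return Numeric kernel (odd length, centred).
#' @export
impulse_response <- function(transducer) {
  fs <- transducer$sampling_rate
  half <- ceiling(5 * transducer$sigma_t * fs)
  t <- (-half:half) / fs
  k <- exp(-0.5 * (t / transducer$sigma_t)^2) * cos(2 * pi * transducer$f_center * t)
  k / sum(k * cos(2 * pi * transducer$f_center * t))  # unit gain at f_center
}
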