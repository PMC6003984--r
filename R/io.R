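sinogram_required_attrs <- c("sampling_rate_mhz", "speed_of_sound_mm_per_us",
                             "ring_radius_mm", "n_elements", "element_height_mm",
                             "elevational_positions_mm", "seed")

#' Write a sinogram container
#'
#' Stores the channel data as a float-32 multi-page TIFF (one page per
#' elevational step, each `elements x samples`) with a JSON sidecar carrying
#' the acquisition attributes.
#'
#' @param sinogram A `sinogram`.
#' @param path Output TIFF path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sinogram, path) {
  d <- sinogram$data
  scale <- max(abs(d), 1e-300)
  pages <- lapply(seq_len(dim(d)[1]), function(s) (d[s, , ] / scale + 1) / 2)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(sampling_rate_mhz = sinogram$transducer$sampling_rate,
               record_length_us = sinogram$transducer$record_length,
               f_center_mhz = sinogram$transducer$f_center,
               fractional_bandwidth_oneway = sinogram$transducer$fractional_bandwidth_oneway,
               speed_of_sound_mm_per_us = sinogram$speed_of_sound,
               ring_radius_mm = sinogram$geometry$ring_radius,
               n_elements = sinogram$geometry$n_elements,
               element_height_mm = sinogram$geometry$element_height,
               element_pitch_mm = sinogram$geometry$element_pitch,
               elevational_positions_mm = sinogram$geometry$elevational_positions,
               seed = sinogram$noise_seed,
               directivity_model = sinogram$directivity_model,
               amplitude_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a sinogram container
#'
#' @param path TIFF path written by [write_sinogram()].
#' @return A validated `sinogram`.
#' @export
read_sinogram <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar))
    stop("sinogram container or its JSON sidecar not found: ", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(sinogram_required_attrs, names(meta))
  if (length(missing))
    stop("sinogram sidecar is missing required attribute(s): ",
         paste(missing, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nsamp <- ncol(pages[[1]])
  if (nrow(pages[[1]]) != meta$n_elements)
    stop(sprintf("format error: data has %d element rows but n_elements = %d",
                 nrow(pages[[1]]), meta$n_elements))
  if (length(pages) != length(meta$elevational_positions_mm))
    stop("format error: page count does not match elevational_positions_mm")
  data <- array(0, dim = c(length(pages), meta$n_elements, nsamp))
  for (s in seq_along(pages))
    data[s, , ] <- (pages[[s]] * 2 - 1) * meta$amplitude_scale
  if (any(!is.finite(data))) stop("validation error: sinogram contains non-finite values")
  geom <- array_geometry(ring_radius = meta$ring_radius_mm,
                         n_elements = meta$n_elements,
                         element_height = meta$element_height_mm,
                         element_pitch = meta$element_pitch_mm %||% 1.35,
                         elevational_positions = meta$elevational_positions_mm)
  tm <- transducer_model(f_center = meta$f_center_mhz %||% 2.25,
                         fractional_bandwidth_oneway = meta$fractional_bandwidth_oneway %||% 0.95,
                         sampling_rate = meta$sampling_rate_mhz,
                         record_length = meta$record_length_us %||%
                           (nsamp / meta$sampling_rate_mhz),
                         element_height = meta$element_height_mm,
                         sos = meta$speed_of_sound_mm_per_us)
  structure(list(data = data, geometry = geom, transducer = tm,
                 speed_of_sound = meta$speed_of_sound_mm_per_us,
                 noise_seed = meta$seed,
                 directivity_model = meta$directivity_model %||% "aperture"),
            class = "sinogram")
}

#' Write an image volume (float TIFF + NIfTI)
#'
#' @param volume An `image_volume`.
#' @param path Base path; writes `<path>.tif` (pages = slices) and
#'   `<path>.nii` with mm voxel sizes in the header.
#' @return Written paths, invisibly.
#' @export
write_volume <- function(volume, path) {
  v <- volume$values
  if (length(dim(v)) == 2) v <- array(v, dim = c(dim(v), 1))
  lo <- min(v); hi <- max(v)
  pages <- lapply(seq_len(dim(v)[3]), function(z)
    if (hi > lo) (v[, , z] - lo) / (hi - lo) else v[, , z] * 0)
  tif <- paste0(path, ".tif")
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L)
  jsonlite::write_json(list(min = lo, max = hi, dx_mm = volume$dx,
                            dz_mm = volume$dz),
                       paste0(tif, ".json"), auto_unbox = TRUE, digits = NA)
  nii <- paste0(path, ".nii")
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- c(volume$dx, volume$dx, volume$dz)
  RNifti::writeNifti(img, nii)
  invisible(c(tif, nii))
}

#' Write / read a frame sequence (float TIFF + JSON sidecar)
#'
#' @param frames A `frame_sequence`.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  arr <- frames$frames
  lo <- min(arr); hi <- max(arr)
  pages <- lapply(seq_len(dim(arr)[1]), function(f)
    if (hi > lo) (arr[f, , ] - lo) / (hi - lo) else arr[f, , ] * 0)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(frame_rate_hz = frames$frame_rate,
                            pixel_size_mm = frames$pixel_size,
                            min = lo, max = hi, seed = frames$seed,
                            mode = frames$ground_truth$mode %||% NA,
                            frequency_hz = frames$ground_truth$frequency %||% NA),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frames
#' @param path TIFF path written by [write_frames()].
#' @export
read_frames <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages))
    arr[f, , ] <- pages[[f]] * (meta$max - meta$min) + meta$min
  structure(list(frames = arr, frame_rate = meta$frame_rate_hz,
                 pixel_size = meta$pixel_size_mm,
                 ground_truth = list(mode = meta$mode, frequency = meta$frequency_hz),
                 seed = meta$seed),
            class = "frame_sequence")
}

#' Pipeline configuration
#'
#' Returns the full stage-by-stage parameter set with defaults matching the
#' system's processing chain (2 mm density window, mean + 2 SD threshold,
#' 1855-px region filter, 1.0-1.6 Hz heartbeat band, 16 subdomains, 0.2 mm
#' smoothing, 100 elastography realizations, 3-12 px vesselness diameters,
#' 0.5-2.0 mm template range), optionally overridden from a YAML file and/or
#' an override list.
#'
#' @param yaml_file Optional YAML file of overrides.
#' @param overrides Optional named list of overrides (nested by stage).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(yaml_file = NULL, overrides = list()) {
  cfg <- list(
    seed = 1,
    out_dir = "ringpact-run",
    simulate = list(n_levels = 3, root_diameter = 0.9, junction_exponent = 3,
                    asymmetry = 0.9, grid_px = 320, pixel_mm = 0.1,
                    length_factor = 5,
                    n_trees = 0, scatter_density = 0.3, breast_radius = 15,
                    tumor = list(center = c(4, 3), radius = 4.5, multiplier = 6,
                                 stiffness = 0.5),
                    noise_sd = 0, n_sub = 1),
    recon = list(sos = 1.5, dx = 0.1, dz = 1, half_time = TRUE,
                 antialias = TRUE),
    vessels = list(scales = c(1.5, 2.5, 3.5, 4.5, 6), window = 51, k = 0.5,
                   min_segment_px = 3, template_range = c(0.5, 2.0)),
    dynamics = list(n_subdomains = 16, smoothing_radius = 0.2,
                    heart_band = c(1.0, 1.6), motion_rejection = 0.85),
    elastography = list(square_mm = 2, n_realizations = 100,
                        compression_freq = 0.25),
    tumor = list(window_mm = 2, k_sigma = 2.0, min_pixels = 1855,
                 # phantom-scaled support: the synthetic "breast" (vascularized
                 # region) spans ~30 mm of the 32 mm field, mirroring how the
                 # clinical 10 cm circle sits inside the full-breast image
                 support_diameter_mm = 30))
  if (!is.null(yaml_file)) {
    y <- yaml::read_yaml(yaml_file)
    cfg <- utils::modifyList(cfg, y)
  }
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  band <- cfg$dynamics$heart_band
  if (band[2] >= 10 / 2)
    stop("heart_band upper edge must be below the Nyquist frequency (frame_rate / 2)")
  class(cfg) <- "pipeline_config"
  cfg
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(obj, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Run the simulate -> reconstruct -> vessels -> density -> tumor pipeline
#'
#' Executes the full desk-scale pipeline on a synthetic phantom and writes a
#' JSON run manifest with package version, seeds, parameter hash, stage
#' outputs and their checksums. Identical config + seed produce identical
#' manifest hashes.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (defaults to `config$out_dir`).
#' @return The manifest list, invisibly; written to `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest <- list(package = "ringpact",
                   version = as.character(utils::packageVersion("ringpact")),
                   seed = config$seed, config_md5 = md5_of(unclass(config)),
                   outputs = list())
  record <- function(name, path) {
    manifest$outputs[[name]] <<- list(path = path,
                                      md5 = unname(tools::md5sum(path)))
  }
  result <- tryCatch({
    sc <- config$simulate
    half_mm <- sc$grid_px * sc$pixel_mm / 2
    n_trees <- sc$n_trees %||% 1
    parts <- lapply(seq_len(n_trees), function(k) {
      th <- 2 * pi * (k - 1) / n_trees
      generate_vessel_tree(seed = config$seed + 10 * k, n_levels = sc$n_levels,
                           root_diameter = sc$root_diameter,
                           junction_exponent = sc$junction_exponent,
                           asymmetry = sc$asymmetry,
                           length_factor = sc$length_factor %||% 4,
                           root_position = 0.8 * half_mm * c(-cos(th), -sin(th)),
                           root_direction = c(cos(th), sin(th)))
    })
    if ((sc$scatter_density %||% 0) > 0)
      parts <- c(parts, list(scatter_vessels(seed = config$seed + 5,
                                             density = sc$scatter_density,
                                             radius = sc$breast_radius %||% 9)))
    tree <- merge_trees(parts)
    grid <- phantom_grid(nx = sc$grid_px, ny = sc$grid_px, dx = sc$pixel_mm)
    phantom <- rasterize_phantom(tree, grid, tumor_spec = sc$tumor,
                                 seed = config$seed + 1, clip = TRUE)
    sino <- simulate_sinogram(phantom, array_geometry(),
                              transducer_model(),
                              speed_of_sound = config$recon$sos,
                              noise_sd = sc$noise_sd, seed = config$seed + 2,
                              n_sub = sc$n_sub)
    sino_path <- file.path(out_dir, "sinogram.tif")
    write_sinogram(sino, sino_path)
    record("sinogram", sino_path)

    stage <- "recon"
    rc <- config$recon
    cfg <- recon_config(sos = rc$sos, nx = sc$grid_px, ny = sc$grid_px,
                        dx = rc$dx, half_time = rc$half_time,
                        antialias = rc$antialias)
    img <- reconstruct_2d(sino, cfg)
    write_volume(img, file.path(out_dir, "recon"))
    record("recon", file.path(out_dir, "recon.tif"))

    stage <- "vessels"
    vc <- config$vessels
    vm <- enhance_and_segment(img$values, scales = vc$scales,
                              window = vc$window, k = vc$k)
    segs <- skeleton_segments(vm, min_length = vc$min_segment_px)
    seg_csv <- file.path(out_dir, "segments.csv")
    seg_df <- if (length(segs$segments)) {
      px <- do.call(rbind, segs$segments)
      data.frame(segment = rep(seq_along(segs$segments),
                               vapply(segs$segments, nrow, integer(1))),
                 row = px[, 1], col = px[, 2])
    } else data.frame(segment = integer(0), row = integer(0), col = integer(0))
    utils::write.csv(seg_df, seg_csv, row.names = FALSE)
    record("segments", seg_csv)

    stage <- "density"
    tc <- config$tumor
    dmap <- vessel_density_map(segs, dim(img$values), window_mm = tc$window_mm,
                               pixel_mm = rc$dx,
                               support_diameter_mm = tc$support_diameter_mm)

    stage <- "tumor"
    seg <- segment_tumors(dmap, k_sigma = tc$k_sigma,
                          min_pixels = tc$min_pixels)
    tumor_csv <- file.path(out_dir, "tumors.csv")
    utils::write.csv(seg$regions, tumor_csv, row.names = FALSE)
    record("tumors", tumor_csv)
    list(tree = tree, phantom = phantom, image = img, segments = segs,
         density = dmap, tumors = seg)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial outputs in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })
  manifest$outputs_md5 <- md5_of(manifest$outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- c(result, list(manifest = manifest, out_dir = out_dir))
  invisible(out)
}
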