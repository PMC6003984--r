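#' Sliding-window vessel density map
#'
#' Scans the image with a square window (2 mm x 2 mm by default, i.e. 20 x 20
#' px at the 0.1-mm pixel size); at each location the number of distinct
#' independent vessel segments intersecting the window is assigned to the
#' window's centre pixel and divided by the window area. Whole-breast mean
#' and SD are computed over a circular support (10 cm diameter by default)
#' around the image centre.
#'
#' @param segments A [skeleton_segments()] result (short segments already
#'   removed).
#' @param dims Image dimensions (defaults to the segment label image).
#' @param window_mm Window side (mm).
#' @param pixel_mm Pixel size (mm).
#' @param support_diameter_mm Diameter of the support circle for the
#'   whole-breast statistics (mm).
#' @return A `density_map`: `density` (segments per mm^2), `support` mask,
#'   `mean`, `sd`, `window_mm`, `pixel_mm`.
#' @export
vessel_density_map <- function(segments, dims = dim(segments$labels),
                               window_mm = 2.0, pixel_mm = 0.1,
                               support_diameter_mm = 100) {
  w <- round(window_mm / pixel_mm)
  n <- dims[1]; m <- dims[2]
  if (length(segments$segments)) {
    seg_px <- do.call(rbind, segments$segments)
    seg_id <- rep(seq_along(segments$segments),
                  vapply(segments$segments, nrow, integer(1)))
    counts <- window_segment_counts_cpp(seg_px, seg_id, n, m, w)
  } else {
    counts <- matrix(0L, n, m)
  }
  density <- counts / window_mm^2
  ctr <- c((n + 1) / 2, (m + 1) / 2)
  rr <- outer(((seq_len(n) - ctr[1]) * pixel_mm)^2,
              ((seq_len(m) - ctr[2]) * pixel_mm)^2, "+")
  support <- rr <= (support_diameter_mm / 2)^2
  structure(list(density = density, support = support,
                 mean = mean(density[support]), sd = stats::sd(density[support]),
                 window_mm = window_mm, pixel_mm = pixel_mm),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density map: %.3g +/- %.3g segments/mm^2 over support (window %g mm)\n",
              x$mean, x$sd, x$window_mm))
  invisible(x)
}

#' Segment tumors from a vessel density map
#'
#' Thresholds the density map at the whole-breast mean plus `k_sigma`
#' standard deviations, labels 8-connected supra-threshold components inside
#' the support, and rejects components with fewer than `min_pixels` pixels
#' (1855 px = 18.55 mm^2 at the 0.1-mm pixel size).
#'
#' @param dmap A [vessel_density_map()].
#' @param k_sigma Threshold offset in SD units.
#' @param min_pixels Minimum component pixel count.
#' @return A `tumor_segmentation`: `labels`, `regions` (data frame with pixel
#'   count, centre in mm from image centre, longest dimension in mm),
#'   `threshold`.
#' @export
segment_tumors <- function(dmap, k_sigma = 2.0, min_pixels = 1855) {
  if (dmap$sd == 0 || !is.finite(dmap$sd)) {
    warning("degenerate density statistics (SD = 0): no regions segmented")
    return(structure(list(labels = matrix(0L, nrow(dmap$density), ncol(dmap$density)),
                          regions = data.frame(), threshold = NA_real_,
                          k_sigma = k_sigma),
                     class = "tumor_segmentation"))
  }
  thr <- dmap$mean + k_sigma * dmap$sd
  cand <- dmap$density > thr & dmap$support
  lab <- label_components(cand, 8)
  n <- nrow(cand); m <- ncol(cand)
  ctr <- c((n + 1) / 2, (m + 1) / 2)
  out <- matrix(0L, n, m)
  regions <- list()
  for (id in seq_len(max(lab))) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < min_pixels) next
    new_id <- length(regions) + 1L
    out[px] <- new_id
    regions[[new_id]] <- data.frame(
      id = new_id, pixels = nrow(px),
      center_x = (mean(px[, 1]) - ctr[1]) * dmap$pixel_mm,
      center_y = (mean(px[, 2]) - ctr[2]) * dmap$pixel_mm,
      longest_mm = longest_dimension_px(px) * dmap$pixel_mm,
      mean_density = mean(dmap$density[px]))
  }
  structure(list(labels = out,
                 regions = if (length(regions)) do.call(rbind, regions) else data.frame(),
                 threshold = thr, k_sigma = k_sigma, min_pixels = min_pixels),
            class = "tumor_segmentation")
}

#' @export
print.tumor_segmentation <- function(x, ...) {
  cat(sprintf("tumor segmentation: %d region(s) above mean + %g SD\n",
              nrow(x$regions), x$k_sigma))
  invisible(x)
}

#' Per-breast density ratio between high-density and normal regions
#'
#' High-density pixels are those above the whole-breast mean plus `k_sigma`
#' SD; the ratio is their mean density over the mean density of the remaining
#' (normal) support pixels.
#'
#' @param dmap A [vessel_density_map()].
#' @param k_sigma SD multiplier defining "high density".
#' @return The ratio, or `NA` with a warning when no pixel is high-density.
#' @export
density_ratio <- function(dmap, k_sigma = 2.0) {
  thr <- dmap$mean + k_sigma * dmap$sd
  high <- dmap$density > thr & dmap$support
  normal <- !high & dmap$support
  if (!any(high)) {
    warning("no high-density pixels at this threshold; ratio undefined")
    return(NA_real_)
  }
  mean(dmap$density[high]) / mean(dmap$density[normal])
}

#' ROC analysis of density ratios for tumor detection
#'
#' Computes the per-breast density ratio for each `k_sigma` option, sweeps a
#' decision threshold on the ratio over `threshold_range` and reports
#' sensitivity (true-positive rate on affected breasts), specificity
#' (true-negative rate on contralateral breasts) and the trapezoidal AUC.
#'
#' @param density_maps List of [vessel_density_map()] objects (or precomputed
#'   numeric ratios).
#' @param labels Logical/0-1 vector: `TRUE` for affected breasts.
#' @param k_sigma_options SD multipliers defining high density.
#' @param threshold_range Ratio threshold sweep range.
#' @param step Sweep step.
#' @return A `roc_result`: per-k data frame of `ratios`, sweep table
#'   (`threshold`, `sensitivity`, `specificity`), `auc` per k, and the
#'   optimal-threshold interval (maximum Youden index) for each k.
#' @export
density_ratio_and_roc <- function(density_maps, labels,
                                  k_sigma_options = c(1.5, 2.0, 2.5),
                                  threshold_range = c(1, 6), step = 0.01) {
  labels <- as.logical(labels)
  if (length(density_maps) != length(labels))
    stop("one label per breast is required")
  if (length(unique(labels)) < 2)
    stop("need both affected and contralateral breasts")
  numeric_in <- is.numeric(density_maps)
  thresholds <- seq(threshold_range[1], threshold_range[2], by = step)
  out <- list()
  for (k in k_sigma_options) {
    ratios <- if (numeric_in) as.numeric(density_maps) else
      vapply(density_maps, density_ratio, numeric(1), k_sigma = k)
    keep <- is.finite(ratios)
    if (!all(keep))
      warning(sprintf("%d breast(s) excluded at k = %g (undefined ratio)",
                      sum(!keep), k))
    r <- ratios[keep]; lb <- labels[keep]
    tpr <- vapply(thresholds, function(t) mean(r[lb] >= t), numeric(1))
    fpr <- vapply(thresholds, function(t) mean(r[!lb] >= t), numeric(1))
    # append sweep endpoints to close the curve
    ftpr <- c(1, tpr, 0); ffpr <- c(1, fpr, 0)
    o <- order(ffpr, ftpr)
    auc <- sum(diff(ffpr[o]) * (ftpr[o][-1] + ftpr[o][-length(o)]) / 2)
    youden <- tpr + (1 - fpr) - 1
    best <- which(youden == max(youden))
    out[[as.character(k)]] <- list(
      k_sigma = k, ratios = data.frame(ratio = ratios, affected = labels),
      sweep = data.frame(threshold = thresholds, sensitivity = tpr,
                         specificity = 1 - fpr),
      auc = auc,
      optimal_interval = range(thresholds[best]))
  }
  structure(list(by_k = out, k_sigma_options = k_sigma_options),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  for (k in names(x$by_k)) {
    b <- x$by_k[[k]]
    cat(sprintf("k = %s: AUC %.3f, optimal ratio threshold in [%.2f, %.2f]\n",
                k, b$auc, b$optimal_interval[1], b$optimal_interval[2]))
  }
  invisible(x)
}
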