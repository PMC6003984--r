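#' Hessian (Frangi) vesselness response
#'
#' Multi-scale ridge filter for bright tubular structures: at each Gaussian
#' scale the image Hessian is computed by derivative-of-Gaussian convolution
#' (gamma-normalized by `sigma^2`); the per-pixel vesselness combines the
#' eigenvalue anisotropy ratio and second-order structure strength, and the
#' response is the maximum over scales.
#'
#' @param image 2D numeric matrix.
#' @param scales Gaussian sigmas (px); defaults span vessel diameters of
#'   about 3-12 px.
#' @param alpha,beta Frangi anisotropy and structure sensitivity parameters.
#' @return Matrix of vesselness values in `[0, 1]`.
#' @export
frangi_vesselness <- function(image, scales = c(1.5, 2.5, 3.5, 4.5, 6),
                              alpha = 0.5, beta = 0.5) {
  if (diff(range(image)) == 0) return(matrix(0, nrow(image), ncol(image)))
  gauss_kernel <- function(sigma, deriv = 0) {
    half <- ceiling(4 * sigma)
    x <- -half:half
    g <- exp(-x^2 / (2 * sigma^2))
    g <- g / sum(g)
    switch(as.character(deriv),
           "0" = g,
           "1" = -x / sigma^2 * g,
           "2" = (x^2 - sigma^2) / sigma^4 * g)
  }
  sep_filter <- function(img, kr, kc) {
    pad_r <- (length(kr) - 1) / 2
    k2 <- outer(kr, kc)
    EBImage::filter2(img, k2, boundary = "replicate")
  }
  best <- matrix(0, nrow(image), ncol(image))
  for (s in scales) {
    g0 <- gauss_kernel(s, 0); g1 <- gauss_kernel(s, 1); g2 <- gauss_kernel(s, 2)
    hxx <- s^2 * sep_filter(image, g2, g0)
    hyy <- s^2 * sep_filter(image, g0, g2)
    hxy <- s^2 * sep_filter(image, g1, g1)
    tr <- hxx + hyy
    dt <- sqrt(pmax((hxx - hyy)^2 / 4 + hxy^2, 0))
    l1 <- tr / 2 - dt  # more negative eigenvalue for bright ridges
    l2 <- tr / 2 + dt
    swap <- abs(l1) < abs(l2)
    tmp <- l1; l1[swap] <- l2[swap]; l2[swap] <- tmp[swap]
    # now |l1| >= |l2|; bright vessels need l1 < 0
    rb <- ifelse(abs(l1) > 0, abs(l2) / pmax(abs(l1), 1e-300), 0)
    ss <- sqrt(l1^2 + l2^2)
    gamma <- max(ss) / 2
    if (gamma <= 0) next
    v <- exp(-rb^2 / (2 * beta^2)) * (1 - exp(-ss^2 / (2 * gamma^2)))
    v[l1 >= 0] <- 0
    best <- pmax(best, v)
  }
  best
}

#' Vessel enhancement and segmentation
#'
#' Frangi vesselness enhancement followed by adaptive (local mean + k local
#' SD) thresholding and removal of isolated single pixels.
#'
#' @param image 2D slice (or pass slices of a volume one at a time).
#' @param scales Vesselness scales (px).
#' @param window Adaptive-threshold window size (px, odd).
#' @param k Threshold offset in units of the local SD.
#' @param min_response Absolute floor on the vesselness response (guards
#'   against segmenting pure noise in empty slices).
#' @return A `vessel_mask`: logical `mask`, the vesselness `response` and the
#'   parameter provenance.
#' @export
enhance_and_segment <- function(image, scales = c(1.5, 2.5, 3.5, 4.5, 6),
                                window = 51, k = 0.5, min_response = 0.05) {
  v <- frangi_vesselness(image, scales)
  if (all(v == 0)) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
  } else {
    thr <- box_mean(v, window) + k * box_sd(v, window)
    mask <- v > pmax(thr, min_response)
    # single-pixel elimination: drop pixels with no 8-neighbour in the mask
    n <- nrow(mask); m <- ncol(mask)
    pm <- matrix(FALSE, n + 2, m + 2)
    pm[2:(n + 1), 2:(m + 1)] <- mask
    nb <- matrix(0L, n, m)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- nb + pm[2:(n + 1) + dr, 2:(m + 1) + dc]
    }
    mask <- mask & nb > 0
  }
  structure(list(mask = mask, response = v,
                 provenance = list(scales = scales, window = window, k = k,
                                   min_response = min_response)),
            class = "vessel_mask")
}

#' Depth-encoded projection of a volume
#'
#' Maximum amplitude projection (MAP) along the elevational axis together
#' with the depth (elevational coordinate) of the maximum per pixel. The
#' depth map is median filtered with a 3 x 3 window, then a 6 x 6 median
#' restricted to segmented-vessel pixels is applied, and the composite keeps
#' depth only where the MAP belongs to a vessel.
#'
#' @param volume 3D array (nx x ny x nz) or an `image_volume`.
#' @param vessel_mask Logical nx x ny matrix of vessel pixels (e.g. from
#'   [enhance_and_segment()] of the MAP).
#' @param z_coords Elevational coordinate of each slice (mm).
#' @return A `depth_encoded`: `map`, `depth_raw` (unfiltered argmax depth,
#'   mm), `depth` (median-filtered, mm), `composite`.
#' @export
depth_encode <- function(volume, vessel_mask = NULL, z_coords = NULL) {
  if (inherits(volume, "image_volume")) {
    if (is.null(z_coords)) z_coords <- volume$z
    volume <- volume$values
  }
  if (length(dim(volume)) != 3) stop("depth_encode needs a 3D volume")
  nz <- dim(volume)[3]
  if (is.null(z_coords)) z_coords <- seq_len(nz)
  flat <- matrix(volume, ncol = nz)
  iz <- max.col(flat, ties.method = "first")
  map <- matrix(flat[cbind(seq_len(nrow(flat)), iz)], dim(volume)[1], dim(volume)[2])
  depth_raw <- matrix(z_coords[iz], dim(volume)[1], dim(volume)[2])
  depth <- median_filter(depth_raw, 1)  # 3 x 3
  if (!is.null(vessel_mask))
    depth <- masked_median_filter(depth, vessel_mask, 6)
  composite <- depth
  if (!is.null(vessel_mask)) composite[!vessel_mask] <- NA_real_
  structure(list(map = map, depth_raw = depth_raw, depth = depth,
                 composite = composite),
            class = "depth_encoded")
}

# one Zhang-Suen thinning pass; returns the (possibly unchanged) mask
zs_pass <- function(mask, odd) {
  n <- nrow(mask); m <- ncol(mask)
  pm <- matrix(FALSE, n + 2, m + 2)
  pm[2:(n + 1), 2:(m + 1)] <- mask
  sh <- function(dr, dc) pm[2:(n + 1) + dr, 2:(m + 1) + dc]
  p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
  p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
  bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  an <- matrix(0L, n, m)
  for (i in 1:8) an <- an + (!seqs[[i]] & seqs[[i + 1]])
  if (odd) {
    cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
  } else {
    cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
  }
  del <- mask & bn >= 2 & bn <= 6 & an == 1 & cond
  mask & !del
}

#' Skeletonize a vessel mask and split it into independent segments
#'
#' Morphological thinning (Zhang-Suen) to 1-px centrelines; skeleton pixels
#' with more than two 8-neighbours are junction pixels; removing them splits
#' the skeleton into independent vessel segments, and segments shorter than
#' `min_length` pixels are discarded.
#'
#' @param mask Logical matrix (or a `vessel_mask`).
#' @param min_length Minimum segment length in pixels.
#' @return A `segment_set`: `skeleton`, `junctions` (logical matrices),
#'   `segments` (list of ordered n x 2 pixel chains), `labels` (integer
#'   matrix of segment ids).
#' @export
skeleton_segments <- function(mask, min_length = 3) {
  if (inherits(mask, "vessel_mask")) mask <- mask$mask
  mask <- mask > 0
  dims <- dim(mask)
  if (!any(mask))
    return(structure(list(skeleton = mask, junctions = mask,
                          segments = list(), labels = matrix(0L, dims[1], dims[2])),
                     class = "segment_set"))
  sk <- mask
  repeat {
    s1 <- zs_pass(sk, TRUE)
    s2 <- zs_pass(s1, FALSE)
    if (identical(s2, sk)) break
    sk <- s2
  }
  n <- dims[1]; m <- dims[2]
  pm <- matrix(FALSE, n + 2, m + 2)
  pm[2:(n + 1), 2:(m + 1)] <- sk
  nb <- matrix(0L, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + pm[2:(n + 1) + dr, 2:(m + 1) + dc]
  }
  junctions <- sk & nb > 2
  body <- sk & !junctions
  lab <- label_components(body, 8)
  segments <- list()
  labels <- matrix(0L, n, m)
  for (id in seq_len(max(lab))) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < min_length) next
    segments[[length(segments) + 1]] <- order_chain(px)
    labels[px] <- length(segments)
  }
  structure(list(skeleton = sk, junctions = junctions, segments = segments,
                 labels = labels), class = "segment_set")
}

# order component pixels into a chain by walking from an endpoint
order_chain <- function(px) {
  k <- nrow(px)
  if (k <= 2) return(px)
  h <- new.env(hash = TRUE, size = 2 * k)
  for (i in seq_len(k)) assign(paste(px[i, 1], px[i, 2]), i, envir = h)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  nbrs <- lapply(seq_len(k), function(i) {
    out <- integer(0)
    for (o in seq_len(8)) {
      key <- paste(px[i, 1] + offs$dr[o], px[i, 2] + offs$dc[o])
      j <- h[[key]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  })
  deg <- lengths(nbrs)
  start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
  visited <- logical(k)
  path <- integer(0)
  cur <- start
  repeat {
    visited[cur] <- TRUE
    path <- c(path, cur)
    nxt <- nbrs[[cur]][!visited[nbrs[[cur]]]]
    if (!length(nxt)) break
    cur <- nxt[1]
  }
  px[path, , drop = FALSE]
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment set: %d independent segments, %d junction pixels\n",
              length(x$segments), sum(x$junctions)))
  invisible(x)
}

#' Simulate the reconstructed image of a straight vessel
#'
#' Rasterizes an in-plane cylindrical vessel of the given diameter into point
#' sources, runs the ring-array forward model and reconstructs a patch with
#' 2D universal back-projection. Used to build the template bank.
#'
#' @param diameter Vessel diameter (mm).
#' @param geometry,transducer System model used for the simulation.
#' @param patch_px Patch size (odd, px). @param pixel_mm Patch pixel (mm).
#' @param length_mm Simulated vessel length (mm).
#' @param source_spacing Rasterization spacing (mm).
#' @return `patch_px` x `patch_px` image of the vessel along the row axis.
#' @export
simulate_vessel_image <- function(diameter, geometry = array_geometry(),
                                  transducer = transducer_model(),
                                  patch_px = 41, pixel_mm = 0.1,
                                  length_mm = 6, source_spacing = 0.08) {
  xs <- seq(-length_mm / 2, length_mm / 2, by = source_spacing)
  ys <- seq(-diameter / 2 + source_spacing / 2, diameter / 2 - source_spacing / 2,
            by = source_spacing)
  if (!length(ys)) ys <- 0
  g <- expand.grid(x = xs, y = ys)
  src <- point_sources(g$x, g$y, 0, radius = source_spacing / 2)
  sino <- simulate_sinogram(src, geometry, transducer, n_sub = 1)
  cfg <- recon_config(nx = patch_px, ny = patch_px, dx = pixel_mm)
  reconstruct_2d(sino, cfg)$values
}

#' Build a bank of simulated vessel templates
#'
#' Simulated-and-reconstructed images of straight vessels over a grid of
#' diameters and orientations, normalized to zero mean and unit energy.
#'
#' @param diameters Template diameters (mm).
#' @param orientations Template orientations (deg).
#' @param geometry,transducer System model matched to the data.
#' @param patch_px,pixel_mm Template raster.
#' @return A `template_bank`.
#' @export
build_template_bank <- function(diameters = seq(0.5, 2.0, by = 0.1),
                                orientations = seq(0, 150, by = 30),
                                geometry = array_geometry(),
                                transducer = transducer_model(),
                                patch_px = 41, pixel_mm = 0.1) {
  norm_t <- function(t) {
    t <- t - mean(t)
    t / sqrt(sum(t^2))
  }
  base <- lapply(diameters, simulate_vessel_image, geometry = geometry,
                 transducer = transducer, patch_px = patch_px,
                 pixel_mm = pixel_mm)
  ctr <- (patch_px + 1) / 2
  rc <- expand.grid(r = seq_len(patch_px), c = seq_len(patch_px))
  templates <- list()
  for (oi in seq_along(orientations)) {
    th <- orientations[oi] * pi / 180
    rot_r <- ctr + cos(th) * (rc$r - ctr) - sin(th) * (rc$c - ctr)
    rot_c <- ctr + sin(th) * (rc$r - ctr) + cos(th) * (rc$c - ctr)
    for (di in seq_along(diameters)) {
      img <- if (orientations[oi] == 0) base[[di]] else
        matrix(bilinear_sample(base[[di]], rot_r, rot_c), patch_px, patch_px)
      templates[[length(templates) + 1]] <-
        list(image = norm_t(img), diameter = diameters[di],
             orientation = orientations[oi])
    }
  }
  structure(list(templates = templates, diameters = diameters,
                 orientations = orientations, patch_px = patch_px,
                 pixel_mm = pixel_mm,
                 meta = list(f_center = transducer$f_center,
                             bandwidth = transducer$fractional_bandwidth_oneway)),
            class = "template_bank")
}

#' Measure a vessel diameter by template matching
#'
#' Normalized cross-correlation of the patch against every template
#' (diameters x orientations, over small spatial shifts); the diameter of the
#' best-matching template is refined by parabolic interpolation over the
#' diameter grid. A best match at the bank boundary (smallest or largest
#' diameter) is returned with a warning.
#'
#' @param patch Image patch containing one locally straight vessel, at the
#'   bank's pixel size.
#' @param bank A [build_template_bank()].
#' @param max_shift Spatial search radius (px).
#' @return List: `diameter` (mm), `orientation` (deg), `correlation`.
#' @export
measure_diameter <- function(patch, bank, max_shift = 4) {
  p <- bank$patch_px
  if (nrow(patch) < p || ncol(patch) < p)
    stop("patch is smaller than the bank templates")
  r0 <- floor((nrow(patch) - p) / 2) + 1
  c0 <- floor((ncol(patch) - p) / 2) + 1
  shifts <- expand.grid(dr = -max_shift:max_shift, dc = -max_shift:max_shift)
  ok <- r0 + shifts$dr >= 1 & r0 + shifts$dr + p - 1 <= nrow(patch) &
    c0 + shifts$dc >= 1 & c0 + shifts$dc + p - 1 <= ncol(patch)
  shifts <- shifts[ok, ]
  windows <- lapply(seq_len(nrow(shifts)), function(i) {
    w <- patch[r0 + shifts$dr[i] + 0:(p - 1), c0 + shifts$dc[i] + 0:(p - 1)]
    w <- w - mean(w)
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w / nrm else w
  })
  score <- matrix(-Inf, length(bank$diameters), length(bank$orientations))
  for (ti in seq_along(bank$templates)) {
    tpl <- bank$templates[[ti]]
    di <- match(tpl$diameter, bank$diameters)
    oi <- match(tpl$orientation, bank$orientations)
    cc <- max(vapply(windows, function(w) sum(w * tpl$image), numeric(1)))
    score[di, oi] <- max(score[di, oi], cc)
  }
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  di <- best[1]; oi <- best[2]
  d <- bank$diameters[di]
  if (max(score) < 0.5)
    warning(sprintf("best template correlation is only %.2f: the vessel likely lies outside the %.1f-%.1f mm bank range",
                    max(score), min(bank$diameters), max(bank$diameters)))
  if (di == 1 || di == length(bank$diameters)) {
    warning(sprintf("best template at the bank boundary (%.2f mm); diameter out of the 0.5-2.0 mm range", d))
  } else {
    # parabolic refinement over the diameter grid at the best orientation
    y <- score[(di - 1):(di + 1), oi]
    denom <- y[1] - 2 * y[2] + y[3]
    if (is.finite(denom) && denom < 0) {
      dd <- bank$diameters[2] - bank$diameters[1]
      d <- d + 0.5 * (y[1] - y[3]) / denom * dd
    }
  }
  list(diameter = d, orientation = bank$orientations[oi],
       correlation = max(score))
}

#' Junction exponent and cube-ratio of a vascular bifurcation
#'
#' The junction exponent `X_B` solves `D_parent^X = D_a^X + D_b^X` (bisection
#' on `[0.5, 10]` to `|f| < 1e-9`); `X_B = 3` is Murray's law. The cube ratio
#' is `R_B = D_parent^3 / (D_a^3 + D_b^3)`.
#'
#' @param d_parent,d_daughter_a,d_daughter_b Diameters (mm), parent largest.
#' @return A `bifurcation` data frame row: diameters, `x_b`, `r_b`.
#' @export
junction_metrics <- function(d_parent, d_daughter_a, d_daughter_b) {
  if (any(c(d_parent, d_daughter_a, d_daughter_b) <= 0))
    stop("diameters must be positive")
  if (d_parent <= max(d_daughter_a, d_daughter_b))
    stop("no junction exponent exists: parent diameter must exceed both daughters")
  f <- function(x) (d_daughter_a / d_parent)^x + (d_daughter_b / d_parent)^x - 1
  lo <- 0.5; hi <- 10
  if (f(lo) < 0 || f(hi) > 0)
    stop("no junction exponent in [0.5, 10] solves these diameters")
  while (TRUE) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-12 || (hi - lo) < 1e-13) break
    if (fm > 0) lo <- mid else hi <- mid
  }
  structure(data.frame(d_parent = d_parent, d_daughter_a = d_daughter_a,
                       d_daughter_b = d_daughter_b, x_b = mid,
                       r_b = d_parent^3 / (d_daughter_a^3 + d_daughter_b^3)),
            class = c("bifurcation", "data.frame"))
}
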