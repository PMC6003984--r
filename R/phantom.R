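#' Generate a branching vessel-tree phantom
#'
#' Builds a planar binary vessel tree in which every bifurcation obeys the
#' planted junction power law `D_parent^X = D_a^X + D_b^X` exactly, with
#' daughter asymmetry `D_b / D_a = asymmetry`. Segment lengths scale with
#' diameter and branch directions receive seeded angular jitter.
#'
#' @param seed Integer seed; identical seeds give identical trees.
#' @param n_levels Number of bifurcation levels (>= 1).
#' @param root_diameter Root vessel diameter, mm, in (0.2, 5).
#' @param junction_exponent Planted exponent X, in (1.5, 4).
#' @param asymmetry Daughter diameter ratio `D_b / D_a`, in (0, 1].
#' @param root_position,root_direction Root start (mm) and unit direction.
#' @param length_factor Segment length = `length_factor * diameter`.
#' @param branch_angle_deg Mean half-angle between daughters (degrees).
#' @param jitter_deg SD of angular jitter applied to branch directions.
#' @return A `vessel_tree`: `segments` (list of polyline, radius, level),
#'   `bifurcations` (data frame of parent/daughter ids and diameters) and the
#'   generation parameters.
#' @export
generate_vessel_tree <- function(seed = 1, n_levels = 5, root_diameter = 1.6,
                                 junction_exponent = 3, asymmetry = 1,
                                 root_position = c(-16, 0),
                                 root_direction = c(1, 0), length_factor = 6,
                                 branch_angle_deg = 32, jitter_deg = 7) {
  if (n_levels < 1) stop("n_levels must be >= 1")
  if (root_diameter <= 0.2 || root_diameter >= 5)
    stop("root_diameter must lie in (0.2, 5) mm")
  if (junction_exponent <= 1.5 || junction_exponent >= 4)
    stop("junction_exponent must lie in (1.5, 4)")
  if (asymmetry <= 0 || asymmetry > 1) stop("asymmetry must lie in (0, 1]")
  set.seed(seed)
  segments <- list()
  bifurcations <- list()
  dirn <- root_direction / sqrt(sum(root_direction^2))
  grow <- function(pos, dirn, diameter, level) {
    len <- length_factor * diameter
    end <- pos + dirn * len
    seg <- list(polyline = rbind(pos, end), radius = diameter / 2, level = level)
    segments[[length(segments) + 1]] <<- seg
    id <- length(segments)
    if (level > n_levels) return(id)
    x <- junction_exponent
    d_a <- diameter / (1 + asymmetry^x)^(1 / x)
    d_b <- asymmetry * d_a
    th <- atan2(dirn[2], dirn[1])
    spread <- branch_angle_deg * pi / 180
    ja <- stats::rnorm(2, sd = jitter_deg * pi / 180)
    th_a <- th + spread / 2 + ja[1]
    th_b <- th - spread / 2 + ja[2]
    id_a <- grow(end, c(cos(th_a), sin(th_a)), d_a, level + 1)
    id_b <- grow(end, c(cos(th_b), sin(th_b)), d_b, level + 1)
    bifurcations[[length(bifurcations) + 1]] <<-
      data.frame(parent = id, daughter_a = id_a, daughter_b = id_b,
                 d_parent = diameter, d_daughter_a = d_a, d_daughter_b = d_b)
    id
  }
  grow(root_position, dirn, root_diameter, 1)
  structure(list(segments = segments,
                 bifurcations = do.call(rbind, bifurcations),
                 params = list(seed = seed, n_levels = n_levels,
                               root_diameter = root_diameter,
                               junction_exponent = junction_exponent,
                               asymmetry = asymmetry)),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("vessel tree: %d segments, %d bifurcations, planted junction exponent %.3f\n",
              length(x$segments),
              if (is.null(x$bifurcations)) 0L else nrow(x$bifurcations),
              x$params$junction_exponent))
  invisible(x)
}

#' Voxel grid specification
#'
#' @param nx,ny,nz Grid size; `nz = 1` gives a single-slice phantom.
#' @param dx In-plane voxel size (mm). @param dz Elevational voxel size (mm).
#' @param center Physical centre (mm), on the ring axis by default.
#' @return A `grid_spec` with coordinate vectors `x`, `y`, `z`.
#' @export
phantom_grid <- function(nx = 256, ny = 256, nz = 1, dx = 0.1, dz = 1,
                         center = c(0, 0, 0)) {
  structure(list(nx = nx, ny = ny, nz = nz, dx = dx, dz = dz, center = center,
                 x = center[1] + (seq_len(nx) - (nx + 1) / 2) * dx,
                 y = center[2] + (seq_len(ny) - (ny + 1) / 2) * dx,
                 z = center[3] + (seq_len(nz) - (nz + 1) / 2) * dz),
            class = "grid_spec")
}

# mark voxels within `radius` of the sampled centreline of a segment
rasterize_segment <- function(absorption, grid, polyline, radius, value = 1) {
  step <- grid$dx / 2
  pts <- list()
  for (i in seq_len(nrow(polyline) - 1)) {
    a <- polyline[i, ]; b <- polyline[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    tseq <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
    pts[[i]] <- cbind(a[1] + tseq * (b[1] - a[1]), a[2] + tseq * (b[2] - a[2]))
  }
  pts <- do.call(rbind, pts)
  half <- ceiling(radius / grid$dx) + 1
  iz <- which.min(abs(grid$z))
  for (k in seq_len(nrow(pts))) {
    i0 <- findInterval(pts[k, 1], grid$x + grid$dx / 2) + 1
    j0 <- findInterval(pts[k, 2], grid$y + grid$dx / 2) + 1
    ii <- max(1, i0 - half):min(grid$nx, i0 + half)
    jj <- max(1, j0 - half):min(grid$ny, j0 + half)
    if (!length(ii) || !length(jj)) next
    dx2 <- outer((grid$x[ii] - pts[k, 1])^2, (grid$y[jj] - pts[k, 2])^2, "+")
    sel <- dx2 <= radius^2
    if (any(sel)) {
      sub <- absorption[ii, jj, iz]
      sub[sel] <- pmax(sub[sel], value)
      absorption[ii, jj, iz] <- sub
    }
  }
  absorption
}

#' Rasterize a vessel tree into a voxel phantom
#'
#' Paints the tree onto an absorption grid and optionally plants a tumor-like
#' region: a disc that receives extra short vessel segments until its segment
#' count per area is about `multiplier` times the background, and whose
#' stiffness is reduced to the given factor (tumors present as dense-vessel,
#' low-compliance regions).
#'
#' @param tree A [generate_vessel_tree()] result.
#' @param grid A [phantom_grid()]; must cover the tree's bounding box.
#' @param tumor_spec Optional `list(center = c(x, y) mm, radius = mm,
#'   multiplier >= 1, stiffness <= 1)`.
#' @param vessel_absorption Absorption value painted on vessel voxels.
#' @param seed Seed for the tumor's extra segments (defaults to the tree's).
#' @param clip Clamp out-of-grid polyline points to the grid instead of
#'   raising an out-of-bounds error.
#' @return A `pact_phantom`: `absorption`, `stiffness`, `labels` (0 background,
#'   1 vessel, 2 tumor region), the grid, segment records and tumor spec.
#' @export
rasterize_phantom <- function(tree, grid = phantom_grid(), tumor_spec = NULL,
                              vessel_absorption = 1, seed = NULL, clip = FALSE) {
  segs <- tree$segments
  if (length(segs) > 0) {
    if (clip) {
      segs <- lapply(segs, function(s) {
        s$polyline[, 1] <- pmin(pmax(s$polyline[, 1], grid$x[1]), grid$x[grid$nx])
        s$polyline[, 2] <- pmin(pmax(s$polyline[, 2], grid$y[1]), grid$y[grid$ny])
        s
      })
    }
    allpts <- do.call(rbind, lapply(segs, `[[`, "polyline"))
    if (min(allpts[, 1]) < grid$x[1] || max(allpts[, 1]) > grid$x[grid$nx] ||
        min(allpts[, 2]) < grid$y[1] || max(allpts[, 2]) > grid$y[grid$ny])
      stop("vessel tree extends outside the phantom grid (out of bounds)")
  }
  absorption <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  stiffness <- array(1, dim = dim(absorption))
  labels <- array(0L, dim = dim(absorption))
  seg_records <- lapply(seq_along(segs), function(i) {
    list(polyline = segs[[i]]$polyline, radius = segs[[i]]$radius,
         level = segs[[i]]$level, tumor = FALSE)
  })
  if (!is.null(tumor_spec)) {
    stopifnot(tumor_spec$multiplier >= 1, tumor_spec$stiffness <= 1)
    if (is.null(seed)) seed <- (tree$params$seed %||% 1) + 1000L
    set.seed(seed)
    ctr <- tumor_spec$center; rad <- tumor_spec$radius
    area_tumor <- pi * rad^2
    mid <- function(p) colMeans(p$polyline)
    mids <- if (length(seg_records)) t(vapply(seg_records, mid, numeric(2))) else matrix(0, 0, 2)
    in_tumor <- if (nrow(mids)) (mids[, 1] - ctr[1])^2 + (mids[, 2] - ctr[2])^2 <= rad^2 else logical(0)
    # background density is referenced to the vascularized region (convex
    # hull of the segment midpoints), not the full grid, so the planted
    # multiplier means "times the surrounding tissue's vessel density"
    support_area <- if (nrow(mids) >= 3) {
      h <- mids[grDevices::chull(mids[, 1], mids[, 2]), , drop = FALSE]
      abs(sum(h[, 1] * (h[c(2:nrow(h), 1), 2] - h[c(nrow(h), 1:(nrow(h) - 1)), 2])) / 2) -
        area_tumor
    } else {
      (grid$x[grid$nx] - grid$x[1]) * (grid$y[grid$ny] - grid$y[1]) - area_tumor
    }
    bg_density <- sum(!in_tumor) / max(support_area, area_tumor)
    n_target <- round(tumor_spec$multiplier * bg_density * area_tumor)
    n_extra <- max(0, n_target - sum(in_tumor))
    # hard-core placement: microvessels keep a minimum centre separation,
    # which matches spaced angiogenic growth and keeps them resolvable
    placed <- matrix(numeric(0), 0, 2)
    min_sep <- 0.4
    for (k in seq_len(n_extra)) {
      for (try in 1:200) {
        c0 <- ctr + stats::runif(2, -rad, rad)
        if (sum((c0 - ctr)^2) > (0.9 * rad)^2) next
        if (nrow(placed) == 0 ||
            min((placed[, 1] - c0[1])^2 + (placed[, 2] - c0[2])^2) >= min_sep^2)
          break
        c0 <- NULL
      }
      if (is.null(c0)) next
      placed <- rbind(placed, c0)
      th <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 1.0, 1.5)
      d <- stats::runif(1, 0.15, 0.2)  # angiogenic microvessels: thin
      seg_records[[length(seg_records) + 1]] <-
        list(polyline = rbind(c0 - len / 2 * c(cos(th), sin(th)),
                              c0 + len / 2 * c(cos(th), sin(th))),
             radius = d / 2, level = NA_integer_, tumor = TRUE)
    }
    iz <- which.min(abs(grid$z))
    disc <- outer((grid$x - ctr[1])^2, (grid$y - ctr[2])^2, "+") <= rad^2
    sl <- stiffness[, , iz]; sl[disc] <- tumor_spec$stiffness; stiffness[, , iz] <- sl
    ll <- labels[, , iz]; ll[disc] <- 2L; labels[, , iz] <- ll
  }
  for (s in seg_records)
    absorption <- rasterize_segment(absorption, grid, s$polyline, s$radius,
                                    vessel_absorption)
  labels[absorption > 0] <- 1L
  structure(list(absorption = absorption, stiffness = stiffness,
                 labels = labels, grid = grid, segments = seg_records,
                 tumor_spec = tumor_spec, tree = tree),
            class = "pact_phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pact_phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d x %d voxels (%.2g mm in-plane), %d segments%s\n",
              x$grid$nx, x$grid$ny, x$grid$nz, x$grid$dx, length(x$segments),
              if (is.null(x$tumor_spec)) "" else
                sprintf(", tumor (r = %g mm, density x%g)", x$tumor_spec$radius,
                        x$tumor_spec$multiplier)))
  invisible(x)
}

#' Merge several vessel trees into one phantom tree
#'
#' A breast cross-section contains many vascular trees entering from
#' different directions; merging independently generated trees gives phantoms
#' with spatially even background vessel density.
#'
#' @param trees List of [generate_vessel_tree()] results.
#' @return A `vessel_tree` with concatenated segments and bifurcations.
#' @export
merge_trees <- function(trees) {
  segments <- list()
  bifs <- list()
  for (tr in trees) {
    off <- length(segments)
    segments <- c(segments, tr$segments)
    if (!is.null(tr$bifurcations) && nrow(tr$bifurcations)) {
      b <- tr$bifurcations
      b$parent <- b$parent + off
      b$daughter_a <- b$daughter_a + off
      b$daughter_b <- b$daughter_b + off
      bifs[[length(bifs) + 1]] <- b
    }
  }
  structure(list(segments = segments,
                 bifurcations = if (length(bifs)) do.call(rbind, bifs) else NULL,
                 params = trees[[1]]$params),
            class = "vessel_tree")
}

#' Uniformly scattered short-vessel background
#'
#' Generates straight short vessel segments with uniformly random positions
#' and orientations inside a disc, emulating an evenly vascularized tissue
#' cross-section (or the chopped-fiber phantoms used to mimic small vessels).
#' The result merges with trees via [merge_trees()] and rasterizes like any
#' vessel tree.
#'
#' @param seed Integer seed.
#' @param density Segments per mm^2.
#' @param center,radius Disc region (mm).
#' @param length_range,diameter_range Segment length / diameter ranges (mm).
#' @param min_sep Minimum centre-to-centre separation (mm; hard-core
#'   placement, emulating spaced vessels/fibres).
#' @return A `vessel_tree` with unbranched segments.
#' @export
scatter_vessels <- function(seed = 1, density = 1.0, center = c(0, 0),
                            radius = 9, length_range = c(1.0, 1.5),
                            diameter_range = c(0.15, 0.2), min_sep = 0.8) {
  set.seed(seed)
  n <- stats::rpois(1, density * pi * radius^2)
  segments <- vector("list", n)
  placed <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n)) {
    p <- NULL
    for (try in 1:200) {
      p <- center + stats::runif(2, -radius, radius)
      if (sum((p - center)^2) > radius^2) { p <- NULL; next }
      if (nrow(placed) == 0 ||
          min((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) >= min_sep^2)
        break
      p <- NULL
    }
    if (is.null(p)) next
    placed <- rbind(placed, p)
    th <- stats::runif(1, 0, pi)
    len <- stats::runif(1, length_range[1], length_range[2])
    d <- stats::runif(1, diameter_range[1], diameter_range[2])
    segments[[k]] <- list(polyline = rbind(p - len / 2 * c(cos(th), sin(th)),
                                           p + len / 2 * c(cos(th), sin(th))),
                          radius = d / 2, level = 1L)
  }
  segments <- segments[!vapply(segments, is.null, logical(1))]
  structure(list(segments = segments, bifurcations = NULL,
                 params = list(seed = seed, density = density,
                               radius = radius)),
            class = "vessel_tree")
}
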