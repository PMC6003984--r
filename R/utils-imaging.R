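# Shared raster helpers. Images are plain numeric matrices [row, col];
# physical coordinates place x along rows and y along columns with the
# origin at the grid centre.

# zero-phase convolution of every row of `mat` with a centred odd-length
# kernel, linear (zero-padded) boundaries
convolve_rows <- function(mat, kernel) {
  n <- ncol(mat)
  half <- (length(kernel) - 1) / 2
  nfft <- stats::nextn(n + length(kernel), 2)
  kpad <- numeric(nfft)
  kpad[1:(half + 1)] <- kernel[(half + 1):length(kernel)]
  kpad[(nfft - half + 1):nfft] <- kernel[1:half]
  K <- stats::fft(kpad)
  X <- stats::mvfft(t(cbind(mat, matrix(0, nrow(mat), nfft - n))))
  Re(t(stats::mvfft(X * K, inverse = TRUE)))[, 1:n, drop = FALSE] / nfft
}

# separable Gaussian blur with replicated edges
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma, boundary = "replicate")
}

# local mean over a w x w box (replicated edges) via cumulative sums
box_mean <- function(img, w) {
  half <- floor(w / 2)
  n <- nrow(img); m <- ncol(img)
  pad <- img[c(rep(1, half), 1:n, rep(n, w - 1 - half)),
             c(rep(1, half), 1:m, rep(m, w - 1 - half)), drop = FALSE]
  cs <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  Z <- rbind(0, cbind(0, cs))
  i1 <- 1:n; i2 <- i1 + w; j1 <- 1:m; j2 <- j1 + w
  (Z[i2, j2] - Z[i2, j1, drop = FALSE] - Z[i1, j2, drop = FALSE] +
     Z[i1, j1, drop = FALSE]) / (w * w)
}

box_sd <- function(img, w) {
  m1 <- box_mean(img, w)
  m2 <- box_mean(img^2, w)
  sqrt(pmax(m2 - m1^2, 0))
}

# median filter over a (2r+1) x (2r+1) window (EBImage needs [0,1] range)
median_filter <- function(img, radius) {
  lo <- min(img); hi <- max(img)
  if (hi <= lo) return(img)
  EBImage::medianFilter((img - lo) / (hi - lo), size = radius) * (hi - lo) + lo
}

# median over w x w window restricted to `mask` pixels; non-mask pixels kept
masked_median_filter <- function(img, mask, w) {
  half <- floor(w / 2)
  out <- img
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  n <- nrow(img); m <- ncol(img)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    rr <- max(1, r - half):min(n, r + half - ((w + 1) %% 2))
    cc <- max(1, c - half):min(m, c + half - ((w + 1) %% 2))
    vals <- img[rr, cc][mask[rr, cc]]
    if (length(vals)) out[r, c] <- stats::median(vals)
  }
  out
}

# bilinear sampling at continuous (row, col) positions with replicated
# edges (out-of-domain positions clamp to the border value, which keeps
# correlations and registration residuals meaningful near frame borders)
bilinear_sample <- function(img, r, c) {
  n <- nrow(img); m <- ncol(img)
  r <- pmin(pmax(as.vector(r), 1), n); c <- pmin(pmax(as.vector(c), 1), m)
  r0 <- pmin(floor(r), n - 1); c0 <- pmin(floor(c), m - 1)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) img[cbind(ri, ci)]
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
}

# 8- or 4-connected component labels of a logical matrix (0 = background)
label_components <- function(mask, connectivity = 8) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  id <- integer(n * m); id[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  r <- (idx - 1L) %% n + 1L; c <- (idx - 1L) %/% n + 1L
  for (o in offs) {
    r2 <- r + o[1]; c2 <- c + o[2]
    ok <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= m
    i2 <- (c2[ok] - 1L) * n + r2[ok]
    keep <- mask[i2]
    edges[[length(edges) + 1]] <- cbind(id[idx[ok][keep]], id[i2[keep]])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(rbind(e, cbind(seq_along(idx), seq_along(idx))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# indices (row, col) of pixels whose centres fall inside a triangle
rasterize_triangle <- function(v, nrow, ncol) {
  r0 <- max(1L, floor(min(v[, 1]))); r1 <- min(nrow, ceiling(max(v[, 1])))
  c0 <- max(1L, floor(min(v[, 2]))); c1 <- min(ncol, ceiling(max(v[, 2])))
  if (r1 < r0 || c1 < c0) return(matrix(integer(0), 0, 2))
  g <- expand.grid(r = r0:r1, c = c0:c1)
  d <- function(p, a, b) (p$r - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (p$c - b[2])
  d1 <- d(g, v[1, ], v[2, ]); d2 <- d(g, v[2, ], v[3, ]); d3 <- d(g, v[3, ], v[1, ])
  neg <- d1 < 0 | d2 < 0 | d3 < 0
  pos <- d1 > 0 | d2 > 0 | d3 > 0
  inside <- !(neg & pos)
  as.matrix(g[inside, , drop = FALSE])
}

# longest pairwise distance among pixel coordinates (px), via convex hull
longest_dimension_px <- function(coords) {
  if (nrow(coords) == 1) return(0)
  h <- coords[grDevices::chull(coords[, 1], coords[, 2]), , drop = FALSE]
  max(stats::dist(h))
}

# Catmull-Rom (cubic) sampling at continuous (row, col) positions with
# replicated edges (out-of-domain positions clamp to the border value). Used
# by the frame generator, where interpolation smoothing and border effects
# must stay well below the planted intensity signals.
cubic_sample <- function(img, r, c) {
  n <- nrow(img); m <- ncol(img)
  r <- pmin(pmax(as.vector(r), 1), n); c <- pmin(pmax(as.vector(c), 1), m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ck <- function(f) cbind(
    -0.5 * f + f^2 - 0.5 * f^3,
    1 - 2.5 * f^2 + 1.5 * f^3,
    0.5 * f + 2 * f^2 - 1.5 * f^3,
    -0.5 * f^2 + 0.5 * f^3)
  wr <- ck(fr); wc <- ck(fc)
  out <- numeric(length(r))
  cl <- function(i, size) pmin(pmax(i, 1), size)
  for (a in 1:4) {
    ra <- cl(r0 + a - 2, n)
    rowacc <- numeric(length(r))
    for (b in 1:4) {
      ca <- cl(c0 + b - 2, m)
      rowacc <- rowacc + wc[, b] * img[cbind(ra, ca)]
    }
    out <- out + wr[, a] * rowacc
  }
  out
}
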