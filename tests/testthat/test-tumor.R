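make_segments <- function(seg_list, dims) {
  labels <- matrix(0L, dims[1], dims[2])
  for (i in seq_along(seg_list)) labels[seg_list[[i]]] <- i
  structure(list(skeleton = labels > 0, junctions = labels & FALSE,
                 segments = seg_list, labels = labels),
            class = "segment_set")
}

test_that("density windows count distinct segments per 2 mm window", {
  # uniform parallel lines 1 mm apart -> 2 lines per 2 mm window = 0.5 / mm^2
  dims <- c(120, 120)
  segs <- lapply(seq(10, 110, by = 10), function(r) cbind(r, 10:110))
  ss <- make_segments(segs, dims)
  dm <- vessel_density_map(ss, dims, window_mm = 2, pixel_mm = 0.1,
                           support_diameter_mm = 8)
  inner <- dm$density[35:85, 35:85]
  expect_true(all(abs(inner - 0.5) <= 0.25 + 1e-9))
  expect_equal(stats::median(inner), 0.5)
  # empty segment set -> zero map
  dm0 <- vessel_density_map(make_segments(list(), dims), dims)
  expect_true(all(dm0$density == 0))
})

test_that("window counting equals a brute-force oracle", {
  set.seed(4)
  dims <- c(90, 90)
  segs <- lapply(1:25, function(i) {
    r0 <- sample(10:80, 1); c0 <- sample(10:80, 1)
    len <- sample(3:9, 1)
    if (stats::runif(1) < 0.5) cbind(r0:(min(90, r0 + len)), c0)
    else cbind(r0, c0:(min(90, c0 + len)))
  })
  ss <- make_segments(segs, dims)
  dm <- vessel_density_map(ss, dims, window_mm = 2, pixel_mm = 0.1)
  w <- 20; half <- floor(w / 2)
  for (r in seq(15, 75, by = 6)) for (c in seq(15, 75, by = 6)) {
    rows <- (r - half):(r + w - 1 - half)
    cols <- (c - half):(c + w - 1 - half)
    cnt <- sum(vapply(segs, function(s)
      any(s[, 1] >= rows[1] & s[, 1] <= rows[w] &
          s[, 2] >= cols[1] & s[, 2] <= cols[w]), logical(1)))
    expect_equal(dm$density[r, c], cnt / 4, info = paste(r, c))
  }
})

test_that("tumor segmentation applies the mean + k SD and 1855 px rules", {
  # constant map -> degenerate statistics, no regions
  dims <- c(100, 100)
  dm0 <- vessel_density_map(make_segments(list(), dims), dims)
  expect_warns(seg0 <- segment_tumors(dm0), "degenerate")
  expect_equal(nrow(seg0$regions), 0)
  # boundary behaviour at exactly 1855 pixels
  fake <- dm0
  n <- 300
  fake$density <- matrix(0, n, n)
  fake$support <- matrix(TRUE, n, n)
  rc <- expand.grid(r = 1:n, c = 1:n)
  d1 <- matrix((rc$r - 80)^2 + (rc$c - 80)^2, n, n)
  d2 <- matrix((rc$r - 220)^2 + (rc$c - 220)^2, n, n)
  fake$density[order(d1)[1:1854]] <- 10   # exactly 1854 px
  fake$density[order(d2)[1:1856]] <- 10   # exactly 1856 px
  fake$mean <- mean(fake$density); fake$sd <- stats::sd(fake$density)
  fake$pixel_mm <- 0.1
  seg <- segment_tumors(fake, k_sigma = 2, min_pixels = 1855)
  expect_equal(nrow(seg$regions), 1)
  expect_equal(seg$regions$pixels, 1856)
  # planted smooth bump: exactly one region centred within 1 mm
  bump <- dm0
  g <- matrix(exp(-(d1 / 2 / 25^2)), n, n)
  bump$density <- 0.2 + g
  bump$support <- matrix(TRUE, n, n)
  bump$mean <- mean(bump$density); bump$sd <- stats::sd(bump$density)
  bump$pixel_mm <- 0.1
  thr <- bump$mean + 2 * bump$sd
  expect_gt(max(bump$density), thr + 0.5 * bump$sd)  # supra-threshold core
  segb <- segment_tumors(bump, k_sigma = 2)
  expect_equal(nrow(segb$regions), 1)
  ctr_err <- sqrt((segb$regions$center_x - (80 - (n + 1) / 2) * 0.1)^2 +
                  (segb$regions$center_y - (80 - (n + 1) / 2) * 0.1)^2)
  expect_lt(ctr_err, 1)
  # monotone nesting in k: regions at larger k lie inside smaller-k regions
  labs <- lapply(c(1.5, 2.0, 2.5), function(k)
    segment_tumors(bump, k_sigma = k, min_pixels = 100)$labels > 0)
  expect_true(all(labs[[3]] <= labs[[2]]))
  expect_true(all(labs[[2]] <= labs[[1]]))
})

test_that("ROC sweep reproduces exact AUCs", {
  # perfectly separated ratios
  r <- density_ratio_and_roc(c(4, 4.5, 5, 2, 2.2, 2.4),
                             c(1, 1, 1, 0, 0, 0), k_sigma_options = 2)
  expect_equal(r$by_k[["2"]]$auc, 1.0)
  # concordant-pair (Mann-Whitney) counting oracle
  r2 <- density_ratio_and_roc(c(2.5, 3.5, 2.0, 3.0), c(1, 1, 0, 0),
                              k_sigma_options = 2)
  expect_equal(r2$by_k[["2"]]$auc, 0.75)
  # all equal ratios -> chance
  r3 <- density_ratio_and_roc(c(3, 3, 3, 3), c(1, 1, 0, 0), k_sigma_options = 2)
  expect_equal(r3$by_k[["2"]]$auc, 0.5)
  # random tie-free data equal the Mann-Whitney AUC exactly
  set.seed(8)
  ratios <- sample(seq(1.25, 5.75, by = 0.05), 14)  # distinct, > sweep step apart
  labels <- rep(c(TRUE, FALSE), 7)
  rr <- density_ratio_and_roc(ratios, labels, k_sigma_options = 2)
  mw <- mean(outer(ratios[labels], ratios[!labels], ">") +
               0.5 * outer(ratios[labels], ratios[!labels], "=="))
  expect_equal(rr$by_k[["2"]]$auc, mw, tolerance = 1e-12)
  expect_error(density_ratio_and_roc(c(1, 2), c(1, 1)), "both")
})

test_that("density ratio warns when no pixel is high-density", {
  dims <- c(100, 100)
  segs <- list(cbind(50, 40:60))
  dm <- vessel_density_map(make_segments(segs, dims), dims)
  dm$density <- matrix(1, 100, 100); dm$mean <- 1; dm$sd <- 0
  expect_warns(expect_true(is.na(density_ratio(dm))), "undefined")
})
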