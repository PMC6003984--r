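test_that("vesselness enhances tubes and segmentation removes lone pixels", {
  img <- matrix(0, 80, 80)
  img[38:43, 5:75] <- 1  # 6 px wide tube
  vs <- enhance_and_segment(img)
  on_tube <- mean(vs$response[40, 10:70])
  off_tube <- mean(vs$response[10, 10:70])
  expect_gt(on_tube, 5 * max(off_tube, 1e-6))
  expect_true(any(vs$mask[40, ]))
  # morphology invariant: no isolated single pixel survives in the mask,
  # even on a noisy slice
  set.seed(3)
  img2 <- img + matrix(stats::rnorm(80 * 80, sd = 0.08), 80, 80)
  m2 <- enhance_and_segment(img2)$mask
  nb <- matrix(0L, 80, 80)
  pm <- matrix(FALSE, 82, 82); pm[2:81, 2:81] <- m2
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + pm[2:81 + dr, 2:81 + dc]
  }
  expect_false(any(m2 & nb == 0))
  expect_true(any(m2[40, ]))
  # constant slice -> empty mask
  expect_false(any(enhance_and_segment(matrix(1, 50, 50))$mask))
  expect_false(any(enhance_and_segment(matrix(0, 50, 50))$mask))
})

test_that("depth encoding projects the brightest voxel's depth", {
  vol <- array(0, dim = c(20, 20, 5))
  vol[10, 10, 4] <- 2
  de <- depth_encode(vol, z_coords = c(0, 5, 10, 15, 20))
  expect_equal(de$depth_raw[10, 10], 15)
  expect_equal(de$map[10, 10], 2)
  expect_error(depth_encode(matrix(0, 5, 5)), "3D")
  # crossing vessels: the crossing pixel reports the brighter vessel's depth
  vol2 <- array(0, dim = c(21, 21, 8))
  vol2[11, , 2] <- 1.0   # bright vessel at depth index 2
  vol2[, 11, 6] <- 0.6   # dimmer vessel at depth index 6
  zc <- seq(0, 35, by = 5)
  de2 <- depth_encode(vol2, z_coords = zc)
  expect_equal(de2$depth[11, 11], zc[2])
  # a salt depth outlier is removed by the 3 x 3 median
  vol3 <- array(0, dim = c(15, 15, 3))
  vol3[, , 2] <- 1
  vol3[8, 8, 2] <- 0; vol3[8, 8, 3] <- 2   # one pixel peaks at another depth
  de3 <- depth_encode(vol3, z_coords = c(1, 2, 3))
  expect_equal(de3$depth[8, 8], 2)
})

test_that("skeletons split at junctions and drop short segments", {
  m <- matrix(FALSE, 20, 20)
  m[10, 2:19] <- TRUE
  ss <- skeleton_segments(m)
  expect_equal(length(ss$segments), 1)
  expect_equal(sum(ss$junctions), 0)
  # Y shape: three segments around a junction cluster
  y <- matrix(FALSE, 15, 15)
  y[8:14, 8] <- TRUE
  for (i in 0:6) { y[8 - i, 8 - i] <- TRUE; y[8 - i, 8 + i] <- TRUE }
  sy <- skeleton_segments(y)
  expect_equal(length(sy$segments), 3)
  expect_gte(sum(sy$junctions), 1)
  # a 2-px chain is dropped
  s2 <- matrix(FALSE, 10, 10)
  s2[5, 5:6] <- TRUE
  expect_equal(length(skeleton_segments(s2)$segments), 0)
  # empty mask
  expect_equal(length(skeleton_segments(matrix(FALSE, 5, 5))$segments), 0)
  # every segment pixel lies on the skeleton, which lies in the mask
  big <- matrix(FALSE, 40, 40)
  big[20, 5:35] <- TRUE; big[5:35, 20] <- TRUE
  sb <- skeleton_segments(big)
  for (seg in sb$segments) expect_true(all(big[seg]))
  # segment count is invariant under 90-degree rotation
  rot <- t(big)[, rev(seq_len(40))]
  expect_equal(length(skeleton_segments(rot)$segments), length(sb$segments))
})

test_that("junction metrics solve the exponent and the cube ratio", {
  j <- junction_metrics(1.2599, 1, 1)
  expect_equal(j$x_b, 3.0, tolerance = 1e-3)
  expect_equal(j$r_b, 1.0, tolerance = 1e-3)
  j2 <- junction_metrics(1.0, 0.8, 0.7)
  expect_equal(j2$x_b, 2.43, tolerance = 0.01)
  expect_equal(j2$r_b, 1 / (0.8^3 + 0.7^3))
  # exact R_B identity for diameters solving Murray's law
  d <- c(1.7, 1.2)
  dp <- (d[1]^3 + d[2]^3)^(1 / 3)
  expect_equal(junction_metrics(dp, d[1], d[2])$r_b, 1.0, tolerance = 1e-12)
  expect_error(junction_metrics(1.0, 1.0, 0.5), "parent diameter")
  expect_error(junction_metrics(-1, 0.5, 0.5), "positive")
})

test_that("template matching recovers simulated vessel diameters", {
  bank <- template_bank_small()
  # self-match: the 1.0 mm template scores ~1 at its own diameter
  tpl <- Filter(function(t) t$diameter == 1.0 && t$orientation == 0,
                bank$templates)[[1]]
  m <- measure_diameter(tpl$image, bank, max_shift = 2)
  expect_equal(m$diameter, 1.0, tolerance = 0.02)
  expect_gt(m$correlation, 0.999)
  # forward-model round trip at 1.4 mm
  img <- simulate_vessel_image(1.4)
  m2 <- measure_diameter(img, bank, max_shift = 2)
  expect_equal(m2$diameter, 1.4, tolerance = 0.1)
  # an out-of-range vessel cannot be matched and warns
  img3 <- simulate_vessel_image(3.0)
  expect_warns(measure_diameter(img3, bank, max_shift = 2),
               "outside|boundary")
})
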