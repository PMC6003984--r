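test_that("demons registration recovers planted smooth warps", {
  n <- 64
  tex <- speckle_texture(n, seed = 5)
  rc <- expand.grid(r = 1:n, c = 1:n)
  # identical frames -> zero displacement
  arr <- array(0, dim = c(12, n, n))
  for (f in 1:12) arr[f, , ] <- tex
  reg0 <- register_nonrigid(arr)
  expect_lt(max(abs(reg0$displacement)), 0.05)
  # planted smooth sinusoidal warp of 2 px amplitude, recovered within 0.5 px RMS
  ur <- 2 * sin(2 * pi * rc$r / n) * sin(pi * rc$c / n)
  uc <- 2 * cos(2 * pi * rc$c / n) * sin(pi * rc$r / n)
  arr2 <- arr
  warped <- matrix(ringpact:::cubic_sample(tex, rc$r - ur, rc$c - uc), n, n)
  for (f in 2:12) arr2[f, , ] <- warped
  reg2 <- register_nonrigid(arr2)
  err_r <- reg2$displacement[12, , , 1] - matrix(ur, n, n)
  err_c <- reg2$displacement[12, , , 2] - matrix(uc, n, n)
  inner <- as.matrix(expand.grid(8:(n - 7), 8:(n - 7)))
  expect_lt(sqrt(mean(err_r[inner]^2 + err_c[inner]^2)), 0.5)
  # a pure noise frame warns about convergence
  arr3 <- arr
  set.seed(2)
  arr3[6, , ] <- matrix(stats::rnorm(n * n, 0.5, 0.3), n, n)
  expect_warns(register_nonrigid(arr3), "did not converge")
  expect_error(register_nonrigid(arr[1:4, , ]), "10 frames")
})

test_that("stable triangulation tracks areas through rigid and affine motion", {
  n <- 80
  tex <- speckle_texture(n, seed = 6)
  # squares are 20 x 20 px for 2 mm at 0.1 mm pixels
  arr <- array(0, dim = c(12, n, n))
  for (f in 1:12) arr[f, , ] <- tex
  reg <- register_nonrigid(arr)
  tg <- stable_triangulation(reg, square_mm = 2.0, seed = 2)
  expect_equal(tg$ni, 4)  # 80 px / 20 px squares
  expect_gte(length(tg$triangles), 3)
  # with exact displacement fields, rigid translation leaves every triangle
  # area constant and uniform dilation scales each by (1 + eps)^2
  reg_syn <- reg
  for (f in 2:12) {
    reg_syn$displacement[f, , , 1] <- 1.5
    reg_syn$displacement[f, , , 2] <- -0.8
  }
  tg2 <- stable_triangulation(reg_syn, seed = 2)
  rel <- sweep(tg2$areas, 2, tg2$areas[1, ], "/") - 1
  expect_lt(max(abs(rel)), 1e-9)
  eps <- 0.01
  ctr <- (n + 1) / 2
  rc <- expand.grid(r = 1:n, c = 1:n)
  for (f in 2:12) {
    reg_syn$displacement[f, , , 1] <- matrix(eps * (rc$r - ctr), n, n)
    reg_syn$displacement[f, , , 2] <- matrix(eps * (rc$c - ctr), n, n)
  }
  tg3 <- stable_triangulation(reg_syn, seed = 2)
  growth <- tg3$areas[12, ] / tg3$areas[1, ] - 1
  expect_equal(mean(growth), (1 + eps)^2 - 1, tolerance = 1e-3)
  # demons-tracked rigid translation stays area-preserving to a few percent
  arr2 <- arr
  for (f in 2:12)
    arr2[f, , ] <- matrix(ringpact:::cubic_sample(tex, rc$r - 1.5, rc$c - 0.8), n, n)
  reg2 <- register_nonrigid(arr2)
  tg4 <- stable_triangulation(reg2, seed = 2)
  rel4 <- sweep(tg4$areas, 2, tg4$areas[1, ], "/") - 1
  expect_lt(stats::median(abs(rel4[12, ])), 0.05)
})

test_that("deformation maps are zero for static input and deterministic without noise", {
  n <- 80
  tex <- speckle_texture(n, seed = 7)
  arr <- array(0, dim = c(40, n, n))
  for (f in 1:40) arr[f, , ] <- tex
  fr <- structure(list(frames = arr, frame_rate = 10, pixel_size = 0.1),
                  class = "frame_sequence")
  reg <- register_nonrigid(fr)
  tg <- stable_triangulation(reg, seed = 1)
  dm <- suppressWarnings(deformation_map(tg, 0.25, n_realizations = 3, seed = 1))
  expect_lt(max(dm$map), 1e-3)
  expect_error(deformation_map(tg, compression_freq = 6), "Nyquist")
  # noise-free uniform compression: every realization paints the same
  # amplitude, so 1 vs many realizations agree on commonly covered pixels
  fc <- generate_dynamic_frames(tex, "compression", frequency = 0.25,
                                amplitude = 0.02, n_frames = 80,
                                noise_sd = 0, seed = 2)
  regc <- register_nonrigid(fc)
  tgc <- stable_triangulation(regc, seed = 3)
  d1 <- suppressWarnings(deformation_map(tgc, 0.25, n_realizations = 1, seed = 5))
  d5 <- suppressWarnings(deformation_map(tgc, 0.25, n_realizations = 5, seed = 5))
  both <- d1$coverage > 0 & d5$coverage == 1
  expect_gt(sum(both), 100)
  expect_lt(mean(abs(d1$map[both] - d5$map[both])), 0.1 * 0.02)
  # map amplitude is invariant under global intensity rescaling
  fc2 <- fc; fc2$frames <- fc$frames * 4
  regc2 <- register_nonrigid(fc2)
  tgc2 <- stable_triangulation(regc2, seed = 3)
  d2 <- suppressWarnings(deformation_map(tgc2, 0.25, n_realizations = 1, seed = 5))
  expect_lt(mean(abs(d2$map[both] - d1$map[both])), 0.1 * 0.02)
  # doubling the compression amplitude doubles the map
  fc3 <- generate_dynamic_frames(tex, "compression", frequency = 0.25,
                                 amplitude = 0.04, n_frames = 80,
                                 noise_sd = 0, seed = 2)
  regc3 <- register_nonrigid(fc3)
  tgc3 <- stable_triangulation(regc3, seed = 3)
  d3 <- suppressWarnings(deformation_map(tgc3, 0.25, n_realizations = 1, seed = 5))
  sel <- both & d3$coverage > 0
  expect_equal(mean(d3$map[sel]) / mean(d1$map[sel]), 2, tolerance = 0.05)
})
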