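test_that("measure_fwhm interpolates widths and rejects degenerate profiles", {
  x <- seq(-5, 5, by = 0.01)
  expect_equal(measure_fwhm(exp(-x^2 / 2), 0.01), 2 * sqrt(2 * log(2)),
               tolerance = 1e-3)
  expect_equal(measure_fwhm(c(0, 0, 0, 1, 0, 0, 0), 1), 1.0)
  expect_error(measure_fwhm(rep(1, 50)), "flat")
  expect_error(measure_fwhm(c(5, 4, 3, 2, 1, 0)), "boundary")
})

test_that("2D back-projection localizes sources and is linear", {
  tm <- transducer_model()
  geom <- array_geometry(n_elements = 128, element_pitch = 1.35)
  # all-zero sinogram reconstructs to all zeros
  zero <- simulate_sinogram(point_sources(numeric(0), numeric(0)), geom, tm)
  cfg <- recon_config(nx = 32, ny = 32, dx = 0.1, center = c(10, 0, 0))
  expect_true(all(reconstruct_2d(zero, cfg)$values == 0))
  # a point at (10, 0) peaks within one pixel of (10, 0)
  s <- simulate_sinogram(point_sources(10, 0), geom, tm, n_sub = 1)
  img <- reconstruct_2d(s, cfg)
  pk <- which(img$values == max(img$values), arr.ind = TRUE)[1, ]
  expect_lte(abs(img$x[pk[1]] - 10), 0.1)
  expect_lte(abs(img$y[pk[2]]), 0.1)
  # linearity: recon(a A + b B) = a recon(A) + b recon(B)
  s2 <- simulate_sinogram(point_sources(9.5, 0.5, amplitude = 2), geom, tm,
                          n_sub = 1)
  mix <- s
  mix$data <- 0.3 * s$data + 1.7 * s2$data
  im1 <- reconstruct_2d(s, cfg)$values
  im2 <- reconstruct_2d(s2, cfg)$values
  imx <- reconstruct_2d(mix, cfg)$values
  expect_lt(max(abs(imx - (0.3 * im1 + 1.7 * im2))) / max(abs(imx)), 1e-10)
})

test_that("rotating the source rotates the reconstructed peak", {
  tm <- transducer_model()
  geom <- array_geometry(n_elements = 128, element_pitch = 1.35)
  phi <- 2 * pi / geom$n_elements
  r0 <- 8
  cfg <- recon_config(nx = 64, ny = 64, dx = 0.1, center = c(r0, 0, 0))
  s1 <- simulate_sinogram(point_sources(r0, 0), geom, tm, n_sub = 1)
  im1 <- reconstruct_2d(s1, cfg)
  pk1 <- which(im1$values == max(im1$values), arr.ind = TRUE)[1, ]
  cfg2 <- recon_config(nx = 64, ny = 64, dx = 0.1,
                       center = c(r0 * cos(phi), r0 * sin(phi), 0))
  s2 <- simulate_sinogram(point_sources(r0 * cos(phi), r0 * sin(phi)), geom,
                          tm, n_sub = 1)
  im2 <- reconstruct_2d(s2, cfg2)
  pk2 <- which(im2$values == max(im2$values), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(pk1 - pk2)), 1)  # same grid-relative position +- 1 px
})

test_that("anti-aliasing bank matches the Nyquist cutoff rule", {
  # cutoff is non-increasing in radius and capped at the band edge
  r <- seq(0, 60, by = 1)
  fc <- nyquist_cutoff(r, 512, 1.5, 3.32)
  expect_true(all(diff(fc) <= 1e-12))
  expect_equal(fc[1], 3.32)
  expect_error(nyquist_cutoff(-1), "non-negative")
  # the spatially well-sampled (unfiltered) zone is ~39 mm across
  r0 <- 512 * 1.5 / (4 * pi * 3.32)
  expect_gt(2 * r0, 0.9 * 39)
  expect_lt(2 * r0, 1.1 * 39)
  # a pure tone above the local cutoff is attenuated by >= 20 dB
  tm <- transducer_model()
  geom <- array_geometry(n_elements = 64, element_pitch = 1.35)
  n <- tm$n_samples
  tone_f <- 3.0
  tone <- sin(2 * pi * tone_f * (0:(n - 1)) / tm$sampling_rate)
  sino <- structure(list(
    data = array(rep(tone, each = 64), dim = c(1, 64, n)),
    geometry = geom, transducer = tm, speed_of_sound = 1.5,
    noise_seed = NULL, directivity_model = "sinc"), class = "sinogram")
  bank <- antialias_lowpass(sino, r_max = 50, n_bins = 8)
  outer_bin <- length(bank$data)
  expect_lt(bank$cutoffs[outer_bin], tone_f)
  att <- max(abs(bank$data[[outer_bin]][1, 200:3800])) /
    max(abs(sino$data[1, 1, 200:3800]))
  expect_lt(att, 10^(-20 / 20))
  # innermost zone passes the data unfiltered
  expect_identical(bank$data[[1]], sino$data[1, , ])
})

test_that("3D mode validates its inputs", {
  tm <- transducer_model()
  geom1 <- array_geometry(n_elements = 64, element_pitch = 1.35)
  s1 <- simulate_sinogram(point_sources(0, 0), geom1, tm, n_sub = 1)
  expect_error(reconstruct_3d(s1, recon_config(nz = 5)), "reconstruct_2d")
  expect_error(reconstruct_2d(s1, recon_config(nz = 5)), "nz = 1")
  # zero scan reconstructs to a zero volume
  geom2 <- array_geometry(n_elements = 64, element_pitch = 1.35,
                          elevational_positions = c(-1, 0, 1))
  z <- simulate_sinogram(point_sources(numeric(0), numeric(0)), geom2, tm)
  vol <- reconstruct_3d(z, recon_config(nx = 8, ny = 8, nz = 5, dz = 0.5))
  expect_true(all(vol$values == 0))
})

test_that("elevational sensitivity profile distinguishes its two estimators", {
  sino <- scan_sinogram()
  div <- elevational_sensitivity_profile(sino, "divergence")
  expect_length(div, 31)
  expect_equal(which.max(div), 16)  # peak at the in-plane step
  expect_true(all(div >= 0))
})
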