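test_that("gen_irf produces a unit-area Gaussian peaked in the right channel", {
  irf <- gen_irf(irf_spec(center = 500, fwhm = 100), 4096, 7)
  # 0-based channel floor(500/7) = 71 -> 1-based 72
  expect_equal(which.max(irf$counts), 72L)
  expect_equal(sum(irf$counts), 1, tolerance = 1e-12)

  # count-weighted sd reproduces the Gaussian sigma = fwhm / (2 sqrt(2 ln 2))
  mu <- sum(irf$time * irf$counts)
  sdv <- sqrt(sum((irf$time - mu)^2 * irf$counts))
  expect_equal(sdv, 100 / (2 * sqrt(2 * log(2))), tolerance = 0.01)

  expect_error(gen_irf(irf_spec(fwhm = -5)), class = "lcophys_invalid_parameter")
  expect_error(gen_irf(irf_spec(), 4096, 0), class = "lcophys_invalid_parameter")
  expect_error(gen_irf(irf_spec(), 8, 7), class = "lcophys_invalid_parameter")
})

test_that("gen_decay: exponential identity, determinism, parameter checks", {
  # single component, delta IRF, no noise: ratio over one lifetime is e^-1
  d <- delta_irf(512, 10)
  tr <- gen_decay(decay_params(500, 100), d, peak_counts = 1e4, noise = FALSE)
  k <- 10
  expect_equal(tr$counts[k + 50] / tr$counts[k], exp(-1), tolerance = 1e-6)

  irf <- small_irf()
  p <- decay_params(c(332, 788), c(88, 12))
  expect_identical(gen_decay(p, irf, 1e4, seed = 7)$counts,
                   gen_decay(p, irf, 1e4, seed = 7)$counts)
  expect_false(identical(gen_decay(p, irf, 1e4, seed = 7)$counts,
                         gen_decay(p, irf, 1e4, seed = 8)$counts))

  expect_error(gen_decay(p, irf, peak_counts = 10),
               class = "lcophys_invalid_parameter")
  expect_error(decay_params(c(332, 788), c(88, 12, 5)),
               class = "lcophys_invalid_parameter")
})

test_that("gen_decay counts are Poisson around the analytic convolution curve", {
  irf <- small_irf(n_channels = 64, channel_width = 100)
  p <- decay_params(c(400, 900), c(60, 40), background = 2)
  expected <- gen_decay(p, irf, 500, noise = FALSE)$counts
  acc <- matrix(0, 200, 64)
  for (s in 1:200) acc[s, ] <- gen_decay(p, irf, 500, seed = s)$counts
  z <- (colMeans(acc) - expected) / sqrt(pmax(expected, 1e-9) / 200)
  expect_true(all(abs(z) < 4))
  expect_true(mean(abs(z) < 3) > 0.95)
})

test_that("gen_emission_spectrum: band placement, linearity, noise clipping", {
  s2 <- gen_emission_spectrum(list(c(540, 25, 1), c(580, 25, 0.8)))
  pk <- find_peaks(s2)
  expect_equal(pk$wavelength, c(540, 580))

  s1 <- gen_emission_spectrum(list(c(565, 30, 2)))
  expect_equal(s1$wavelength[which.max(s1$intensity)], 565)

  s1b <- gen_emission_spectrum(list(c(565, 30, 4)))
  expect_equal(s1b$intensity, 2 * s1$intensity, tolerance = 1e-12)

  noisy <- gen_emission_spectrum(list(c(565, 30, 0.01)), noise_sd = 0.5,
                                 seed = 3)
  expect_true(all(noisy$intensity >= 0))
  expect_identical(noisy$intensity,
                   gen_emission_spectrum(list(c(565, 30, 0.01)),
                                         noise_sd = 0.5, seed = 3)$intensity)
  expect_error(gen_emission_spectrum(list()),
               class = "lcophys_invalid_parameter")
})

test_that("gen_binding_dataset: zero-noise passthrough and zero-conc zero signal", {
  p <- binding_params(kd1 = 100, sites1 = 1000, qy_free = 0.06,
                      qy_site1 = 0.4, kd2 = 300, sites2 = 1000,
                      qy_site2 = 0.2)
  conc <- c(0, 100, 500, 1000, 2000, 4500)
  ds <- gen_binding_dataset(p, conc, noise_cv = 0, n_reps = 2, seed = 1)
  ref <- simulate_curve(p, conc)
  expect_equal(ds$signal[, 1], ref$signal[, 1], tolerance = 1e-12)
  expect_equal(ds$signal[, 2], ref$signal[, 1], tolerance = 1e-12)
  expect_equal(ds$signal[1, ], c(0, 0))
  expect_identical(gen_binding_dataset(p, conc, 0.05, 3, seed = 2)$signal,
                   gen_binding_dataset(p, conc, 0.05, 3, seed = 2)$signal)
  expect_error(gen_binding_dataset(p, conc, noise_cv = -0.1),
               class = "lcophys_invalid_parameter")
})

test_that("gen_flim_image respects regions and rejects overlapping masks", {
  irf <- gen_irf(irf_spec(500, 100), 128, 50)
  m1 <- matrix(FALSE, 10, 10); m1[1:5, ] <- TRUE
  m2 <- matrix(FALSE, 10, 10); m2[6:10, ] <- TRUE
  sc <- flim_scene(10, 10,
                   regions = list(
                     list(mask = m1, params = decay_params(700, 100)),
                     list(mask = m2, params = decay_params(1000, 100))),
                   photons_per_pixel = 2000,
                   n_channels = 128, channel_width = 50)
  img <- gen_flim_image(sc, irf, seed = 1)
  map <- pixel_lifetimes(img, min_photons = 100)
  expect_equal(mean(map$tau[m1]), 0.7, tolerance = 0.05)
  expect_equal(mean(map$tau[m2]), 1.0, tolerance = 0.05)
  expect_identical(gen_flim_image(sc, irf, seed = 4)$counts,
                   gen_flim_image(sc, irf, seed = 4)$counts)

  m_bad <- m2; m_bad[5, 1] <- TRUE
  expect_error(
    flim_scene(10, 10, regions = list(
      list(mask = m1, params = decay_params(700, 100)),
      list(mask = m_bad, params = decay_params(1000, 100))),
      photons_per_pixel = 2000, n_channels = 128, channel_width = 50),
    class = "lcophys_invalid_parameter")
})

test_that("zero-photon scenes give empty histograms and downstream errors", {
  irf <- gen_irf(irf_spec(500, 100), 64, 50)
  sc <- uniform_scene(800, side = 8, photons = 0, n_channels = 64,
                      channel_width = 50)
  img <- gen_flim_image(sc, irf, seed = 1)
  expect_true(all(img$counts == 0))
  map <- pixel_lifetimes(img, min_photons = 1)
  expect_true(all(is.na(map$tau)))
  expect_error(roi_histogram(map), class = "lcophys_insufficient_pixels")
})
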