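test_that("pixel_lifetimes: exact on noiseless exponentials, sentinels on dark pixels", {
  # one-pixel image with a pure exponential and delta excitation
  nc <- 512; dt <- 25
  tt <- (seq_len(nc) - 0.5) * dt
  counts <- array(0, dim = c(1, 1, nc))
  counts[1, 1, ] <- 1e4 * exp(-(seq_len(nc) - 1) * dt / 1000)
  img <- flim_image(counts, dt, irf = c(1, numeric(nc - 1)))
  map <- pixel_lifetimes(img, min_photons = 1)
  # exact up to the exponential tail truncated by the finite window
  expect_equal(map$tau[1, 1], 1.0, tolerance = 1e-4)

  dark <- flim_image(array(0, dim = c(2, 2, nc)), dt,
                     irf = c(1, numeric(nc - 1)))
  dm <- pixel_lifetimes(dark, min_photons = 1)
  expect_true(all(is.na(dm$tau)))

  no_irf <- flim_image(counts, dt)
  expect_error(pixel_lifetimes(no_irf), class = "lcophys_missing_irf")
  # explicit centroid override: the delta sits at the first bin centre
  expect_equal(pixel_lifetimes(no_irf, irf_centroid_ps = tt[1])$tau[1, 1],
               1.0, tolerance = 1e-4)
})

test_that("generated scenes round-trip through the lifetime map within 3%", {
  irf <- gen_irf(irf_spec(500, 100), 512, 25)
  means <- vapply(1:25, function(s) {
    sc <- uniform_scene(1000, side = 10, photons = 5000)
    mean(pixel_lifetimes(gen_flim_image(sc, irf, seed = s))$tau,
         na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(means), 1.0, tolerance = 0.03)
})

test_that("histogram mean bias shrinks as the photon budget grows", {
  irf <- gen_irf(irf_spec(500, 100), 512, 25)
  bias <- vapply(c(200, 1000, 5000), function(ph) {
    sc <- uniform_scene(1000, side = 16, photons = ph)
    m <- pixel_lifetimes(gen_flim_image(sc, irf, seed = 11),
                         min_photons = 50)
    abs(mean(m$tau, na.rm = TRUE) - 1.0)
  }, numeric(1))
  expect_lt(bias[3], 0.01)
  expect_true(bias[3] <= bias[1])
})

test_that("roi_histogram: normalization, ROI separation, mixture property", {
  irf <- gen_irf(irf_spec(500, 100), 512, 25)
  m1 <- matrix(FALSE, 40, 40); m1[, 1:20] <- TRUE
  m2 <- !m1
  sc <- flim_scene(40, 40,
                   regions = list(
                     list(mask = m1, params = decay_params(700, 100)),
                     list(mask = m2, params = decay_params(1000, 100))),
                   photons_per_pixel = 3000)
  map <- pixel_lifetimes(gen_flim_image(sc, irf, seed = 2))

  h1 <- roi_histogram(map, m1)
  h2 <- roi_histogram(map, m2)
  expect_equal(sum(h1$density) * h1$bin_width, 1, tolerance = 1e-9)
  expect_equal(sum(h2$density) * h2$bin_width, 1, tolerance = 1e-9)
  expect_equal(sum(h1$bin_centers * h1$density) * h1$bin_width, 0.7,
               tolerance = 0.05)
  expect_equal(sum(h2$bin_centers * h2$density) * h2$bin_width, 1.0,
               tolerance = 0.05)

  # union histogram is the pixel-count-weighted mixture of the parts
  hu <- roi_histogram(map, m1 | m2)
  dens_on <- function(h, centers) {
    out <- numeric(length(centers))
    idx <- match(floor(h$bin_centers / h$bin_width),
                 floor(centers / h$bin_width))
    out[idx] <- h$density
    out
  }
  mix <- (h1$n_pixels * dens_on(h1, hu$bin_centers) +
            h2$n_pixels * dens_on(h2, hu$bin_centers)) /
    (h1$n_pixels + h2$n_pixels)
  expect_equal(hu$density, mix, tolerance = 1e-9)

  # two disjoint ROIs over a homogeneous map agree in distribution
  schom <- uniform_scene(1000, side = 50, photons = 2000)
  mhom <- pixel_lifetimes(gen_flim_image(schom, irf, seed = 3),
                          min_photons = 50)
  a <- matrix(FALSE, 50, 50); a[, 1:25] <- TRUE
  va <- mhom$tau[a]; vb <- mhom$tau[!a]
  ks <- suppressWarnings(stats::ks.test(va[!is.na(va)], vb[!is.na(vb)]))
  expect_lt(unname(ks$statistic), 0.1)

  expect_error(roi_histogram(map, m1[1:10, 1:10]),
               class = "lcophys_invalid_parameter")
})

test_that("identical lifetimes collapse to one occupied bin with moment fallback", {
  map <- structure(list(tau = matrix(0.8, 10, 10),
                        photon_count = matrix(1000, 10, 10),
                        min_photons = 100),
                   class = "lifetime_map")
  h <- roi_histogram(map)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(sum(h$density) * h$bin_width, 1, tolerance = 1e-9)
  g <- fit_gaussian(h)
  expect_true(g$fallback)
  expect_equal(g$center, h$bin_centers[h$counts > 0], tolerance = 1e-9)
})

test_that("fit_gaussian recovers center and width from exact Gaussian samples", {
  # narrow homogeneous-fibril regime: center 1.0 ns, sigma 0.051 ns
  vals <- with(list(n = 1e4), {
    set.seed(21); stats::rnorm(n, 1.0, 0.051)
  })
  map <- structure(list(tau = matrix(vals, 100, 100),
                        photon_count = matrix(1e4, 100, 100),
                        min_photons = 100),
                   class = "lifetime_map")
  g <- fit_gaussian(roi_histogram(map))
  expect_equal(g$center, 1.0, tolerance = 0.005)
  expect_equal(g$fwhm, 2 * sqrt(2 * log(2)) * 0.051, tolerance = 0.05)
  expect_equal(g$fwhm, 2 * sqrt(2 * log(2)) * g$sigma, tolerance = 1e-12)
  expect_false(g$fallback)

  # center recovery across the aggregate regimes 0.7 / 0.86 / 1.0 ns
  for (ctr in c(0.7, 0.86, 1.0)) {
    set.seed(round(1000 * ctr))
    v <- stats::rnorm(1e4, ctr, 0.051)
    mp <- structure(list(tau = matrix(v, 100, 100),
                         photon_count = matrix(1e4, 100, 100),
                         min_photons = 100),
                    class = "lifetime_map")
    gg <- fit_gaussian(roi_histogram(mp))
    expect_equal(gg$center, ctr, tolerance = 0.02 * ctr)
  }
})

test_that("Gaussian-fit center is stable under bin-width halving", {
  set.seed(33)
  v <- stats::rnorm(1e4, 0.9, 0.08)
  mp <- structure(list(tau = matrix(v, 100, 100),
                       photon_count = matrix(1e4, 100, 100),
                       min_photons = 100),
                  class = "lifetime_map")
  g1 <- fit_gaussian(roi_histogram(mp, bin_width = 0.02))
  g2 <- fit_gaussian(roi_histogram(mp, bin_width = 0.01))
  expect_equal(g1$center, g2$center, tolerance = 0.01)
})

test_that("render_false_color maps, clips and inverts within one LUT step", {
  tau <- matrix(c(1.0, 1.0, -5, 7, NA, 0.31), 2, 3)
  map <- structure(list(tau = tau, photon_count = matrix(1e3, 2, 3),
                        min_photons = 100),
                   class = "lifetime_map")
  img <- render_false_color(map, range = c(0, 2))
  lut <- attr(img, "colormap")
  rgb_lut <- t(grDevices::col2rgb(lut)) / 255

  # midpoint of the range renders the mid-colormap color
  mid <- rgb_lut[129, ]
  expect_equal(as.numeric(img[1, 1, ]), as.numeric(mid), tolerance = 1e-9)
  # out-of-range values clip to the endpoints
  expect_equal(as.numeric(img[1, 2, ]), as.numeric(rgb_lut[1, ]))
  expect_equal(as.numeric(img[2, 2, ]), as.numeric(rgb_lut[256, ]))
  # undefined pixels are black
  expect_equal(as.numeric(img[1, 3, ]), c(0, 0, 0))

  # inverse lookup recovers the lifetime within one quantization step
  px <- as.numeric(img[2, 3, ])
  idx <- which.min(colSums((t(rgb_lut) - px)^2))
  tau_back <- (idx - 1) / 255 * 2
  expect_lt(abs(tau_back - 0.31), 2 / 255 + 1e-9)

  expect_error(render_false_color(map, range = c(2, 1)),
               class = "lcophys_invalid_parameter")
})
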