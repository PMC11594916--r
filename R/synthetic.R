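#' Instrument response function specification
#'
#' @param center IRF centre in ps.
#' @param fwhm full width at half maximum in ps, > 0.
#' @param shape only `"gaussian"` is supported.
#' @return object of class `irf_spec`.
#' @export
irf_spec <- function(center = 500, fwhm = 100, shape = "gaussian") {
  check_that(is.numeric(fwhm) && length(fwhm) == 1 && is.finite(fwhm) &&
               fwhm > 0,
             "invalid_parameter", "`fwhm` must be a positive width in ps")
  check_that(is.numeric(center) && length(center) == 1 && is.finite(center),
             "invalid_parameter", "`center` must be a single ps value")
  check_that(identical(shape, "gaussian"), "invalid_parameter",
             "only the gaussian IRF shape is supported")
  structure(list(center = center, fwhm = fwhm, shape = shape),
            class = "irf_spec")
}

#' Generate a noiseless discretized IRF
#'
#' Gaussian IRF sampled at the channel bin centres and normalized to unit
#' total, so convolution with it preserves total intensity.
#'
#' @param spec an [irf_spec].
#' @param n_channels number of channels, >= 16.
#' @param channel_width channel width in ps, > 0.
#' @return a [decay_trace] whose `counts` hold the unit-area IRF.
#' @export
gen_irf <- function(spec = irf_spec(), n_channels = 4096, channel_width = 7) {
  check_that(inherits(spec, "irf_spec"), "invalid_parameter",
             "`spec` must be an irf_spec")
  check_that(is.numeric(channel_width) && channel_width > 0,
             "invalid_parameter", "`channel_width` must be > 0")
  check_that(n_channels >= 16, "invalid_parameter",
             "`n_channels` must be >= 16")
  tt <- channel_times(n_channels, channel_width)
  sigma <- spec$fwhm / FWHM_SIGMA
  v <- exp(-(tt - spec$center)^2 / (2 * sigma^2))
  check_that(sum(v) > 0, "invalid_parameter",
             "IRF centre falls outside the channel window")
  decay_trace(tt, v / sum(v), meta = list(kind = "irf", fwhm = spec$fwhm,
                                          center = spec$center))
}

#' Simulate a Poisson TCSPC decay
#'
#' The expected (pre-noise) curve is the discrete convolution of the IRF
#' with \eqn{\sum_i (B_i/100)\,e^{-t/\tau_i}}, rescaled so its maximum
#' equals `peak_counts`, plus the model background; observed counts are
#' independent Poisson draws per channel (photon counting statistics).
#'
#' @param params a [decay_params].
#' @param irf a [decay_trace] from [gen_irf] (its grid defines the
#'   channels).
#' @param peak_counts expected counts in the peak channel, >= 100.
#' @param seed RNG seed (ignored when `noise = FALSE`).
#' @param noise draw Poisson noise (default `TRUE`); `FALSE` returns the
#'   expected curve itself.
#' @return a [decay_trace] carrying the IRF and, in `meta$expected`, the
#'   noiseless curve.
#' @export
gen_decay <- function(params, irf, peak_counts = 1e4, seed = 1,
                      noise = TRUE) {
  check_that(inherits(params, "decay_params"), "invalid_parameter",
             "`params` must be a decay_params")
  check_that(inherits(irf, "decay_trace"), "invalid_parameter",
             "`irf` must be a decay_trace (see gen_irf)")
  check_that(peak_counts >= 100, "invalid_parameter",
             "`peak_counts` must be >= 100")
  no_bg <- structure(list(tau = params$tau, amp = params$amp,
                          background = 0), class = "decay_params")
  m <- convolve_model(irf$counts, no_bg, irf$time)
  expected <- m * (peak_counts / max(m)) + params$background
  counts <- if (noise) {
    with_seed(seed, stats::rpois(length(expected), expected))
  } else {
    expected
  }
  decay_trace(irf$time, counts, irf = irf$counts,
              meta = list(expected = expected, seed = if (noise) seed,
                          truth = params))
}

#' Simulate a plate-reader emission spectrum
#'
#' Sum of Gaussian emission bands on a wavelength grid plus additive
#' Gaussian noise; negative draws are clipped at 0 (intensities are
#' non-negative).
#'
#' @param bands list of `c(center_nm, fwhm_nm, amplitude)` triplets.
#' @param grid `c(start, stop, step)` in nm (default `c(500, 700, 5)`,
#'   the plate-reader emission window).
#' @param noise_sd additive noise standard deviation (intensity units).
#' @param seed RNG seed (used when `noise_sd > 0`).
#' @return a [spectrum].
#' @export
gen_emission_spectrum <- function(bands, grid = c(500, 700, 5),
                                  noise_sd = 0, seed = 1) {
  check_that(is.list(bands) && length(bands) >= 1, "invalid_parameter",
             "`bands` must be a non-empty list of (center, fwhm, amplitude)")
  check_that(length(grid) == 3 && grid[3] > 0 && grid[2] > grid[1],
             "invalid_parameter", "`grid` must be c(start, stop, step>0)")
  check_that(noise_sd >= 0, "invalid_parameter", "`noise_sd` must be >= 0")
  w <- seq(grid[1], grid[2], by = grid[3])
  v <- numeric(length(w))
  for (b in bands) {
    check_that(is.numeric(b) && length(b) == 3 && b[2] > 0,
               "invalid_parameter",
               "each band must be c(center_nm, fwhm_nm > 0, amplitude)")
    sigma <- b[2] / FWHM_SIGMA
    v <- v + b[3] * exp(-(w - b[1])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) {
    v <- with_seed(seed, v + stats::rnorm(length(v), 0, noise_sd))
    v <- pmax(v, 0)
  }
  spectrum(w, v, meta = list(bands = bands, noise_sd = noise_sd))
}

#' Simulate a binding titration with multiplicative noise
#'
#' Each replicate is the deterministic model signal from
#' [simulate_curve] times \eqn{(1 + \epsilon)},
#' \eqn{\epsilon \sim N(0, \mathrm{CV})} — plate-reader error scales with
#' signal. The matching ligand-only series is included noise-free.
#'
#' @param params a [binding_params].
#' @param conc_series total-ligand concentrations (nM).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_reps number of replicates, >= 1.
#' @param seed RNG seed.
#' @return a [binding_dataset] with an `n_reps`-column signal matrix.
#' @export
gen_binding_dataset <- function(params, conc_series, noise_cv = 0.05,
                                n_reps = 3, seed = 1) {
  check_that(is.numeric(noise_cv) && noise_cv >= 0, "invalid_parameter",
             "`noise_cv` must be >= 0")
  check_that(n_reps >= 1, "invalid_parameter", "`n_reps` must be >= 1")
  base <- simulate_curve(params, conc_series)
  mu <- base$signal[, 1]
  sig <- if (noise_cv > 0) {
    with_seed(seed, {
      eps <- matrix(stats::rnorm(length(mu) * n_reps, 0, noise_cv),
                    nrow = length(mu))
      mu * (1 + eps)
    })
  } else {
    matrix(rep(mu, n_reps), ncol = n_reps)
  }
  binding_dataset(conc_series, sig, base$ligand_only_signal,
                  params$sites1)
}

#' Synthetic FLIM scene description
#'
#' @param width,height image size in pixels.
#' @param regions list of regions, each a list with `mask` (logical
#'   matrix `height x width`), `params` (a [decay_params]) and optional
#'   `tau_jitter_sd` (ps): Gaussian pixel-to-pixel dispersion added to
#'   every component lifetime, emulating heterogeneous binding
#'   environments. Region masks must be pairwise disjoint.
#' @param photons_per_pixel expected photons per in-region pixel; 0 gives
#'   empty histograms (useful for degenerate-input tests).
#' @param n_channels,channel_width channel grid (default 512 x 25 ps).
#' @return object of class `flim_scene`.
#' @export
flim_scene <- function(width, height, regions, photons_per_pixel = 5000,
                       n_channels = 512, channel_width = 25) {
  check_that(width >= 1 && height >= 1, "invalid_parameter",
             "image must have positive dimensions")
  check_that(photons_per_pixel >= 0, "invalid_parameter",
             "`photons_per_pixel` must be >= 0")
  check_that(is.list(regions) && length(regions) >= 1, "invalid_parameter",
             "`regions` must be a non-empty list")
  cover <- matrix(0L, height, width)
  for (r in regions) {
    check_that(is.list(r) && !is.null(r$mask) && !is.null(r$params) &&
                 inherits(r$params, "decay_params") &&
                 all(dim(r$mask) == c(height, width)),
               "invalid_parameter",
               "each region needs a height x width mask and decay_params")
    cover <- cover + (as.logical(r$mask) * 1L)
  }
  check_that(all(cover <= 1L), "invalid_parameter",
             "region masks overlap; they must be disjoint")
  structure(list(width = width, height = height, regions = regions,
                 photons_per_pixel = photons_per_pixel,
                 n_channels = n_channels, channel_width = channel_width),
            class = "flim_scene")
}

#' Simulate a FLIM image
#'
#' Per-pixel photon totals are Poisson-distributed around
#' `photons_per_pixel`; given its total, a pixel's arrival histogram is a
#' multinomial draw from the IRF-convolved decay of its region (so each
#' channel count is Poisson, as in [gen_decay]). With `tau_jitter_sd > 0`
#' the component lifetimes get an independent Gaussian perturbation per
#' pixel. Pixels outside all regions carry background counts only.
#'
#' @param scene a [flim_scene].
#' @param irf a [decay_trace] IRF; its grid must match the scene's
#'   channel grid.
#' @param seed RNG seed.
#' @return a [flim_image] with the IRF attached.
#' @export
gen_flim_image <- function(scene, irf, seed = 1) {
  check_that(inherits(scene, "flim_scene"), "invalid_parameter",
             "`scene` must be a flim_scene")
  check_that(inherits(irf, "decay_trace") &&
               length(irf$time) == scene$n_channels &&
               isTRUE(all.equal(grid_step(irf$time), scene$channel_width,
                                tolerance = 1e-9)),
             "invalid_parameter",
             "IRF grid must match the scene's channel grid")
  nc <- scene$n_channels
  counts <- array(0, dim = c(scene$height, scene$width, nc))
  with_seed(seed, {
    for (r in scene$regions) {
      pix <- which(as.logical(r$mask))
      if (length(pix) == 0) next
      jit <- if (!is.null(r$tau_jitter_sd)) r$tau_jitter_sd else 0
      base <- r$params
      no_bg <- structure(list(tau = base$tau, amp = base$amp,
                              background = 0), class = "decay_params")
      prob0 <- NULL
      if (jit == 0) {
        m <- convolve_model(irf$counts, no_bg, irf$time)
        prob0 <- m / sum(m)
      }
      n_tot <- stats::rpois(length(pix), scene$photons_per_pixel)
      bgl <- base$background
      for (k in seq_along(pix)) {
        prob <- prob0
        if (is.null(prob)) {
          tau_k <- pmax(base$tau + stats::rnorm(length(base$tau), 0, jit), 1)
          pk <- structure(list(tau = tau_k, amp = base$amp, background = 0),
                          class = "decay_params")
          m <- convolve_model(irf$counts, pk, irf$time)
          prob <- m / sum(m)
        }
        h <- if (n_tot[k] > 0) {
          as.numeric(stats::rmultinom(1, n_tot[k], prob))
        } else {
          numeric(nc)
        }
        if (bgl > 0) h <- h + stats::rpois(nc, bgl)
        ij <- arrayInd(pix[k], dim(r$mask))
        counts[ij[1], ij[2], ] <- h
      }
    }
    ## background-only pixels outside all regions
    bg_out <- max(vapply(scene$regions,
                         function(r) r$params$background, numeric(1)))
    outside <- matrix(TRUE, scene$height, scene$width)
    for (r in scene$regions) outside <- outside & !as.logical(r$mask)
    if (bg_out > 0 && any(outside)) {
      pix <- which(outside)
      for (k in seq_along(pix)) {
        ij <- arrayInd(pix[k], dim(outside))
        counts[ij[1], ij[2], ] <- stats::rpois(nc, bg_out)
      }
    }
  })
  flim_image(counts, scene$channel_width, irf = irf$counts,
             meta = list(seed = seed))
}
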