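#' FLIM image: per-pixel photon-arrival histograms
#'
#' @param counts 3-D array `[height, width, n_channels]` of non-negative
#'   photon counts; every pixel shares one channel grid.
#' @param channel_width channel width in ps.
#' @param irf optional shared IRF (length `n_channels`).
#' @param meta named list (excitation nm, repetition rate MHz, ...).
#' @return object of class `flim_image`. Channel times are bin centres
#'   `(k - 1/2) * channel_width`.
#' @export
flim_image <- function(counts, channel_width, irf = NULL, meta = list()) {
  check_that(is.array(counts) && length(dim(counts)) == 3,
             "invalid_parameter",
             "`counts` must be a [height, width, channels] array")
  check_that(all(counts >= 0), "invalid_parameter",
             "photon counts must be non-negative")
  check_that(is.numeric(channel_width) && channel_width > 0,
             "invalid_parameter", "`channel_width` must be > 0")
  if (!is.null(irf)) {
    check_that(length(irf) == dim(counts)[3] && all(irf >= 0),
               "invalid_parameter",
               "`irf` must be non-negative with one value per channel")
  }
  structure(list(counts = counts, channel_width = channel_width,
                 irf = if (!is.null(irf)) as.numeric(irf), meta = meta),
            class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_image> %d x %d pixels, %d channels x %g ps%s\n",
              d[1], d[2], d[3], x$channel_width,
              if (is.null(x$irf)) "" else ", IRF attached"))
  invisible(x)
}

channel_times <- function(n, dt) (seq_len(n) - 0.5) * dt

centroid_time <- function(values, times) {
  sum(times * values) / sum(values)
}

#' Per-pixel fast lifetimes
#'
#' Estimates each pixel's lifetime as the mean photon arrival time minus
#' the IRF centroid (the "fast" or centroid lifetime, photon-efficient at
#' low counts), then inverts the discrete-geometric mean of an exponential
#' sampled on a uniform grid, \eqn{m = \Delta/(e^{\Delta/\tau} - 1)}, i.e.
#' \eqn{\tau = \Delta/\log(1 + \Delta/m)}, which removes the
#' \eqn{\approx \Delta/2} channel-discretization bias. Pixels with fewer
#' than `min_photons` counts are marked undefined (`NA`).
#'
#' @param img a [flim_image]; must carry an IRF unless `irf_centroid_ps`
#'   supplies the centroid explicitly (use 0 for delta excitation at the
#'   first channel edge).
#' @param min_photons minimum photons per pixel (default 100).
#' @param irf_centroid_ps optional explicit IRF centroid (ps).
#' @return object of class `lifetime_map`: `tau` matrix (ns; `NA` where
#'   undefined), `photon_count` matrix, `min_photons`.
#' @export
pixel_lifetimes <- function(img, min_photons = 100, irf_centroid_ps = NULL) {
  check_that(inherits(img, "flim_image"), "invalid_parameter",
             "`img` must be a flim_image")
  check_that(min_photons >= 1, "invalid_parameter",
             "`min_photons` must be >= 1")
  d <- dim(img$counts)
  dt <- img$channel_width
  tt <- channel_times(d[3], dt)
  if (is.null(irf_centroid_ps)) {
    check_that(!is.null(img$irf) && sum(img$irf) > 0, "missing_irf",
               "no IRF in image and no explicit `irf_centroid_ps` given")
    irf_centroid_ps <- centroid_time(img$irf, tt)
  }
  flat <- matrix(img$counts, nrow = d[1] * d[2], ncol = d[3])
  nph <- rowSums(flat)
  mean_t <- as.vector(flat %*% tt) / nph
  m <- mean_t - irf_centroid_ps
  tau_ps <- ifelse(m > 0, dt / log1p(dt / m), NA_real_)
  tau_ps[nph < min_photons] <- NA_real_
  structure(
    list(tau = matrix(tau_ps / 1000, d[1], d[2]),
         photon_count = matrix(nph, d[1], d[2]),
         min_photons = min_photons),
    class = "lifetime_map"
  )
}

#' @export
print.lifetime_map <- function(x, ...) {
  ok <- sum(!is.na(x$tau))
  cat(sprintf("<lifetime_map> %d x %d pixels, %d defined (>= %g photons)\n",
              nrow(x$tau), ncol(x$tau), ok, x$min_photons))
  if (ok > 0) {
    cat(sprintf("  lifetime %.3g-%.3g ns (mean %.3g ns)\n",
                min(x$tau, na.rm = TRUE), max(x$tau, na.rm = TRUE),
                mean(x$tau, na.rm = TRUE)))
  }
  invisible(x)
}

#' ROI lifetime distribution
#'
#' Area-normalized histogram of the defined pixel lifetimes inside a
#' binary region-of-interest mask, on uniform bins of width `bin_width`
#' ns. The density integrates to 1 so that distributions from ROIs of
#' different size are comparable.
#'
#' @param map a [lifetime_map].
#' @param mask logical (or 0/1) matrix of the same shape; `NULL` selects
#'   the whole image.
#' @param bin_width histogram bin width in ns (default 0.02).
#' @return object of class `lifetime_dist`: `bin_centers` (ns), `density`
#'   (1/ns, area 1), `counts`, `n_pixels`, `bin_width`.
#' @export
roi_histogram <- function(map, mask = NULL, bin_width = 0.02) {
  check_that(inherits(map, "lifetime_map"), "invalid_parameter",
             "`map` must be a lifetime_map")
  check_that(bin_width > 0, "invalid_parameter", "`bin_width` must be > 0")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(map$tau), ncol(map$tau))
  check_that(all(dim(mask) == dim(map$tau)), "invalid_parameter",
             "mask shape must equal map shape")
  vals <- map$tau[as.logical(mask)]
  vals <- vals[!is.na(vals)]
  check_that(length(vals) >= 50, "insufficient_pixels",
             sprintf("only %d defined pixels in ROI; >= 50 required",
                     length(vals)))
  lo <- floor(min(vals) / bin_width) * bin_width
  hi <- ceiling(max(vals) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  cts <- tabulate(findInterval(vals, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1)
  structure(
    list(bin_centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
         density = cts / (length(vals) * bin_width),
         counts = cts, n_pixels = length(vals), bin_width = bin_width),
    class = "lifetime_dist"
  )
}

#' @export
print.lifetime_dist <- function(x, ...) {
  cat(sprintf("<lifetime_dist> %d pixels in %d bins of %g ns\n",
              x$n_pixels, length(x$bin_centers), x$bin_width))
  invisible(x)
}

#' Gaussian fit of an ROI lifetime distribution
#'
#' Least-squares fit of \eqn{A\,e^{-(t - \mu)^2 / 2\sigma^2}} to the
#' histogram density; the centre \eqn{\mu} summarizes the ROI lifetime
#' and the width is reported both as \eqn{\sigma} and as
#' FWHM = \eqn{2\sqrt{2\ln 2}\,\sigma}. On non-convergence (or fewer than
#' 5 occupied bins available for the moment path via `allow_fallback`),
#' a moment-based fallback (weighted mean and sd) is returned with
#' `fallback = TRUE`.
#'
#' @param dist a [lifetime_dist] with >= 5 occupied bins (fewer occupied
#'   bins triggers the moment fallback rather than a fit).
#' @return object of class `gaussian_fit`: `center` (ns), `sigma`,
#'   `fwhm`, `amplitude`, `stderr` (named: center, sigma, fwhm,
#'   amplitude), `fallback`, `converged`.
#' @export
fit_gaussian <- function(dist) {
  check_that(inherits(dist, "lifetime_dist"), "invalid_parameter",
             "`dist` must be a lifetime_dist")
  x <- dist$bin_centers
  y <- dist$density
  occupied <- sum(y > 0)
  w_mean <- sum(x * y) / sum(y)
  w_sd <- sqrt(max(sum((x - w_mean)^2 * y) / sum(y), 0))
  fallback <- function(msg) {
    structure(
      list(center = w_mean, sigma = w_sd, fwhm = FWHM_SIGMA * w_sd,
           amplitude = max(y),
           stderr = c(center = NA_real_, sigma = NA_real_,
                      fwhm = NA_real_, amplitude = NA_real_),
           fallback = TRUE, converged = FALSE, note = msg),
      class = "gaussian_fit")
  }
  if (occupied < 5) {
    return(fallback("fewer than 5 occupied bins; moment estimates reported"))
  }
  p0 <- c(amp = max(y), mu = w_mean, lsig = log(max(w_sd, dist$bin_width / 2)))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0,
      fn = function(p) {
        p[["amp"]] * exp(-(x - p[["mu"]])^2 / (2 * exp(2 * p[["lsig"]]))) - y
      },
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4) || !all(is.finite(fit$par))) {
    return(fallback("Gaussian fit failed to converge; moment fallback"))
  }
  sigma <- exp(fit$par[["lsig"]])
  dof <- max(length(y) - 3, 1)
  s2 <- fit$deviance / dof
  se <- rep(NA_real_, 3)
  cov <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
    se <- unname(sqrt(diag(cov)))
  }
  structure(
    list(center = fit$par[["mu"]], sigma = sigma,
         fwhm = FWHM_SIGMA * sigma, amplitude = fit$par[["amp"]],
         stderr = c(center = se[2], sigma = se[3] * sigma,
                    fwhm = FWHM_SIGMA * se[3] * sigma, amplitude = se[1]),
         fallback = FALSE, converged = fit$info %in% 1:3),
    class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> center %.4g +/- %.2g ns, FWHM %.3g ns%s\n",
              x$center, x$stderr[["center"]], x$fwhm,
              if (x$fallback) " (moment fallback)" else ""))
  invisible(x)
}

#' Render a false-color lifetime map
#'
#' Lifetimes are linearly mapped onto a perceptually uniform colormap
#' (viridis by default) over `range` ns, clipping values outside the
#' range to the endpoints. Undefined pixels render black. The mapping is
#' deterministic and invertible up to one colormap quantization step.
#'
#' @param map a [lifetime_map].
#' @param range `c(lo, hi)` ns display range (default `c(0, 2)`).
#' @param n_colors colormap resolution (default 256).
#' @param palette palette name passed to [grDevices::hcl.colors].
#' @return `[height, width, 3]` RGB array in `[0, 1]` with attributes
#'   `colormap` (the hex LUT) and `range`.
#' @export
render_false_color <- function(map, range = c(0, 2), n_colors = 256,
                               palette = "viridis") {
  check_that(inherits(map, "lifetime_map"), "invalid_parameter",
             "`map` must be a lifetime_map")
  check_that(length(range) == 2 && range[1] < range[2],
             "invalid_parameter", "`range` must be c(lo, hi), lo < hi")
  lut <- grDevices::hcl.colors(n_colors, palette)
  rgb_lut <- t(grDevices::col2rgb(lut)) / 255
  tau <- map$tau
  frac <- (tau - range[1]) / (range[2] - range[1])
  frac <- pmin(pmax(frac, 0), 1)
  idx <- 1L + as.integer(round(frac * (n_colors - 1)))
  out <- array(0, dim = c(nrow(tau), ncol(tau), 3))
  defined <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(tau), ncol(tau))
    plane[defined] <- rgb_lut[idx[defined], ch]
    out[, , ch] <- plane
  }
  attr(out, "colormap") <- lut
  attr(out, "range") <- range
  out
}
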