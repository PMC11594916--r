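#' Emission/excitation spectrum
#'
#' @param wavelength nm grid, strictly increasing.
#' @param intensity intensities (arbitrary units), same length.
#' @param meta named list (excitation nm, sample label, ROI id, ...).
#' @return object of class `spectrum`.
#' @export
spectrum <- function(wavelength, intensity, meta = list()) {
  check_that(is.numeric(wavelength) && length(wavelength) >= 2 &&
               all(diff(wavelength) > 0),
             "invalid_parameter", "`wavelength` must be strictly increasing")
  check_that(is.numeric(intensity) && length(intensity) == length(wavelength),
             "invalid_parameter",
             "`intensity` must match `wavelength` in length")
  structure(list(wavelength = as.numeric(wavelength),
                 intensity = as.numeric(intensity), meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %g-%g nm\n", length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$wavelength) == length(b$wavelength) &&
    isTRUE(all.equal(a$wavelength, b$wavelength, tolerance = 1e-12))
}

#' Subtract a blank spectrum
#'
#' Pointwise subtraction of a buffer/blank spectrum measured on the same
#' wavelength grid (no silent interpolation). Negative differences are
#' floored at 0 by default because downstream area normalization requires
#' non-negative mass; set `floor = FALSE` to keep raw differences.
#'
#' @param sample,blank [spectrum] objects on identical grids.
#' @param floor floor negative differences at zero (default `TRUE`).
#' @return blank-corrected [spectrum]; `meta$blank` records the blank label.
#' @export
subtract_blank <- function(sample, blank, floor = TRUE) {
  check_that(inherits(sample, "spectrum") && inherits(blank, "spectrum"),
             "invalid_parameter", "inputs must be spectrum objects")
  check_that(same_grid(sample, blank), "grid_mismatch",
             "sample and blank wavelength grids differ")
  v <- sample$intensity - blank$intensity
  if (floor) v <- pmax(v, 0)
  meta <- sample$meta
  meta$blank <- if (!is.null(blank$meta$label)) blank$meta$label else "blank"
  spectrum(sample$wavelength, v, meta)
}

trapz_ <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Normalize a spectrum to unit area
#'
#' Divides intensities by the trapezoidal integral over the full grid so
#' that the spectrum integrates to 1. Used to compare spectral shape across
#' regions of interest independently of brightness.
#'
#' @param s a [spectrum].
#' @return area-normalized [spectrum].
#' @export
area_normalize <- function(s) {
  check_that(inherits(s, "spectrum"), "invalid_parameter",
             "`s` must be a spectrum")
  a <- trapz_(s$wavelength, s$intensity)
  check_that(is.finite(a) && a > 0, "degenerate_spectrum",
             "spectrum has non-positive total area; cannot normalize")
  spectrum(s$wavelength, s$intensity / a, s$meta)
}

#' Integrate a spectrum over a wavelength range
#'
#' Trapezoidal integral on the native grid, clipped to `range`. Partial
#' edge intervals are included by linear interpolation at the range
#' endpoints.
#'
#' @param s a [spectrum].
#' @param range `c(lo, hi)` in nm; default full grid.
#' @return scalar integral (intensity x nm).
#' @export
integrate_spectrum <- function(s, range = NULL) {
  check_that(inherits(s, "spectrum"), "invalid_parameter",
             "`s` must be a spectrum")
  w <- s$wavelength
  if (is.null(range)) range <- c(w[1], w[length(w)])
  check_that(length(range) == 2 && range[1] < range[2],
             "invalid_range", "`range` must be c(lo, hi) with lo < hi")
  lo <- max(range[1], w[1])
  hi <- min(range[2], w[length(w)])
  check_that(lo < hi, "invalid_range",
             "integration range does not intersect the wavelength grid")
  inside <- w > lo & w < hi
  xx <- c(lo, w[inside], hi)
  yy <- stats::approx(w, s$intensity, xout = xx)$y
  trapz_(xx, yy)
}

#' Locate emission peaks
#'
#' Local maxima of a Savitzky--Golay (moving-polynomial, order 2) smoothed
#' copy of the spectrum, at least `min_separation` nm apart; when two
#' candidate maxima fall closer than the separation the higher one is
#' kept. Reported intensities are taken from the *unsmoothed* spectrum.
#'
#' @param s a [spectrum].
#' @param smooth_window smoothing window in nm (default 15); must cover at
#'   least 3 grid points.
#' @param min_separation minimum peak separation in nm (default 10).
#' @return data.frame with columns `wavelength`, `intensity`, sorted by
#'   wavelength; zero rows when no local maximum exists.
#' @export
find_peaks <- function(s, smooth_window = 15, min_separation = 10) {
  check_that(inherits(s, "spectrum"), "invalid_parameter",
             "`s` must be a spectrum")
  w <- s$wavelength
  step <- mean(diff(w))
  span <- w[length(w)] - w[1]
  check_that(smooth_window <= span, "invalid_parameter",
             "`smooth_window` exceeds the wavelength span of the spectrum")
  npt <- max(3L, round(smooth_window / step))
  if (npt %% 2 == 0) npt <- npt + 1L
  npt <- min(npt, length(w) - (1 - length(w) %% 2)) # odd, <= n
  check_that(npt >= 3, "invalid_parameter",
             "`smooth_window` must cover at least 3 grid points")
  y <- signal::sgolayfilt(s$intensity, p = 2, n = npt)
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L # strict interior maxima
  cand <- cand[cand > 1 & cand < n]
  if (length(cand) == 0) {
    return(data.frame(wavelength = numeric(0), intensity = numeric(0)))
  }
  ## greedy suppression: keep the highest (smoothed) candidates first
  keep <- integer(0)
  for (i in cand[order(-y[cand])]) {
    if (all(abs(w[i] - w[keep]) >= min_separation)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  data.frame(wavelength = w[keep], intensity = s$intensity[keep])
}

#' Aggregate replicate spectra into a mean +/- sd band
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator) across
#' replicate spectra on identical grids — the shaded-band representation
#' used for replicate emission scans.
#'
#' @param group list of at least two [spectrum] objects, identical grids.
#' @return object of class `spectrum_band` with elements `mean`
#'   (a [spectrum]), `sd` (per-wavelength), `n`.
#' @export
aggregate_replicates <- function(group) {
  check_that(is.list(group) && length(group) >= 2 &&
               all(vapply(group, inherits, logical(1), "spectrum")),
             "invalid_parameter", "`group` must list at least 2 spectra")
  for (g in group[-1]) {
    check_that(same_grid(group[[1]], g), "grid_mismatch",
               "replicate spectra are on different wavelength grids")
  }
  m <- vapply(group, function(g) g$intensity, numeric(length(group[[1]]$intensity)))
  structure(
    list(mean = spectrum(group[[1]]$wavelength, rowMeans(m),
                         group[[1]]$meta),
         sd = apply(m, 1, stats::sd),
         n = length(group)),
    class = "spectrum_band"
  )
}

#' @export
print.spectrum_band <- function(x, ...) {
  cat(sprintf("<spectrum_band> mean of %d replicates, %d points\n",
              x$n, length(x$mean$wavelength)))
  invisible(x)
}
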