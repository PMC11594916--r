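#' Dilution series for gradient-method quantum yield
#'
#' Pairs of absorbance (at the excitation wavelength) and integrated
#' emission for a dilution series of one fluorophore in one solvent. The
#' gradient method stays in the optically dilute regime; absorbances above
#' 0.2 trigger a recorded warning (inner-filter effects bias the slope).
#'
#' @param absorbance unitless absorbance values.
#' @param integrated_emission integrated emission (a.u.), same length
#'   (typically from [integrate_spectrum]).
#' @param refractive_index solvent refractive index (default NA; required
#'   only when the index correction is applied in [relative_qy]).
#' @param label sample label.
#' @return object of class `qy_series`.
#' @export
qy_series <- function(absorbance, integrated_emission,
                      refractive_index = NA_real_, label = "") {
  check_that(is.numeric(absorbance) && is.numeric(integrated_emission) &&
               length(absorbance) == length(integrated_emission) &&
               length(absorbance) >= 1,
             "invalid_parameter",
             "absorbance and integrated emission must be equal-length numeric")
  check_that(all(absorbance >= 0), "invalid_parameter",
             "absorbance must be non-negative")
  dilute <- all(absorbance <= 0.2)
  if (!dilute) {
    warning("absorbance exceeds 0.2: outside the optically dilute regime",
            call. = FALSE)
  }
  structure(list(absorbance = as.numeric(absorbance),
                 integrated_emission = as.numeric(integrated_emission),
                 refractive_index = refractive_index, label = label,
                 dilute = dilute),
            class = "qy_series")
}

#' Slope of integrated emission vs absorbance
#'
#' Ordinary least-squares gradient with a free intercept (cuvette/plate
#' offsets are real and are not forced through the origin).
#'
#' @param series a [qy_series] with at least 3 points.
#' @return list with `gradient` and `stderr`.
#' @export
fit_gradient <- function(series) {
  check_that(inherits(series, "qy_series"), "invalid_parameter",
             "`series` must be a qy_series")
  check_that(length(series$absorbance) >= 3, "insufficient_data",
             "gradient fit needs at least 3 dilution points")
  check_that(stats::sd(series$absorbance) > 0, "degenerate_design",
             "absorbance values have zero spread; slope is unidentifiable")
  fit <- stats::lm(integrated_emission ~ absorbance,
                   data = data.frame(
                     absorbance = series$absorbance,
                     integrated_emission = series$integrated_emission))
  ## suppressed: lm warns on exact (zero-residual) dilution series, where a
  ## zero slope stderr is the correct answer
  co <- suppressWarnings(summary(fit))$coefficients
  list(gradient = unname(co["absorbance", "Estimate"]),
       stderr = unname(co["absorbance", "Std. Error"]))
}

#' Relative quantum yield from two gradients
#'
#' Gradient (slope) method against a reference fluorophore of known
#' quantum yield:
#' \deqn{\Phi = \Phi_{ref}\,\frac{m_{sample}}{m_{ref}}\,
#'       \frac{n_{sample}^2}{n_{ref}^2}}
#' with first-order error propagation from the two slope standard errors.
#' Common solvent indices: n(PBS) = 1.334, n(MeOH) = 1.329,
#' n(EtOH) = 1.361.
#'
#' @param sample,reference lists with `gradient` (and optionally `stderr`)
#'   as returned by [fit_gradient].
#' @param qy_ref reference quantum yield, in (0, 1].
#' @param n_sample,n_ref refractive indices (default 1, i.e. no
#'   correction; the correction is optional because matched solvents
#'   cancel it).
#' @return object of class `qy_result` with `gradient`, `gradient_stderr`,
#'   `qy` (fraction), `qy_stderr`.
#' @export
relative_qy <- function(sample, reference, qy_ref,
                        n_sample = 1, n_ref = 1) {
  gs <- sample$gradient
  gr <- reference$gradient
  check_that(is.numeric(gr) && gr > 0, "invalid_parameter",
             "reference gradient must be positive")
  check_that(is.numeric(qy_ref) && qy_ref > 0 && qy_ref <= 1,
             "invalid_parameter", "`qy_ref` must be in (0, 1]")
  ses <- if (!is.null(sample$stderr)) sample$stderr else 0
  ser <- if (!is.null(reference$stderr)) reference$stderr else 0
  qy <- qy_ref * (gs / gr) * (n_sample^2 / n_ref^2)
  rel_var <- (ses / gs)^2 + (ser / gr)^2
  structure(
    list(gradient = gs, gradient_stderr = ses,
         qy = qy, qy_stderr = abs(qy) * sqrt(rel_var)),
    class = "qy_result"
  )
}

#' @export
print.qy_result <- function(x, ...) {
  cat(sprintf("<qy_result> QY = %.3g%% +/- %.2g%%\n",
              100 * x$qy, 100 * x$qy_stderr))
  invisible(x)
}
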