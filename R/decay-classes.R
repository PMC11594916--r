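#' Multi-exponential decay model parameters
#'
#' Container for the parameters of a sum-of-exponentials fluorescence decay
#' model: component lifetimes \eqn{\tau_i} (ps), relative amplitudes
#' \eqn{B_i} expressed as percentages summing to 100, and a constant
#' background (counts per channel). Components are stored in canonical
#' order \eqn{\tau_1 < \tau_2 < \dots}.
#'
#' @param tau numeric vector of component lifetimes in ps, all > 0.
#' @param amp numeric vector of relative amplitudes (percent); same length
#'   as `tau`. Normalized to sum to 100.
#' @param background constant background counts per channel, >= 0.
#' @return object of class `decay_params`.
#' @examples
#' decay_params(tau = c(332, 788), amp = c(88, 12))
#' @export
decay_params <- function(tau, amp, background = 0) {
  check_that(is.numeric(tau) && length(tau) >= 1 && all(is.finite(tau)) &&
               all(tau > 0),
             "invalid_parameter", "`tau` must be positive finite lifetimes (ps)")
  check_that(is.numeric(amp) && length(amp) == length(tau) &&
               all(is.finite(amp)) && all(amp >= 0) && sum(amp) > 0,
             "invalid_parameter",
             "`amp` must be non-negative amplitudes matching `tau` in length")
  check_that(is.numeric(background) && length(background) == 1 &&
               is.finite(background) && background >= 0,
             "invalid_parameter", "`background` must be a single value >= 0")
  ord <- order(tau)
  tau <- tau[ord]
  amp <- 100 * amp[ord] / sum(amp)
  check_that(length(tau) == 1 || all(diff(tau) > 0), "invalid_parameter",
             "lifetimes must be distinct for canonical ordering")
  structure(
    list(tau = tau, amp = amp, background = as.numeric(background)),
    class = "decay_params"
  )
}

#' @export
print.decay_params <- function(x, ...) {
  cat("<decay_params> ", length(x$tau), " component(s)\n", sep = "")
  for (i in seq_along(x$tau)) {
    cat(sprintf("  tau%d = %.4g ps  (B%d = %.3g%%)\n",
                i, x$tau[i], i, x$amp[i]))
  }
  cat(sprintf("  background = %.4g counts/channel\n", x$background))
  invisible(x)
}

#' TCSPC decay trace
#'
#' A binned photon-arrival histogram: a uniform time axis (ps, bin
#' centres), non-negative counts per channel, and an optional instrument
#' response function (IRF) sampled on the same grid.
#'
#' @param time numeric ps grid, strictly increasing with uniform spacing.
#' @param counts non-negative counts per channel.
#' @param irf optional non-negative IRF values, same length as `counts`.
#' @param meta named list of free-form metadata (excitation/emission labels).
#' @return object of class `decay_trace`.
#' @export
decay_trace <- function(time, counts, irf = NULL, meta = list()) {
  check_that(is.numeric(time) && length(time) >= 2 && all(diff(time) > 0),
             "invalid_parameter", "`time` must be strictly increasing")
  check_that(is_uniform_grid(time), "unsupported_grid",
             "`time` must have uniform channel spacing")
  check_that(is.numeric(counts) && length(counts) == length(time) &&
               all(counts >= 0),
             "invalid_parameter", "`counts` must be non-negative, one per channel")
  if (!is.null(irf)) {
    check_that(is.numeric(irf) && length(irf) == length(counts) &&
                 all(irf >= 0),
               "invalid_parameter",
               "`irf` must be non-negative and match `counts` in length")
  }
  structure(
    list(time = as.numeric(time), counts = as.numeric(counts),
         irf = if (!is.null(irf)) as.numeric(irf), meta = meta),
    class = "decay_trace"
  )
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("<decay_trace> %d channels x %.4g ps, %.4g total counts%s\n",
              length(x$time), grid_step(x$time), sum(x$counts),
              if (is.null(x$irf)) "" else ", IRF attached"))
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  p <- x$params
  cat("<decay_fit> biexponential reconvolution fit\n")
  for (i in seq_along(p$tau)) {
    cat(sprintf("  tau%d = %.4g +/- %.2g ps   B%d = %.3g%%\n",
                i, p$tau[i], x$stderr[paste0("tau", i)], i, p$amp[i]))
  }
  cat(sprintf("  tau_amp = %.4g ps, tau_int = %.4g ps, chi2_red = %.4g\n",
              x$tau_amp, x$tau_int, x$chi2_red))
  invisible(x)
}
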