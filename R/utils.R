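#' @keywords internal
"_PACKAGE"

## Conversion constants used throughout: times are carried in picoseconds,
## wavelengths in nanometres, concentrations in nanomolar; nanoseconds appear
## only at presentation level (FLIM histograms, rendering).
FWHM_SIGMA <- 2 * sqrt(2 * log(2)) # 2.3548...

#' Signal a classed error
#'
#' All package errors carry a condition class of the form
#' `lcophys_<kind>` plus `lcophys_error`, so callers can branch on the
#' failure mode rather than matching message text.
#'
#' @param kind short kind label, e.g. `"invalid_parameter"`.
#' @param msg human-readable message.
#' @param ... fields attached to the condition (diagnostics).
#' @keywords internal
#' @noRd
lcophys_abort <- function(kind, msg, ...) {
  cond <- errorCondition(
    msg,
    ...,
    class = c(paste0("lcophys_", kind), "lcophys_error")
  )
  stop(cond)
}

check_that <- function(ok, kind, msg, ...) {
  if (!isTRUE(ok)) lcophys_abort(kind, msg, ...)
  invisible(TRUE)
}

#' Evaluate code with a private RNG stream
#'
#' Seeds are explicit operation arguments; the caller's global RNG state is
#' saved and restored so generators never perturb unrelated simulations.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "invalid_parameter", "`seed` must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

## Uniform-grid check with a relative tolerance on the spacing.
is_uniform_grid <- function(x, tol = 1e-8) {
  if (length(x) < 2) return(TRUE)
  d <- diff(x)
  all(d > 0) && (max(d) - min(d)) <= tol * max(abs(d))
}

grid_step <- function(x) {
  if (length(x) < 2) return(NA_real_)
  mean(diff(x))
}

fmt_num <- function(x) sprintf("%.17g", x)
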