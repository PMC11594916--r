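#' Equilibrium binding model parameters with per-species brightness
#'
#' Parameters of a one- or two-site ligand-depletion equilibrium model in
#' which each ligand species (free, bound at site class 1, bound at site
#' class 2) contributes to the fluorescence signal in proportion to its
#' concentration times its quantum yield. Two-site fields (`kd2`,
#' `sites2`, `qy_site2`) must be jointly present or jointly absent.
#'
#' @param kd1 dissociation constant of site class 1 (nM).
#' @param sites1 total concentration of site class 1 (nM).
#' @param qy_free quantum yield of the free ligand (fraction in `[0,1]`).
#' @param qy_site1 quantum yield of ligand bound at site class 1.
#' @param kd2,sites2,qy_site2 the same for site class 2 (`NULL` = one-site).
#' @param scale instrument scale, a.u. per (nM x QY); default 1.
#' @return object of class `binding_params`.
#' @examples
#' # two-site model: distinct affinities and brightnesses per site class
#' binding_params(kd1 = 100, sites1 = 1000, qy_free = 0.06,
#'                qy_site1 = 0.40, kd2 = 300, sites2 = 1000,
#'                qy_site2 = 0.20)
#' @export
binding_params <- function(kd1, sites1, qy_free, qy_site1,
                           kd2 = NULL, sites2 = NULL, qy_site2 = NULL,
                           scale = 1) {
  two_fields <- c(!is.null(kd2), !is.null(sites2), !is.null(qy_site2))
  check_that(all(two_fields) || !any(two_fields), "invalid_parameter",
             "kd2, sites2 and qy_site2 must be jointly present or absent")
  two_site <- all(two_fields)
  vals <- c(kd1, sites1, scale, if (two_site) c(kd2, sites2))
  check_that(all(is.finite(vals)) && all(vals >= 0), "invalid_parameter",
             "concentrations, Kd values and scale must be >= 0")
  qys <- c(qy_free, qy_site1, if (two_site) qy_site2)
  check_that(all(is.finite(qys)) && all(qys >= 0) && all(qys <= 1),
             "invalid_parameter", "quantum yields must lie in [0, 1]")
  structure(
    list(kd1 = kd1, kd2 = if (two_site) kd2,
         sites1 = sites1, sites2 = if (two_site) sites2,
         qy_free = qy_free, qy_site1 = qy_site1,
         qy_site2 = if (two_site) qy_site2,
         scale = scale, two_site = two_site),
    class = "binding_params"
  )
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("<binding_params> %s-site ligand-depletion model\n",
              if (x$two_site) "two" else "one"))
  cat(sprintf("  Kd1 = %.4g nM, sites1 = %.4g nM, QY(site1) = %.3g\n",
              x$kd1, x$sites1, x$qy_site1))
  if (x$two_site) {
    cat(sprintf("  Kd2 = %.4g nM, sites2 = %.4g nM, QY(site2) = %.3g\n",
                x$kd2, x$sites2, x$qy_site2))
  }
  cat(sprintf("  QY(free) = %.3g, scale = %.4g\n", x$qy_free, x$scale))
  invisible(x)
}

new_populations <- function(free, bound1, bound2, empty1, empty2) {
  structure(list(free_ligand = free, bound1 = bound1, bound2 = bound2,
                 empty1 = empty1, empty2 = empty2),
            class = "species_populations")
}

#' @export
print.species_populations <- function(x, ...) {
  cat(sprintf(paste0("<species_populations> free = %.4g, bound1 = %.4g, ",
                     "bound2 = %.4g nM\n"),
              x$free_ligand, x$bound1, x$bound2))
  invisible(x)
}

#' One-site ligand-depletion equilibrium
#'
#' Closed-form solution of the single-site mass-action equilibrium under
#' ligand depletion (bound ligand is not a negligible fraction of total):
#' \deqn{B = \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4PL}}{2}}
#' evaluated in the numerically stable form \eqn{B = 2PL/((P+L+K_d) +
#' \sqrt{(P+L+K_d)^2 - 4PL})} to avoid catastrophic cancellation when
#' \eqn{K_d \ll P, L}.
#'
#' @param total_ligand total ligand concentration L (nM).
#' @param sites total site concentration P (nM).
#' @param kd dissociation constant (nM).
#' @return [new_populations] fields: `free_ligand`, `bound1`, `bound2`
#'   (= 0), `empty1`, `empty2` (= 0), all nM.
#' @export
solve_one_site <- function(total_ligand, sites, kd) {
  check_that(all(is.finite(c(total_ligand, sites, kd))) &&
               all(c(total_ligand, sites, kd) >= 0),
             "invalid_parameter", "inputs must be non-negative")
  s <- total_ligand + sites + kd
  disc <- s^2 - 4 * sites * total_ligand
  disc <- max(disc, 0)
  denom <- s + sqrt(disc)
  bound <- if (denom > 0) 2 * sites * total_ligand / denom else 0
  bound <- min(bound, total_ligand, sites)
  new_populations(free = total_ligand - bound, bound1 = bound, bound2 = 0,
                  empty1 = sites - bound, empty2 = 0)
}

#' Two-site ligand-depletion equilibrium
#'
#' Solves the free-ligand conservation equation
#' \deqn{L + \frac{S_1 L}{L + K_{d1}} + \frac{S_2 L}{L + K_{d2}} = L_{tot}}
#' for the free concentration L by bracketed monotone root finding
#' (the left side is strictly increasing in L, so the root in
#' `[0, L_tot]` is unique), then fills each site class independently:
#' \eqn{B_s = S_s L/(L + K_{ds})}.
#'
#' @param total_ligand total ligand (nM).
#' @param sites1,sites2 site-class concentrations (nM).
#' @param kd1,kd2 per-class dissociation constants (nM).
#' @return species populations as in [solve_one_site], with `bound2` and
#'   `empty2` populated.
#' @export
solve_two_site <- function(total_ligand, sites1, sites2, kd1, kd2) {
  vals <- c(total_ligand, sites1, sites2, kd1, kd2)
  check_that(all(is.finite(vals)) && all(vals >= 0),
             "invalid_parameter", "inputs must be non-negative")
  if (sites2 == 0) {
    p <- solve_one_site(total_ligand, sites1, kd1)
    return(new_populations(p$free_ligand, p$bound1, 0, p$empty1, 0))
  }
  if (total_ligand == 0) {
    return(new_populations(0, 0, 0, sites1, sites2))
  }
  ## Kd = 0 is a stoichiometric limit; nudge to keep mass action defined
  kd1 <- max(kd1, 1e-12)
  kd2 <- max(kd2, 1e-12)
  f <- function(l) {
    l + sites1 * l / (l + kd1) + sites2 * l / (l + kd2) - total_ligand
  }
  if (f(total_ligand) < 0 || f(0) > 0) {
    lcophys_abort("internal",
                  "two-site root not bracketed on [0, total_ligand]",
                  f0 = f(0), f1 = f(total_ligand))
  }
  l <- stats::uniroot(f, c(0, total_ligand),
                      tol = 1e-12 * max(total_ligand, 1))$root
  ## one Newton polish step for full double precision
  fp <- 1 + sites1 * kd1 / (l + kd1)^2 + sites2 * kd2 / (l + kd2)^2
  l <- min(max(l - f(l) / fp, 0), total_ligand)
  b1 <- sites1 * l / (l + kd1)
  b2 <- sites2 * l / (l + kd2)
  new_populations(free = l, bound1 = b1, bound2 = b2,
                  empty1 = sites1 - b1, empty2 = sites2 - b2)
}

solve_populations <- function(params, total_ligand) {
  if (params$two_site) {
    solve_two_site(total_ligand, params$sites1, params$sites2,
                   params$kd1, params$kd2)
  } else {
    solve_one_site(total_ligand, params$sites1, params$kd1)
  }
}

#' Brightness-weighted fluorescence signal of a species mixture
#'
#' \eqn{S = c \,(\Phi_{free}\,L_{free} + \Phi_1 B_1 + \Phi_2 B_2)}:
#' each ligand species contributes in proportion to its concentration and
#' quantum yield, with a single instrument scale `c`.
#'
#' @param pop species populations from [solve_one_site]/[solve_two_site].
#' @param params a [binding_params].
#' @return signal in a.u.
#' @export
predict_signal <- function(pop, params) {
  check_that(inherits(pop, "species_populations") &&
               inherits(params, "binding_params"),
             "invalid_parameter",
             "need species_populations and binding_params inputs")
  check_that(params$two_site || pop$bound2 == 0, "invalid_parameter",
             "two-site populations passed to a one-site parameter set")
  qy2 <- if (params$two_site) params$qy_site2 else 0
  params$scale * (params$qy_free * pop$free_ligand +
                    params$qy_site1 * pop$bound1 + qy2 * pop$bound2)
}

#' Simulate a deterministic binding curve
#'
#' Evaluates the depletion equilibrium and brightness-weighted signal at
#' each total-ligand concentration, along with the matching ligand-only
#' (no protein) series \eqn{c\,\Phi_{free}\,L_{tot}}.
#'
#' @param params a [binding_params].
#' @param conc_series total-ligand concentrations (nM).
#' @return object of class `binding_dataset` with `total_ligand`, `signal`
#'   (single-column matrix), `ligand_only_signal`, `protein_monomer`.
#' @export
simulate_curve <- function(params, conc_series) {
  check_that(inherits(params, "binding_params"), "invalid_parameter",
             "`params` must be a binding_params")
  check_that(is.numeric(conc_series) && all(conc_series >= 0),
             "invalid_parameter", "concentrations must be >= 0")
  sig <- vapply(conc_series,
                function(l) predict_signal(solve_populations(params, l),
                                           params),
                numeric(1))
  binding_dataset(total_ligand = conc_series,
                  signal = matrix(sig, ncol = 1),
                  ligand_only_signal =
                    params$scale * params$qy_free * conc_series,
                  protein_monomer = params$sites1)
}

#' Binding titration dataset
#'
#' @param total_ligand total-ligand concentrations (nM).
#' @param signal matrix of signals, one row per concentration, one column
#'   per replicate.
#' @param ligand_only_signal matching ligand-only series (a.u.), or `NULL`.
#' @param protein_monomer protein concentration on the monomer basis (nM).
#' @return object of class `binding_dataset`.
#' @export
binding_dataset <- function(total_ligand, signal,
                            ligand_only_signal = NULL,
                            protein_monomer = NA_real_) {
  check_that(is.numeric(total_ligand) && all(total_ligand >= 0),
             "invalid_parameter", "concentrations must be >= 0")
  signal <- as.matrix(signal)
  check_that(nrow(signal) == length(total_ligand), "invalid_parameter",
             "`signal` must have one row per concentration")
  if (!is.null(ligand_only_signal)) {
    check_that(length(ligand_only_signal) == length(total_ligand),
               "invalid_parameter",
               "ligand-only series must match the concentration series")
  }
  structure(list(total_ligand = as.numeric(total_ligand), signal = signal,
                 ligand_only_signal = ligand_only_signal,
                 protein_monomer = protein_monomer),
            class = "binding_dataset")
}

#' @export
print.binding_dataset <- function(x, ...) {
  cat(sprintf("<binding_dataset> %d concentrations x %d replicate(s)\n",
              length(x$total_ligand), ncol(x$signal)))
  invisible(x)
}

#' Species fractions along a titration
#'
#' Per-concentration fractions of total ligand that are free, bound at
#' site class 1 and bound at site class 2 (population analysis of a
#' simulated titration). Rows with zero total ligand are reported as `NA`
#' (undefined fraction).
#'
#' @param params a [binding_params].
#' @param conc_series total-ligand concentrations (nM).
#' @return data.frame with columns `total_ligand`, `free`, `bound1`,
#'   `bound2`; defined rows sum to 1.
#' @export
population_fractions <- function(params, conc_series) {
  check_that(inherits(params, "binding_params"), "invalid_parameter",
             "`params` must be a binding_params")
  out <- lapply(conc_series, function(l) {
    if (l == 0) return(c(NA_real_, NA_real_, NA_real_))
    p <- solve_populations(params, l)
    c(p$free_ligand, p$bound1, p$bound2) / l
  })
  m <- do.call(rbind, out)
  data.frame(total_ligand = conc_series,
             free = m[, 1], bound1 = m[, 2], bound2 = m[, 3])
}

## ---- fitting -------------------------------------------------------------

#' Fit a depletion binding model to titration data
#'
#' Nonlinear least squares (Levenberg--Marquardt) of the brightness-
#' weighted one- or two-site depletion model to replicate signals. `Kd`,
#' site concentrations and the instrument scale are fitted on the log
#' scale, which enforces positivity without constrained optimization;
#' quantum yields are fitted on the raw scale. Any parameter may be held
#' fixed via `fixed`.
#'
#' @param data a [binding_dataset] with >= 5 distinct concentrations.
#' @param model `"one_site"` or `"two_site"`.
#' @param fixed named list of parameters to hold fixed (any of `kd1`,
#'   `kd2`, `sites1`, `sites2`, `qy_free`, `qy_site1`, `qy_site2`,
#'   `scale`). Defaults fix the site concentrations to the dataset's
#'   protein monomer concentration (one site class per monomer) and the
#'   quantum yields to the supplied `start` values, leaving `kd` and
#'   `scale` free.
#' @param start a [binding_params] of starting values; a default is built
#'   from `fixed` and the data when omitted.
#' @param free character vector naming the free parameters
#'   (default `c("kd1", "scale")` plus `"kd2"` for the two-site model).
#' @return list with `params` (fitted [binding_params]), `stderr` (named,
#'   delta-method), `residuals`, `rss`, `converged`, `n_obs`.
#' @export
fit_binding <- function(data, model = c("one_site", "two_site"),
                        fixed = list(), start = NULL, free = NULL) {
  model <- match.arg(model)
  check_that(inherits(data, "binding_dataset"), "invalid_parameter",
             "`data` must be a binding_dataset")
  n_conc <- length(unique(data$total_ligand))
  check_that(n_conc >= 5, "insufficient_data",
             "binding fit needs at least 5 distinct concentrations")
  two_site <- model == "two_site"

  sites_default <- if (!is.na(data$protein_monomer)) data$protein_monomer
                   else max(data$total_ligand)
  defaults <- list(kd1 = stats::median(data$total_ligand[data$total_ligand > 0]),
                   kd2 = 3 * stats::median(data$total_ligand[data$total_ligand > 0]),
                   sites1 = sites_default, sites2 = sites_default,
                   qy_free = 0.06, qy_site1 = 0.3, qy_site2 = 0.2,
                   scale = {
                     peak <- max(data$signal)
                     den <- max(data$total_ligand) * 0.3
                     if (peak > 0 && den > 0) peak / den else 1
                   })
  if (!is.null(start)) {
    for (nm in names(defaults)) {
      if (!is.null(start[[nm]])) defaults[[nm]] <- start[[nm]]
    }
  }
  for (nm in names(fixed)) {
    check_that(nm %in% names(defaults), "invalid_parameter",
               sprintf("unknown fixed parameter '%s'", nm))
    defaults[[nm]] <- fixed[[nm]]
  }
  if (is.null(free)) {
    free <- setdiff(c("kd1", if (two_site) "kd2", "scale"), names(fixed))
  }
  check_that(length(free) >= 1, "invalid_parameter",
             "at least one parameter must be free")
  check_that(!any(free %in% names(fixed)), "invalid_parameter",
             "a parameter cannot be both free and fixed")
  check_that(length(free) < n_conc, "identifiability",
             "free parameters must number fewer than distinct concentrations")

  log_pars <- c("kd1", "kd2", "sites1", "sites2", "scale")
  to_internal <- function(nm, v) if (nm %in% log_pars) log(max(v, 1e-12)) else v
  from_internal <- function(nm, v) if (nm %in% log_pars) exp(v) else v

  p0 <- vapply(free, function(nm) to_internal(nm, defaults[[nm]]), numeric(1))
  names(p0) <- free

  make_params <- function(p) {
    cur <- defaults
    for (nm in free) cur[[nm]] <- from_internal(nm, p[[nm]])
    binding_params(kd1 = cur$kd1, sites1 = cur$sites1,
                   qy_free = min(max(cur$qy_free, 0), 1),
                   qy_site1 = min(max(cur$qy_site1, 0), 1),
                   kd2 = if (two_site) cur$kd2,
                   sites2 = if (two_site) cur$sites2,
                   qy_site2 = if (two_site) min(max(cur$qy_site2, 0), 1),
                   scale = cur$scale)
  }

  y <- as.vector(data$signal)
  conc_rep <- rep(data$total_ligand, times = ncol(data$signal))
  resid_fn <- function(p) {
    pars <- make_params(p)
    mu <- vapply(data$total_ligand,
                 function(l) predict_signal(solve_populations(pars, l), pars),
                 numeric(1))
    rep(mu, times = ncol(data$signal)) - y
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300, ptol = 1e-12, ftol = 1e-12))
  pars <- make_params(fit$par)

  dof <- max(length(y) - length(free), 1)
  s2 <- fit$deviance / dof
  se_int <- rep(NA_real_, length(free))
  names(se_int) <- free
  cov <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
    se_int <- sqrt(diag(cov))
  }
  stderr <- vapply(free, function(nm) {
    if (nm %in% log_pars) se_int[[nm]] * from_internal(nm, fit$par[[nm]])
    else se_int[[nm]]
  }, numeric(1))
  names(stderr) <- free
  ## identifiability flag: a log-scale stderr spanning more than a decade
  ## (or an unestimable one from a singular information matrix)
  wide <- free[free %in% log_pars &
                 (!is.finite(se_int[free]) | se_int[free] > log(10))]
  if (length(wide) > 0) {
    warning(sprintf("poorly identified parameter(s): %s (stderr spans >1 decade)",
                    paste(wide, collapse = ", ")), call. = FALSE)
  }

  list(params = pars, stderr = stderr, residuals = resid_fn(fit$par),
       rss = fit$deviance, converged = fit$info %in% 1:3,
       n_obs = length(y), free = free)
}
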