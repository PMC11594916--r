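# independent oracle: bisection on the one-site conservation equation
# bound*Kd = (L - bound)(P - bound)
bisect_one_site <- function(L, P, kd, iters = 200) {
  f <- function(b) (L - b) * (P - b) - b * kd
  lo <- 0; hi <- min(L, P)
  if (f(hi) >= 0) return(hi)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

test_that("solve_one_site matches the bisection oracle and its limits", {
  p <- solve_one_site(1000, 1000, 25)
  expect_equal(p$bound1, bisect_one_site(1000, 1000, 25), tolerance = 1e-9)
  expect_equal(p$bound1, 853.9, tolerance = 1e-3)
  expect_equal(p$free_ligand, 146.1, tolerance = 1e-3)
  # mass action holds: bound*Kd = free*empty
  expect_equal(p$bound1 * 25, p$free_ligand * p$empty1, tolerance = 1e-6)

  z <- solve_one_site(0, 1000, 25)
  expect_equal(z$bound1, 0)
  expect_equal(z$free_ligand, 0)

  st <- solve_one_site(600, 1000, 0) # stoichiometric limit
  expect_equal(st$bound1, 600)

  expect_error(solve_one_site(-1, 10, 10),
               class = "lcophys_invalid_parameter")
})

test_that("solve_two_site matches the conservation-equation bisection oracle", {
  pops <- solve_two_site(1000, 1000, 1000, 100, 300)
  # oracle: bisection on L + S1 L/(L+Kd1) + S2 L/(L+Kd2) = Ltot
  g <- function(l) l + 1000 * l / (l + 100) + 1000 * l / (l + 300) - 1000
  lo <- 0; hi <- 1000
  for (i in 1:200) { mid <- (lo + hi) / 2; if (g(mid) <= 0) lo <- mid else hi <- mid }
  free_oracle <- (lo + hi) / 2
  expect_equal(pops$free_ligand, free_oracle, tolerance = 1e-9)
  expect_equal(pops$free_ligand, 130.6, tolerance = 1e-3)
  expect_equal(pops$bound1, 566, tolerance = 1e-3)
  expect_equal(pops$bound2, 303, tolerance = 1e-2)

  # Kd2 -> infinity reduces to the one-site solution
  far <- solve_two_site(1000, 1000, 1000, 25, 1e12)
  one <- solve_one_site(1000, 1000, 25)
  expect_equal(far$bound1, one$bound1, tolerance = 1e-6)
  expect_equal(far$free_ligand, one$free_ligand, tolerance = 1e-6)

  # S2 = 0 is exactly one-site
  s20 <- solve_two_site(1000, 1000, 0, 25, 300)
  expect_identical(s20$bound1, one$bound1)
})

test_that("mass conservation holds over random parameter sweeps", {
  set.seed(17)
  for (i in 1:300) {
    L <- stats::runif(1, 0, 5000)
    S1 <- stats::runif(1, 0, 3000); S2 <- stats::runif(1, 0, 3000)
    k1 <- stats::runif(1, 1, 1000); k2 <- stats::runif(1, 1, 1000)
    p <- solve_two_site(L, S1, S2, k1, k2)
    scale <- max(L, 1)
    expect_equal((p$free_ligand + p$bound1 + p$bound2) / scale, L / scale,
                 tolerance = 1e-9)
    expect_equal(p$bound1 + p$empty1, S1, tolerance = 1e-9 * max(S1, 1))
    expect_equal(p$bound2 + p$empty2, S2, tolerance = 1e-9 * max(S2, 1))
    expect_true(all(unlist(p) >= -1e-12))
  }
})

test_that("predict_signal is brightness-weighted and monotone in ligand", {
  p1 <- binding_params(kd1 = 25, sites1 = 0, qy_free = 0.06, qy_site1 = 0.3)
  pop <- solve_one_site(1000, 0, 25)
  expect_equal(predict_signal(pop, p1), 60, tolerance = 1e-12)

  # all species equally bright: signal proportional to total ligand
  peq <- binding_params(kd1 = 25, sites1 = 1000, qy_free = 0.2,
                        qy_site1 = 0.2, scale = 3)
  conc <- seq(0, 4500, by = 300)
  sim <- simulate_curve(peq, conc)
  expect_equal(sim$signal[, 1], 3 * 0.2 * conc, tolerance = 1e-9)

  pfig <- binding_params(kd1 = 25, sites1 = 1000, qy_free = 0.06,
                         qy_site1 = 0.3)
  s <- simulate_curve(pfig, seq(0, 4500, by = 150))$signal[, 1]
  expect_true(all(diff(s) > -1e-12))
  expect_equal(s[1], 0)
})

test_that("occupancy and free-ligand fractions reproduce the titration regimes", {
  pfig <- binding_params(kd1 = 25, sites1 = 1000, qy_free = 0.06,
                         qy_site1 = 0.3)
  # sites essentially filled above ~1.5x the site concentration
  occ <- solve_one_site(1500, 1000, 25)
  expect_gte(occ$bound1 / 1000, 0.95)
  # below 500 nM nearly all ligand is bound (free fraction < 5%)
  fr <- population_fractions(pfig, c(100, 250, 500))
  expect_true(all(fr$free < 0.05))
  # fractions always sum to 1 where defined
  fr2 <- population_fractions(
    binding_params(kd1 = 100, sites1 = 1000, qy_free = 0.06,
                   qy_site1 = 0.4, kd2 = 300, sites2 = 1000,
                   qy_site2 = 0.2),
    c(0, 10, 100, 1000, 4500))
  defined <- !is.na(fr2$free)
  expect_false(defined[1])
  expect_equal(unname(rowSums(fr2[defined, c("free", "bound1", "bound2")])),
               rep(1, sum(defined)), tolerance = 1e-9)
  # linear regime: bound fraction approaches S/(S+Kd)
  lin <- population_fractions(
    binding_params(kd1 = 50, sites1 = 5000, qy_free = 0, qy_site1 = 1),
    0.01)
  expect_equal(lin$bound1, 5000 / 5050, tolerance = 1e-3)
})

test_that("fit_binding recovers parameters and flags pathologies", {
  truth <- binding_params(kd1 = 25, sites1 = 1000, qy_free = 0.06,
                          qy_site1 = 0.3, scale = 2)
  conc <- c(0, 35, 70, 141, 282, 563, 1000, 1500, 2250, 3000, 4500)
  clean <- gen_binding_dataset(truth, conc, noise_cv = 0, n_reps = 1,
                               seed = 1)
  fit <- fit_binding(clean, "one_site",
                     fixed = list(qy_free = 0.06, qy_site1 = 0.3,
                                  sites1 = 1000))
  expect_equal(fit$params$kd1, 25, tolerance = 1e-6)
  expect_equal(fit$params$scale, 2, tolerance = 1e-6)
  expect_true(fit$converged)

  # over-parameterized: free params must number fewer than concentrations
  tiny <- binding_dataset(c(0, 100, 1000), matrix(c(0, 1, 2), ncol = 1))
  expect_error(fit_binding(tiny, "one_site"),
               class = "lcophys_insufficient_data")
  five <- gen_binding_dataset(truth, c(0, 100, 500, 1000, 4500), 0, 1, 1)
  expect_error(
    fit_binding(five, "one_site",
                free = c("kd1", "scale", "qy_free", "qy_site1", "sites1")),
    class = "lcophys_identifiability")

  # saturated titration (no curvature): Kd poorly identified
  sat <- gen_binding_dataset(truth, seq(50000, 95000, by = 9000),
                             noise_cv = 0.05, n_reps = 2, seed = 3)
  expect_warning(
    fit_binding(sat, "one_site",
                fixed = list(qy_free = 0.06, qy_site1 = 0.3, sites1 = 1000)),
    "poorly identified")
})

test_that("noisy-titration Kd recovery is within 50% in the median", {
  truth <- binding_params(kd1 = 25, sites1 = 1000, qy_free = 0.06,
                          qy_site1 = 0.3)
  conc <- c(0, 18, 35, 70, 141, 282, 563, 750, 1000, 1500, 2250, 3000,
            3750, 4500)
  kds <- vapply(1:50, function(s) {
    ds <- gen_binding_dataset(truth, conc, noise_cv = 0.05, n_reps = 3,
                              seed = s)
    fit_binding(ds, "one_site",
                fixed = list(qy_free = 0.06, qy_site1 = 0.3,
                             sites1 = 1000))$params$kd1
  }, numeric(1))
  expect_lt(abs(stats::median(kds) - 25) / 25, 0.5)
})
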