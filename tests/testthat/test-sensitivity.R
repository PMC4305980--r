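test_that("the log-difference quotient is exact for power-law outputs", {
  p <- random_params(3, seed = 61)
  # q = beta_2 is a pure power (exponent 1) of parameter index n + 2
  ev <- function(q) q$beta[2]
  for (delta in c(1e-3, 1e-2, 0.1)) {
    expect_equal(sensitivity_fd(ev, p, 5L, delta), 1, tolerance = 1e-10)
  }
  # q = 1/alpha_1: exponent -1
  expect_equal(sensitivity_fd(function(q) 1 / q$alpha[1], p, 1L), -1,
               tolerance = 1e-10)
  # a parameter the output does not involve
  expect_lt(abs(sensitivity_fd(ev, p, 7L)), 1e-10)
})

test_that("finite differences reproduce the analytic period sensitivities", {
  # at rho = 0.5 the beta sensitivity of the closed-form period vanishes
  p <- sym_ring()
  expect_lt(abs(sensitivity_fd(period_full, p, 4L)), 1e-3)

  # forward differences agree with the analytic forms to O(delta)
  delta <- 1e-3
  worst <- 0
  for (k in 1:100) {
    p <- random_params(3, seed = 800 + k)
    # near the bifurcation (rho -> 1) the sensitivities vary so steeply that
    # a fixed-step forward difference carries a visible truncation error
    if (any(rho_ratio(p) > 0.9)) next
    tab <- period_sensitivities_analytic(p)
    for (j in c(1L, 4L, 7L)) {
      s_fd <- sensitivity_fd(period_full, p, j, delta)
      dev <- abs(s_fd - tab$S[j]) / max(abs(tab$S[j]), 1)
      worst <- max(worst, dev)
    }
  }
  # first-order truncation: the worst deviation is O(delta) with a curvature
  # constant of a few (measured ~5.3 for draws capped at rho = 0.9)
  expect_lt(worst, 10 * delta)
  # and it scales linearly: a quarter of the step, about a quarter the error
  p <- random_params(3, seed = 800 + 17)
  tab <- period_sensitivities_analytic(p)
  err_at <- function(d) abs(sensitivity_fd(period_full, p, 1L, d) - tab$S[1])
  expect_lt(err_at(delta / 4), err_at(delta) / 2)
  # central differencing is more accurate where the forward error is visible
  p <- sym_ring(3, rho = 0.3)
  tabS <- period_sensitivities_analytic(p)$S[1]
  err_f <- abs(sensitivity_fd(period_full, p, 1L, 1e-2) - tabS)
  err_c <- abs(sensitivity_fd(period_full, p, 1L, 1e-2, central = TRUE) - tabS)
  expect_lt(err_c, err_f)
})

test_that("perturbations that cross the bifurcation error out with context", {
  p <- sym_ring(3, rho = 0.9995)
  # K * 1.001 pushes rho past 1: the closed form must refuse, not clamp
  expect_error(sensitivity_fd(period_full, p, 7L, 1e-3), "K1")
})

test_that("mps sums squared sensitivities over every kinetic parameter", {
  expect_equal(mps_from_table(sensitivity_table(c(3, 4, rep(0, 7)), n = 3,
                                                output = "toy",
                                                method = "analytic")), 25)

  for (k in 1:5) {
    p <- random_params(sample(3:6, 1), seed = 830 + k)
    r <- mps(function(q) amplitude_full(q)[1], p)
    expect_equal(r$phi, 2, tolerance = 1e-6)
    expect_equal(nrow(r$table), 3L * p$n)
  }

  # two independent evaluators of the same quantity: cycle-closure period vs
  # event-driven simulated period
  p <- sym_ring()
  phi_semi <- mps(function(q) period_semi(q), p)$phi
  phi_sim <- mps(function(q) simulate_ring(q, tol = 1e-12)$cycle$period, p)$phi
  expect_equal(phi_semi, phi_sim, tolerance = 1e-4)

  # large-n semi-analytical amplitude MPS approaches the closed-form 2;
  # measured deviations for the symmetric ring: 4.3e-2 at n = 9, 1.2e-3 at
  # n = 15, shrinking with the trough (~ 2^-n)
  devs <- vapply(c(9L, 15L), function(n) {
    abs(mps_semi_all(sym_ring(n))$phi_eps[[1]] - 2)
  }, numeric(1))
  expect_lt(devs[1], 0.05)
  expect_lt(devs[2], 1.3e-3)
  expect_lt(devs[2], devs[1])
})

test_that("sensitivity tables export as TSV", {
  tab <- period_sensitivities_analytic(sym_ring())
  path <- withr::local_tempfile(fileext = ".tsv")
  export_sensitivities(tab, path)
  got <- utils::read.delim(path)
  expect_identical(names(got), c("parameter", "species", "output", "S",
                                 "method"))
  expect_equal(nrow(got), 9L)
})

test_that("Monte-Carlo normalized variance estimates the MPS", {
  p <- random_params(3, seed = 71)
  r <- mc_variance(function(q) amplitude_full(q)[2], p, sigma = 0.01,
                   n_samples = 4000, seed = 7)
  expect_lt(abs(r$nv - 2), 3 * r$se)

  ps <- sym_ring()
  r2 <- mc_variance(period_full, ps, sigma = 0.01, n_samples = 4000, seed = 7)
  expect_lt(abs(r2$nv - 1 / 3), 3 * r2$se)

  # linear-regime consistency across noise scales
  r3 <- mc_variance(period_full, ps, sigma = 0.005, n_samples = 4000, seed = 8)
  expect_lt(abs(r3$nv - r2$nv), 3 * (r2$se + r3$se))

  # reproducibility under a fixed seed
  r4 <- mc_variance(period_full, ps, sigma = 0.01, n_samples = 4000, seed = 7)
  expect_identical(r2$nv, r4$nv)
})
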