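test_that("closed-form period and amplitude reduce as expected", {
  expect_equal(period_full(sym_ring(3)), 3 * log(4))
  expect_equal(period_full(sym_ring(7)), 7 * log(4))
  p <- osc_params(c(1, 2, 4), c(1, 2, 4), c(0.5, 0.5, 0.5)) # rho = 0.5 each
  expect_equal(period_full(p), log(4) * (1 + 1 / 2 + 1 / 4))

  expect_equal(amplitude_full(osc_params(4, 2, 0.25)), 0.5)
  expect_equal(amplitude_full(sym_ring()), rep(1, 3))
  # amplitude is independent of the thresholds
  expect_equal(amplitude_full(sym_ring(rho = 0.9)),
               amplitude_full(sym_ring(rho = 0.1)))

  expect_error(period_full(osc_params(c(1, 1, 1), c(1, 1, 1), c(2, 0.5, 0.5))),
               "oscillatory branch")
})

test_that("the shape function f(rho) has the documented profile", {
  expect_equal(f_rho(0.5), 1) # g = 0 there
  expect_equal(f_rho(0.5959), 0.6667, tolerance = 1e-3)
  expect_gt(f_rho(0.999), 100) # divergence toward rho = 1
  expect_error(f_rho(1), "oscillatory branch")
  expect_error(f_rho(0), "oscillatory branch")
  expect_length(f_rho(c(0.3, 0.5, 0.7)), 3L)
})

test_that("closed-form period MPS matches its reductions", {
  expect_equal(period_mps_full(sym_ring(3)), 1 / 3)
  expect_equal(period_mps_full(sym_ring(3, rho = 0.5959)), 0.2222,
               tolerance = 1e-3)
  p <- osc_params(c(1, 2, 4), c(1, 2, 4), c(0.5, 0.5, 0.5))
  expect_equal(period_mps_full(p), (1 + 1 / 4 + 1 / 16) / (1 + 1 / 2 + 1 / 4)^2)
})

test_that("period MPS equals the squared sum of the analytic sensitivities and
           obeys its invariances", {
  for (k in 1:20) {
    p <- random_params(sample(3:7, 1), seed = 500 + k)
    tab <- period_sensitivities_analytic(p)
    expect_equal(period_mps_full(p), mps_from_table(tab), tolerance = 1e-12)
    # scale invariance: alpha -> c * alpha at fixed rho (scale K with alpha)
    cfac <- 1 + k / 7
    ps <- osc_params(cfac * p$alpha, p$beta, p$K / cfac)
    expect_equal(rho_ratio(ps), rho_ratio(p))
    expect_equal(period_mps_full(ps), period_mps_full(p), tolerance = 1e-12)
  }
  # uniform reduction: equal alpha, equal rho -> f(rho)/n
  for (n in c(3, 6)) {
    for (rho in c(0.2, 0.5, 0.8)) {
      expect_equal(period_mps_full(sym_ring(n, rho)), f_rho(rho) / n,
                   tolerance = 1e-12)
    }
  }
  # bounds at rho = 0.5 over random alpha: 1/n <= Phi <= 1
  for (k in 1:50) {
    set.seed(600 + k)
    n <- sample(3:8, 1)
    a <- runif(n, 0.01, 10)
    p <- osc_params(a, a, rep(0.5, n)) # K = 0.5 * beta/alpha => rho = 0.5
    expect_equal(rho_ratio(p), rep(0.5, n))
    phi <- period_mps_full(p)
    expect_gte(phi, 1 / n - 1e-12)
    expect_lte(phi, 1 + 1e-12)
  }
  # equality at 1/n iff all alpha equal
  expect_equal(period_mps_full(sym_ring(5)), 1 / 5, tolerance = 1e-14)
})

test_that("analytic period sensitivities have the rho = 0.5 structure", {
  # beta and K sensitivities vanish at rho = 0.5; alpha ones are -1/n when
  # the decay rates are equal
  tab <- period_sensitivities_analytic(sym_ring(4))
  expect_equal(tab$S[5:12], rep(0, 8))
  expect_equal(tab$S[1:4], rep(-1 / 4, 4))

  # sum over all 3n sensitivities is -1 for arbitrary alpha at rho = 0.5
  for (k in 1:10) {
    set.seed(700 + k)
    a <- runif(3, 0.1, 5)
    p <- osc_params(a, a, rep(0.5, 3))
    expect_equal(sum(period_sensitivities_analytic(p)$S), -1,
                 tolerance = 1e-12)
  }
})

test_that("analytic amplitude sensitivities are the (-1, +1, 0) pattern", {
  p <- random_params(4, seed = 51)
  for (i in 1:4) {
    tab <- amplitude_sensitivities_analytic(p, i)
    expect_equal(tab$S[i], -1)
    expect_equal(tab$S[4 + i], 1)
    expect_equal(sum(abs(tab$S)), 2) # everything else zero
    expect_equal(mps_from_table(tab), 2)
  }
  expect_error(amplitude_sensitivities_analytic(p, 5), "out of range")
})

test_that("period_scan produces a finite profile with an interior minimum", {
  for (param in c("alpha", "beta", "K")) {
    sc <- period_scan(param)
    expect_true(all(is.finite(sc$tau) & sc$tau > 0))
    am <- attr(sc, "argmin")
    expect_gt(am, min(sc$value))
    expect_lt(am, max(sc$value))
  }
  # the alpha scan's argmin agrees with the bracketed minimizer
  expect_equal(attr(period_scan("alpha"), "argmin"),
               find_rho_minima()$rho_min_period_vs_alpha, tolerance = 2e-3)
})

test_that("find_rho_minima locates the robustness optima", {
  m <- find_rho_minima()
  expect_equal(m$rho_min_mps, 0.5959, tolerance = 1e-3)
  expect_equal(m$f_min, 0.6667, tolerance = 1e-3)
  expect_equal(m$mps_min_n3, 0.2222, tolerance = 1e-3)
  expect_equal(m$rho_min_period_vs_alpha, 0.7228, tolerance = 1e-3)

  # independent cross-check: the period-vs-alpha minimizer solves
  # log(rho (1 - rho)) = (1 - 2 rho)/(1 - rho), found here by bisection
  h <- function(r) log(r * (1 - r)) - (1 - 2 * r) / (1 - r)
  lo <- 0.5; hi <- 0.99
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (h(lo) * h(mid) <= 0) hi <- mid else lo <- mid
  }
  expect_equal(m$rho_min_period_vs_alpha, (lo + hi) / 2, tolerance = 1e-4)
})
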