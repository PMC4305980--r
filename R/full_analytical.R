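# Closed-form tier: period, amplitude, sensitivities and MPS under the
# saturating approximation (peak -> beta/alpha, trough -> 0), which becomes
# exact as the feedback loop grows long.

# guard: the closed forms involve log(rho*(1-rho)), undefined at rho in {0,1}
RHO_CUTOFF <- 1e-12

check_rho <- function(rho) {
  if (any(!is.finite(rho) | rho <= 0 | rho >= 1 - RHO_CUTOFF)) {
    stop("threshold ratio rho must lie in (0, 1): the closed forms are ",
         "defined only on the oscillatory branch")
  }
  rho
}

# L_i = log(rho_i (1 - rho_i)) and g_i = (1 - 2 rho_i) / (1 - rho_i), the two
# building blocks of every closed-form expression below
rho_terms <- function(rho) {
  check_rho(rho)
  list(L = log(rho * (1 - rho)), g = (1 - 2 * rho) / (1 - rho))
}

#' Closed-form limit-cycle period
#'
#' `tau = -sum(log(rho_i * (1 - rho_i)) / alpha_i)` with threshold ratios
#' `rho_i = K_i alpha_i / beta_i`. Exact in the saturating limit; for short
#' loops it overestimates the finite-trough period slightly.
#'
#' @param p an [osc_params()] object with all rho in (0,1).
#' @return positive scalar period.
#' @export
period_full <- function(p) {
  stopifnot(inherits(p, "osc_params"))
  rho <- check_rho(rho_ratio(p))
  -sum(log(rho * (1 - rho)) / p$alpha)
}

#' Closed-form amplitudes
#'
#' In the saturating limit every species swings over its full attainable
#' range, so `eps_i = beta_i / alpha_i`, independent of the thresholds K.
#'
#' @param p an [osc_params()] object.
#' @return numeric vector of n amplitudes.
#' @export
amplitude_full <- function(p) {
  stopifnot(inherits(p, "osc_params"))
  p$beta / p$alpha
}

#' Per-loop period-MPS shape function f(rho)
#'
#' With equal decay rates and a common threshold ratio the period MPS reduces
#' to `f(rho)/n` where `f(rho) = ((L - g)^2 + 2 g^2) / L^2`,
#' `L = log(rho (1 - rho))`, `g = (1 - 2 rho)/(1 - rho)`. f has a single
#' interior minimum (about 2/3 near rho = 0.596) and diverges as rho -> 1:
#' thresholds close to the attainable maximum make the period fragile.
#'
#' @param rho numeric vector of threshold ratios in (0, 1); values at or
#'   beyond `1 - 1e-12` are a domain error (log overflow guard).
#' @return numeric vector f(rho).
#' @export
f_rho <- function(rho) {
  tm <- rho_terms(rho)
  ((tm$L - tm$g)^2 + 2 * tm$g^2) / tm$L^2
}

#' Closed-form period multiparameter sensitivity
#'
#' `Phi_tau = sum_i ((L_i - g_i)^2 + 2 g_i^2) / alpha_i^2 /
#' (sum_i L_i / alpha_i)^2`; identically the sum of the squared analytic
#' single-parameter sensitivities over all 3n kinetic parameters.
#'
#' @param p an [osc_params()] object with all rho in (0,1).
#' @return positive dimensionless scalar.
#' @export
period_mps_full <- function(p) {
  stopifnot(inherits(p, "osc_params"))
  tm <- rho_terms(rho_ratio(p))
  a <- p$alpha
  sum(((tm$L - tm$g) / a)^2 + 2 * (tm$g / a)^2) / sum(tm$L / a)^2
}

#' Closed-form amplitude multiparameter sensitivity
#'
#' The closed-form amplitude is `beta_i/alpha_i`, a pure power law in two
#' parameters, so its MPS is `(-1)^2 + 1^2 = 2` for every species and every
#' parameter set.
#'
#' @return the constant 2.
#' @export
amplitude_mps_full <- function() {
  2
}

#' Analytic single-parameter sensitivities of the closed-form period
#'
#' Logarithmic derivatives of [period_full()]:
#' `S_alpha_i = (L_i - g_i) / (tau alpha_i)`,
#' `S_beta_i = g_i / (tau alpha_i)`, `S_K_i = -S_beta_i`. At rho = 0.5 the
#' beta and K sensitivities vanish and the alpha sensitivities sum to -1.
#'
#' @param p an [osc_params()] object with all rho in (0,1).
#' @return a `sensitivity_table` data.frame with 3n rows (`parameter`,
#'   `species`, `S`) ordered (alpha_1..alpha_n, beta_1..beta_n, K_1..K_n),
#'   with attributes `output` and `method`.
#' @export
period_sensitivities_analytic <- function(p) {
  stopifnot(inherits(p, "osc_params"))
  tm <- rho_terms(rho_ratio(p))
  tau <- period_full(p)
  s_alpha <- (tm$L - tm$g) / (tau * p$alpha)
  s_beta <- tm$g / (tau * p$alpha)
  sensitivity_table(c(s_alpha, s_beta, -s_beta), n = p$n,
                    output = "period", method = "analytic")
}

#' Analytic single-parameter sensitivities of the closed-form amplitude
#'
#' The amplitude of species i is `beta_i/alpha_i`: its only non-zero
#' sensitivities are -1 with respect to `alpha_i` and +1 with respect to
#' `beta_i`; the thresholds never enter.
#'
#' @param p an [osc_params()] object.
#' @param i species index whose amplitude is the output.
#' @return a `sensitivity_table` data.frame (see
#'   [period_sensitivities_analytic()]).
#' @export
amplitude_sensitivities_analytic <- function(p, i) {
  stopifnot(inherits(p, "osc_params"))
  if (!(i %in% seq_len(p$n))) stop(sprintf("species index out of range 1..%d", p$n))
  s <- numeric(3L * p$n)
  s[i] <- -1
  s[p$n + i] <- 1
  sensitivity_table(s, n = p$n, output = sprintf("amplitude-%d", i),
                    method = "analytic")
}

#' Scan the closed-form period along one kinetic parameter
#'
#' One-dimensional scan for a symmetric n = 3 ring with the other two
#' parameter families fixed at 1: along `alpha` or `K` the scanned value
#' ranges over (0,1) (there rho equals the scanned parameter), along `beta`
#' over (1, upper) since oscillation requires beta > K alpha = 1. The grid
#' argmin is reported as-is; no reference value is asserted for the beta/K
#' scans.
#'
#' @param param which parameter to scan.
#' @param grid scan grid; a sensible default per parameter.
#' @return data.frame with columns `value` and `tau`, with the grid argmin
#'   in attribute `argmin`.
#' @export
period_scan <- function(param = c("alpha", "beta", "K"), grid = NULL) {
  param <- match.arg(param)
  if (is.null(grid)) {
    grid <- switch(param,
                   alpha = seq(0.01, 0.99, by = 0.001),
                   beta = seq(1.01, 10, by = 0.01),
                   K = seq(0.01, 0.99, by = 0.001))
  }
  tau <- vapply(grid, function(v) {
    a <- b <- K <- rep(1, 3)
    if (param == "alpha") a <- rep(v, 3)
    if (param == "beta") b <- rep(v, 3)
    if (param == "K") K <- rep(v, 3)
    period_full(osc_params(a, b, K))
  }, numeric(1))
  out <- data.frame(value = grid, tau = tau)
  attr(out, "argmin") <- grid[which.min(tau)]
  out
}

#' Locate the robustness-relevant minima of the closed forms
#'
#' Three bracketed scalar minimizations (tolerance 1e-6):
#' \enumerate{
#'   \item the minimum of the shape function [f_rho()] over (0,1),
#'   \item the implied minimum of the period MPS for n = 3 with equal decay
#'     rates and a common rho (`f(rho)/3`),
#'   \item the minimizer of the period viewed as a function of the decay
#'     rate alpha with beta = K = 1 (so rho = alpha),
#'     `tau(alpha) = -3 log(alpha (1 - alpha)) / alpha`; at the minimum the
#'     alpha-sensitivity vanishes, i.e. `log(rho(1-rho)) = (1-2rho)/(1-rho)`.
#' }
#'
#' @return list with `rho_min_mps` (argmin of f), `f_min` (its value),
#'   `mps_min_n3` (`f_min / 3`), and `rho_min_period_vs_alpha`.
#' @export
find_rho_minima <- function() {
  of <- stats::optimize(f_rho, c(1e-9, 1 - 1e-9), tol = 1e-6)
  tau_alpha <- function(a) -3 * log(a * (1 - a)) / a
  ot <- stats::optimize(tau_alpha, c(1e-9, 1 - 1e-9), tol = 1e-6)
  list(rho_min_mps = of$minimum,
       f_min = of$objective,
       mps_min_n3 = of$objective / 3,
       rho_min_period_vs_alpha = ot$minimum)
}
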