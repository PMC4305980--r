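#' Integral constants of the limit cycle
#'
#' On the rising phase of species i the exact solution is
#' `x_i(t) = beta_i/alpha_i + C_i1 * exp(-alpha_i * (t - t0))` and on the
#' falling phase `x_i(t) = C_i2 * exp(-alpha_i * (t - t0))`; the 2n constants
#' `C_i1 < 0`, `C_i2 > 0` are fixed by requiring the phases of all species to
#' close into one periodic orbit. Two derived ratios appear throughout:
#' `gamma_i = (K_i - beta_i/alpha_i) / C_i1` and `delta_i = K_i / C_i2`, both
#' in (0,1) on the oscillatory branch. Geometrically `C_i2` is the peak of
#' species i and `beta_i/alpha_i + C_i1` its trough.
#'
#' @param C1 numeric vector of n rising-phase constants (negative).
#' @param C2 numeric vector of n falling-phase constants (positive).
#' @param residual_norm scaled residual norm achieved by the solver (0 for
#'   constants constructed directly).
#' @return object of class `integral_constants` with fields `C1`, `C2` and
#'   `residual_norm` (`gamma`/`delta` are computed against a parameter set
#'   by [gamma_delta()]).
#' @export
integral_constants <- function(C1, C2, residual_norm = NA_real_) {
  stopifnot(length(C1) == length(C2))
  structure(list(C1 = as.numeric(C1), C2 = as.numeric(C2),
                 residual_norm = residual_norm),
            class = "integral_constants")
}

#' Ratios gamma and delta implied by a set of integral constants
#'
#' @param p an [osc_params()] object.
#' @param C an [integral_constants()] object.
#' @param check error out when a ratio leaves (0, 1)? The cycle-closure
#'   equations raise gamma and delta to real powers, so they are only defined
#'   on that domain.
#' @return list with numeric vectors `gamma` and `delta`.
#' @export
gamma_delta <- function(p, C, check = TRUE) {
  xmax <- p$beta / p$alpha
  g <- (p$K - xmax) / C$C1
  d <- p$K / C$C2
  if (check && any(!is.finite(g) | !is.finite(d) | g <= 0 | d <= 0)) {
    stop("non-positive gamma or delta: constants left the feasible region")
  }
  list(gamma = g, delta = d)
}

# right-hand sides of the cycle-closure equations:
#   C_i1 = K_i * prod_{j<i} gamma_j^(a_i/a_j) * prod_{j>i} delta_j^(a_i/a_j)
#          - beta_i/alpha_i
#   C_i2 = C_i1 * prod_{j>=i} gamma_j^(a_i/a_j) * prod_{j<i} delta_j^(a_i/a_j)
#          + beta_i/alpha_i
closure_rhs <- function(p, C) {
  n <- p$n
  a <- p$alpha
  xmax <- p$beta / a
  gd <- gamma_delta(p, C)
  lg <- log(gd$gamma)
  ld <- log(gd$delta)
  rhs1 <- numeric(n)
  rhs2 <- numeric(n)
  for (i in seq_len(n)) {
    before <- seq_len(i - 1L)
    after <- if (i < n) (i + 1L):n else integer(0)
    rhs1[i] <- p$K[i] *
      exp(a[i] * (sum(lg[before] / a[before]) + sum(ld[after] / a[after]))) -
      xmax[i]
    rhs2[i] <- C$C1[i] *
      exp(a[i] * (sum(lg[i:n] / a[i:n]) + sum(ld[before] / a[before]))) +
      xmax[i]
  }
  list(C1 = rhs1, C2 = rhs2)
}

#' Defect of the cycle-closure equations
#'
#' Returns the 2n residuals (current constants minus the closure right-hand
#' sides); the vector is zero exactly at the true limit-cycle constants.
#'
#' @param p an [osc_params()] object (must be oscillatory).
#' @param C an [integral_constants()] object.
#' @return numeric vector of length 2n, ordered (C_11..C_n1, C_12..C_n2).
#' @export
constants_residual <- function(p, C) {
  stopifnot(inherits(p, "osc_params"))
  rhs <- closure_rhs(p, C)
  c(C$C1 - rhs$C1, C$C2 - rhs$C2)
}

# constants implied by observed peaks and troughs (used as a solver fallback
# and as the simulator-side oracle in the tests)
constants_from_cycle <- function(p, peaks, troughs) {
  integral_constants(C1 = troughs - p$beta / p$alpha, C2 = peaks)
}

feasible_constants <- function(p, C1, C2) {
  xmax <- p$beta / p$alpha
  g <- (p$K - xmax) / C1
  d <- p$K / C2
  all(is.finite(g) & is.finite(d)) && all(g > 0 & g < 1) && all(d > 0 & d < 1)
}

#' Solve the cycle-closure equations for the integral constants
#'
#' Damped Newton iteration with a finite-difference Jacobian on the 2n
#' residuals of [constants_residual()]. Steps are halved until the iterate
#' keeps every gamma and delta inside (0,1) and does not increase the
#' residual norm. The initial guess is the saturating closed-form limit
#' `C_i1 = -beta_i/alpha_i`, `C_i2 = beta_i/alpha_i` (exact trough 0, peak
#' `beta_i/alpha_i`); if Newton fails from there, a second attempt starts
#' from constants implied by a short event-driven simulation.
#'
#' @param p an [osc_params()] object; must satisfy both oscillation
#'   conditions.
#' @param tol convergence tolerance on the scaled residual norm
#'   `max(|residual| / max(1, |C|))`.
#' @param max_iter Newton iteration cap per attempt.
#' @return an [integral_constants()] object with `residual_norm <= tol` and
#'   an `iterations` attribute.
#' @export
solve_constants <- function(p, tol = 1e-12, max_iter = 60L) {
  stopifnot(inherits(p, "osc_params"))
  v <- validate_params(p)
  if (!v$oscillatory) {
    stop(paste("parameters are not oscillatory:",
               paste(v$diagnostics, collapse = "; ")))
  }
  xmax <- p$beta / p$alpha
  attempt <- function(z0) newton_constants(p, z0, tol, max_iter)

  res <- attempt(c(-xmax, xmax))
  if (is.null(res)) {
    sim <- simulate_ring(p, tol = 1e-6)
    if (sim$cycle$converged) {
      Cs <- constants_from_cycle(p, sim$cycle$peaks, sim$cycle$troughs)
      res <- attempt(c(Cs$C1, Cs$C2))
    }
  }
  if (is.null(res)) {
    stop("Newton iteration failed to converge on the cycle-closure system ",
         "from both the closed-form and the simulator-derived initial guess")
  }
  res
}

newton_constants <- function(p, z, tol, max_iter) {
  n <- p$n
  unpack <- function(z) integral_constants(z[seq_len(n)], z[n + seq_len(n)])
  resid <- function(z) constants_residual(p, unpack(z))
  scaled_norm <- function(r, z) max(abs(r) / pmax(1, abs(z)))
  if (!feasible_constants(p, z[seq_len(n)], z[n + seq_len(n)])) return(NULL)
  r <- resid(z)
  for (it in seq_len(max_iter)) {
    nrm <- scaled_norm(r, z)
    if (nrm <= tol) {
      out <- unpack(z)
      out$residual_norm <- nrm
      attr(out, "iterations") <- it - 1L
      return(out)
    }
    J <- matrix(0, 2L * n, 2L * n)
    for (k in seq_len(2L * n)) {
      h <- 1e-7 * max(abs(z[k]), 1e-8)
      zk <- z
      zk[k] <- zk[k] + h
      J[, k] <- (resid(zk) - r) / h
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    accepted <- FALSE
    for (halve in 1:40) {
      zt <- z - lambda * step
      if (feasible_constants(p, zt[seq_len(n)], zt[n + seq_len(n)])) {
        rt <- resid(zt)
        if (scaled_norm(rt, zt) < nrm) {
          z <- zt
          r <- rt
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!accepted) return(NULL)
  }
  nrm <- scaled_norm(r, z)
  if (nrm <= tol) {
    out <- unpack(z)
    out$residual_norm <- nrm
    attr(out, "iterations") <- max_iter
    return(out)
  }
  NULL
}

#' Limit-cycle period from solved integral constants
#'
#' `tau = -sum(log(gamma_i * delta_i) / alpha_i)`: the sum of per-species
#' rise and fall interval times.
#'
#' @param p an [osc_params()] object.
#' @param C solved [integral_constants()]; solved internally when omitted.
#' @return positive scalar period.
#' @export
period_semi <- function(p, C = solve_constants(p)) {
  gd <- gamma_delta(p, C)
  -sum(log(gd$gamma * gd$delta) / p$alpha)
}

#' Limit-cycle amplitudes from solved integral constants
#'
#' `eps_i = C_i1 * (prod_{j>=i} gamma_j^(a_i/a_j) * prod_{j<i}
#' delta_j^(a_i/a_j) - 1)`, the peak-minus-trough of species i.
#'
#' @inheritParams period_semi
#' @return numeric vector of n positive amplitudes.
#' @export
amplitude_semi <- function(p, C = solve_constants(p)) {
  n <- p$n
  a <- p$alpha
  gd <- gamma_delta(p, C)
  lg <- log(gd$gamma)
  ld <- log(gd$delta)
  eps <- numeric(n)
  for (i in seq_len(n)) {
    before <- seq_len(i - 1L)
    prod_i <- exp(a[i] * (sum(lg[i:n] / a[i:n]) + sum(ld[before] / a[before])))
    eps[i] <- C$C1[i] * (prod_i - 1)
  }
  eps
}

#' Per-interval rise and fall times of the limit cycle
#'
#' `tau_rise[i] = -log(gamma_i)/alpha_i` is the time species i spends rising
#' from its trough to K_i; `tau_fall[i] = -log(delta_i)/alpha_i` the time
#' falling from its peak to K_i. Their grand sum is the period.
#'
#' @inheritParams period_semi
#' @return list with numeric vectors `tau_rise` and `tau_fall`.
#' @export
cycle_times <- function(p, C = solve_constants(p)) {
  gd <- gamma_delta(p, C)
  list(tau_rise = -log(gd$gamma) / p$alpha,
       tau_fall = -log(gd$delta) / p$alpha)
}
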