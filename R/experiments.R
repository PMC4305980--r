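# Scripted validation experiments: random-parameter sweeps comparing the
# three solution tiers (event-driven simulation, semi-analytical constants,
# closed forms), the loop-length robustness law, and the rho minima.

#' Draw a random oscillatory parameter set
#'
#' `alpha_i` and `beta_i` are uniform on (0, 1) and each threshold `K_i` is
#' uniform on (0, beta_i/alpha_i), so every draw satisfies both oscillation
#' conditions by construction and the threshold ratios rho_i are uniform on
#' (0, 1).
#'
#' @param n loop length (>= 3).
#' @param seed optional integer seed; the same seed reproduces the same
#'   draw. When `NULL` the current RNG stream is used.
#' @return an [osc_params()] object.
#' @export
random_params <- function(n, seed = NULL) {
  if (n < 3L) stop("random oscillatory parameter sets require n >= 3")
  if (!is.null(seed)) set.seed(as.integer(seed))
  alpha <- stats::runif(n)
  beta <- stats::runif(n)
  K <- stats::runif(n) * beta / alpha
  osc_params(alpha, beta, K)
}

join_vec <- function(x) paste(format(x, digits = 17, trim = TRUE),
                              collapse = ";")

#' Finite-difference MPS of all semi-analytical outputs at once
#'
#' The period and the n amplitudes share the same solved integral constants,
#' so one constants solve per perturbed parameter set (3n + 1 in total)
#' yields every sensitivity. Perturbations that lose the oscillation
#' propagate as errors.
#'
#' @param p an [osc_params()] object.
#' @param delta_fraction relative finite-difference step.
#' @return list with `phi_tau` (period MPS), `phi_eps` (n amplitude MPSs)
#'   and `S`, the 3n x (n+1) matrix of sensitivities (outputs in columns:
#'   period, amplitude 1..n).
#' @export
mps_semi_all <- function(p, delta_fraction = 1e-3) {
  stopifnot(inherits(p, "osc_params"))
  n <- p$n
  eval_all <- function(q) {
    C <- solve_constants(q)
    c(period_semi(q, C), amplitude_semi(q, C))
  }
  base <- eval_all(p)
  ld <- log1p(delta_fraction)
  S <- matrix(NA_real_, 3L * n, n + 1L,
              dimnames = list(param_labels(n),
                              c("period", paste0("amplitude", seq_len(n)))))
  for (k in seq_len(3L * n)) {
    qk <- eval_all(perturbed_params(p, k, 1 + delta_fraction))
    S[k, ] <- (log(qk) - log(base)) / ld
  }
  list(phi_tau = sum(S[, 1L]^2),
       phi_eps = colSums(S[, -1L, drop = FALSE]^2),
       S = S)
}

#' Three-tier validation sweep over random parameter sets
#'
#' For each of `sets_per_n` seeded random draws at every loop length in
#' `n_values`, computes the period and amplitudes with all three tiers —
#' exact event-driven simulation, the semi-analytical constants solver, and
#' the closed forms — plus, optionally, the period/amplitude MPS for the
#' semi-analytical tier (finite-difference) and the closed-form tier
#' (analytic). Per-record failures (solver or simulator non-convergence) are
#' recorded in `status` and never abort the sweep.
#'
#' @param n_values integer vector of loop lengths (each >= 3).
#' @param sets_per_n random parameter sets per loop length.
#' @param seed integer master seed; draws are reproducible per (n, set).
#' @param with_mps also compute finite-difference MPS of the semi-analytical
#'   period plus the closed-form MPS? (3n + 1 extra solves per record).
#' @param delta_fraction relative step for finite-difference MPS.
#' @param sim_tol relative convergence tolerance passed to [simulate_ring()].
#' @param out optional TSV path; written with full precision so identical
#'   seeds reproduce identical files.
#' @return data.frame with one row per parameter set: identifiers, tier
#'   periods `tau_sim`/`tau_semi`/`tau_full`, `;`-joined amplitude vectors,
#'   pairwise relative-deviation summaries (`dev_*`), optional MPS columns,
#'   and `status` (`ok`, `sim_fail`, `solver_fail`).
#' @export
run_sweep <- function(n_values, sets_per_n = 200L, seed = 1L, with_mps = FALSE,
                      delta_fraction = 1e-3, sim_tol = 1e-10, out = NULL) {
  stopifnot(sets_per_n >= 1L)
  rows <- list()
  for (n in n_values) {
    for (k in seq_len(sets_per_n)) {
      draw_seed <- as.integer(seed) + 7919L * match(n, n_values) + k
      p <- random_params(n, seed = draw_seed)
      row <- list(seed = draw_seed, n = n, set = k,
                  alpha = join_vec(p$alpha), beta = join_vec(p$beta),
                  K = join_vec(p$K),
                  tau_sim = NA_real_, tau_semi = NA_real_,
                  tau_full = NA_real_,
                  eps_sim = NA_character_, eps_semi = NA_character_,
                  eps_full = NA_character_,
                  dev_tau_semi_sim = NA_real_, dev_eps_semi_sim = NA_real_,
                  dev_tau_full_semi = NA_real_, dev_eps_full_semi = NA_real_,
                  status = "ok")
      if (with_mps) {
        row <- c(row, list(mps_tau_semi = NA_real_, mps_tau_full = NA_real_,
                           mps_eps_semi = NA_character_, mps_eps_full = 2))
      }
      sim <- tryCatch(simulate_ring(p, tol = sim_tol),
                      error = function(e) NULL)
      if (is.null(sim) || !sim$cycle$converged) {
        row$status <- "sim_fail"
      } else {
        row$tau_sim <- sim$cycle$period
        row$eps_sim <- join_vec(sim$cycle$amplitude)
      }
      C <- tryCatch(solve_constants(p), error = function(e) NULL)
      if (is.null(C)) {
        row$status <- if (row$status == "ok") "solver_fail" else row$status
      } else {
        row$tau_semi <- period_semi(p, C)
        eps_semi <- amplitude_semi(p, C)
        row$eps_semi <- join_vec(eps_semi)
        row$tau_full <- period_full(p)
        eps_full <- amplitude_full(p)
        row$eps_full <- join_vec(eps_full)
        row$dev_tau_full_semi <- abs(row$tau_full - row$tau_semi) /
          row$tau_semi
        row$dev_eps_full_semi <- max(abs(eps_full - eps_semi) / eps_semi)
        if (row$status == "ok") {
          row$dev_tau_semi_sim <- abs(row$tau_semi - row$tau_sim) /
            row$tau_sim
          row$dev_eps_semi_sim <- max(
            abs(eps_semi - sim$cycle$amplitude) / sim$cycle$amplitude)
        }
        if (with_mps) {
          mp <- tryCatch(mps_semi_all(p, delta_fraction),
                         error = function(e) NULL)
          if (!is.null(mp)) {
            row$mps_tau_semi <- mp$phi_tau
            row$mps_eps_semi <- join_vec(mp$phi_eps)
          }
          row$mps_tau_full <- period_mps_full(p)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (!is.null(out)) {
    utils::write.table(format(df, digits = 17, trim = TRUE), out, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  df
}

#' Agreement statistics of a sweep
#'
#' Median and 95th-percentile relative deviations per loop length for the
#' semi-analytical-vs-simulation and full-vs-semi-analytical tier pairs,
#' computed over records with `status == "ok"`; failure counts are reported
#' alongside.
#'
#' @param sweep a data.frame from [run_sweep()].
#' @return data.frame with one row per loop length.
#' @export
summarize_sweep <- function(sweep) {
  out <- lapply(split(sweep, sweep$n), function(d) {
    ok <- d[d$status == "ok", ]
    q <- function(x, p) stats::quantile(x, p, na.rm = TRUE, names = FALSE)
    data.frame(
      n = d$n[1L], n_sets = nrow(d), n_ok = nrow(ok),
      n_sim_fail = sum(d$status == "sim_fail"),
      n_solver_fail = sum(d$status == "solver_fail"),
      med_dev_tau_semi_sim = q(ok$dev_tau_semi_sim, 0.5),
      p95_dev_tau_semi_sim = q(ok$dev_tau_semi_sim, 0.95),
      med_dev_eps_semi_sim = q(ok$dev_eps_semi_sim, 0.5),
      p95_dev_eps_semi_sim = q(ok$dev_eps_semi_sim, 0.95),
      med_dev_tau_full_semi = q(ok$dev_tau_full_semi, 0.5),
      p95_dev_tau_full_semi = q(ok$dev_tau_full_semi, 0.95),
      med_dev_eps_full_semi = q(ok$dev_eps_full_semi, 0.5),
      p95_dev_eps_full_semi = q(ok$dev_eps_full_semi, 0.95))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$n), , drop = FALSE]
}

#' Loop-length robustness law
#'
#' For the symmetric ring (alpha = beta = 1, K = 0.5, so rho = 0.5) the
#' closed forms give `tau = n log 4` and `Phi_tau = 1/n`: lengthening the
#' loop lengthens the period and spreads the time delay over more reactions,
#' lowering the period MPS. Optionally cross-checks the period against the
#' exact simulator.
#'
#' @param n_values integer vector of loop lengths (>= 3).
#' @param with_sim also run the event-driven simulator per n?
#' @return data.frame with columns `n`, `tau_full`, `phi_tau_full` and
#'   (optionally) `tau_sim`.
#' @export
loop_length_study <- function(n_values = 3:10, with_sim = FALSE) {
  res <- data.frame(
    n = as.integer(n_values),
    tau_full = vapply(n_values, function(n) {
      period_full(osc_params(rep(1, n), rep(1, n), rep(0.5, n)))
    }, numeric(1)),
    phi_tau_full = vapply(n_values, function(n) {
      period_mps_full(osc_params(rep(1, n), rep(1, n), rep(0.5, n)))
    }, numeric(1)))
  if (with_sim) {
    res$tau_sim <- vapply(n_values, function(n) {
      p <- osc_params(rep(1, n), rep(1, n), rep(0.5, n))
      sim <- simulate_ring(p)
      if (sim$cycle$converged) sim$cycle$period else NA_real_
    }, numeric(1))
  }
  res
}

#' Summary of the closed-form robustness minima
#'
#' Formats the output of [find_rho_minima()]: the threshold ratio minimizing
#' the period-MPS shape function, the resulting minimal period MPS at n = 3,
#' and the threshold ratio at which the period (as a function of the decay
#' rate, beta = K = 1) is minimal.
#'
#' @return data.frame with columns `quantity` and `value`.
#' @export
minima_report <- function() {
  m <- find_rho_minima()
  data.frame(
    quantity = c("rho at minimal period MPS",
                 "minimal f(rho)",
                 "minimal period MPS (n = 3, equal alpha)",
                 "rho at minimal period vs alpha (n = 3, beta = K = 1)"),
    value = c(m$rho_min_mps, m$f_min, m$mps_min_n3,
              m$rho_min_period_vs_alpha))
}
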