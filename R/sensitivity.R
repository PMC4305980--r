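# Generic sensitivity / MPS machinery: works on any scalar evaluator
# q(p) > 0 over the 3n-dimensional kinetic parameter vector
# (alpha_1..alpha_n, beta_1..beta_n, K_1..K_n).

param_labels <- function(n) {
  c(paste0("alpha", seq_len(n)), paste0("beta", seq_len(n)),
    paste0("K", seq_len(n)))
}

sensitivity_table <- function(S, n, output, method,
                              delta_fraction = NA_real_) {
  stopifnot(length(S) == 3L * n)
  df <- data.frame(parameter = param_labels(n),
                   species = rep(seq_len(n), 3L),
                   S = as.numeric(S))
  attr(df, "output") <- output
  attr(df, "method") <- method
  attr(df, "delta_fraction") <- delta_fraction
  class(df) <- c("sensitivity_table", "data.frame")
  df
}

#' Export a sensitivity table as TSV
#'
#' One row per kinetic parameter with columns `parameter`, `species`,
#' `output`, `S`, `method`.
#'
#' @param tab a `sensitivity_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_sensitivities <- function(tab, path) {
  df <- data.frame(parameter = tab$parameter, species = tab$species,
                   output = attr(tab, "output"), S = tab$S,
                   method = attr(tab, "method"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

perturbed_params <- function(p, param_index, factor) {
  n <- p$n
  if (!(param_index %in% seq_len(3L * n))) {
    stop(sprintf("param_index out of range 1..%d", 3L * n))
  }
  a <- p$alpha
  b <- p$beta
  K <- p$K
  i <- ((param_index - 1L) %% n) + 1L
  block <- (param_index - 1L) %/% n
  if (block == 0L) a[i] <- a[i] * factor
  else if (block == 1L) b[i] <- b[i] * factor
  else K[i] <- K[i] * factor
  osc_params(a, b, K)
}

eval_output <- function(evaluator, p, label) {
  q <- tryCatch(evaluator(p), error = function(e) {
    stop(sprintf("evaluator failed at %s: %s", label, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.finite(q) || q <= 0) {
    stop(sprintf("evaluator returned a non-positive value at %s", label),
         call. = FALSE)
  }
  q
}

#' Finite-difference logarithmic sensitivity of a scalar output
#'
#' One-sided difference on the log-log scale,
#' `S = (log q(p') - log q(p)) / (log(p_i + dp_i) - log p_i)` with
#' `dp_i = delta_fraction * p_i` (default 1e-3). For an output that is a pure
#' power of the parameter the log-difference is exact for any step size. A
#' central variant (geometric two-sided step) is available but not the
#' default.
#'
#' @param evaluator function of one [osc_params()] argument returning a
#'   positive scalar (e.g. `period_full`, or a semi-analytical or simulated
#'   period). Failures on the perturbed set (e.g. oscillation lost) propagate
#'   as errors with parameter context: a sensitivity is undefined across the
#'   bifurcation, so out-of-domain perturbations are never clamped.
#' @param p an [osc_params()] object.
#' @param param_index index 1..3n into (alpha_1..alpha_n, beta_1..beta_n,
#'   K_1..K_n).
#' @param delta_fraction relative step, in (0, 0.1].
#' @param central use a symmetric step `p_i * delta^(+-1)`? Default FALSE.
#' @return scalar sensitivity.
#' @export
sensitivity_fd <- function(evaluator, p, param_index, delta_fraction = 1e-3,
                           central = FALSE) {
  stopifnot(inherits(p, "osc_params"),
            delta_fraction > 0, delta_fraction <= 0.1)
  lab <- param_labels(p$n)[param_index]
  if (central) {
    qp <- eval_output(evaluator, perturbed_params(p, param_index,
                                                  1 + delta_fraction),
                      paste0(lab, " (up)"))
    qm <- eval_output(evaluator, perturbed_params(p, param_index,
                                                  1 / (1 + delta_fraction)),
                      paste0(lab, " (down)"))
    return((log(qp) - log(qm)) / (2 * log1p(delta_fraction)))
  }
  q0 <- eval_output(evaluator, p, "the unperturbed parameters")
  q1 <- eval_output(evaluator, perturbed_params(p, param_index,
                                                1 + delta_fraction), lab)
  (log(q1) - log(q0)) / log1p(delta_fraction)
}

#' Multiparameter sensitivity (MPS) of a scalar output
#'
#' Computes all 3n finite-difference sensitivities and returns their squared
#' sum, which measures the fragility of the output under small, random,
#' simultaneous fluctuations of every kinetic parameter.
#'
#' @inheritParams sensitivity_fd
#' @return list with `phi` (the MPS) and `table` (a `sensitivity_table`).
#' @export
mps <- function(evaluator, p, delta_fraction = 1e-3, central = FALSE) {
  stopifnot(inherits(p, "osc_params"))
  q0 <- eval_output(evaluator, p, "the unperturbed parameters")
  labs <- param_labels(p$n)
  ld <- log1p(delta_fraction)
  S <- vapply(seq_len(3L * p$n), function(k) {
    if (central) {
      sensitivity_fd(evaluator, p, k, delta_fraction, central = TRUE)
    } else {
      q1 <- eval_output(evaluator,
                        perturbed_params(p, k, 1 + delta_fraction), labs[k])
      (log(q1) - log(q0)) / ld
    }
  }, numeric(1))
  tab <- sensitivity_table(S, n = p$n, output = "user",
                           method = if (central) "central-difference"
                                    else "finite-difference",
                           delta_fraction = delta_fraction)
  list(phi = sum(S^2), table = tab)
}

#' Squared-sum MPS of an analytic sensitivity table
#'
#' @param tab a `sensitivity_table`.
#' @return scalar sum of squared sensitivities.
#' @export
mps_from_table <- function(tab) {
  sum(tab$S^2)
}

#' Monte-Carlo normalized output variance
#'
#' Perturbs the log of every kinetic parameter independently with zero-mean
#' uniform noise of standard deviation `sigma`, evaluates the output for each
#' sample, and returns `Var(log q)` normalized by the realized input
#' variance. In the small-noise (linear) regime this equals the MPS, giving
#' an independent stochastic check of the squared-sensitivity sum.
#'
#' @inheritParams sensitivity_fd
#' @param sigma standard deviation of the log-scale noise (<= 0.01 keeps the
#'   linearization accurate).
#' @param n_samples number of Monte-Carlo samples (>= 1000).
#' @param seed integer seed for reproducibility.
#' @return list with `nv` (normalized variance), `se` (standard error of the
#'   variance estimate, on the normalized scale), `n_fail` (failed
#'   evaluations, at most 1% tolerated), `n_samples`.
#' @export
mc_variance <- function(evaluator, p, sigma = 0.01, n_samples = 10000L,
                        seed = 1L) {
  stopifnot(inherits(p, "osc_params"), sigma > 0, sigma <= 0.01,
            n_samples >= 1000L)
  n <- p$n
  m <- 3L * n
  half <- sigma * sqrt(3) # uniform(-half, half) has sd sigma
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  noise <- matrix(stats::runif(n_samples * m, -half, half), n_samples, m)
  base <- c(p$alpha, p$beta, p$K)
  lq <- rep(NA_real_, n_samples)
  for (k in seq_len(n_samples)) {
    pv <- base * exp(noise[k, ])
    pk <- osc_params(pv[seq_len(n)], pv[n + seq_len(n)], pv[2L * n + seq_len(n)])
    q <- tryCatch(evaluator(pk), error = function(e) NA_real_)
    if (is.finite(q) && q > 0) lq[k] <- log(q)
  }
  n_fail <- sum(is.na(lq))
  if (n_fail > 0.01 * n_samples) {
    stop(sprintf(
      "%d of %d perturbed evaluations failed (> 1%%): noise scale pushes the",
      n_fail, n_samples), " system off the oscillatory branch")
  }
  lq <- lq[!is.na(lq)]
  N <- length(lq)
  v <- stats::var(lq)
  m4 <- mean((lq - mean(lq))^4)
  realized <- stats::var(as.vector(noise))
  list(nv = v / realized,
       se = sqrt(max(m4 - v^2, 0) / N) / realized,
       n_fail = n_fail,
       n_samples = n_samples)
}
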