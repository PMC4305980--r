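#' Construct a negative-feedback oscillator parameter set
#'
#' Represents the kinetic parameters of an n-species ring in which species i
#' activates species i+1 and the last species represses the first. Species i
#' is produced at rate `beta[i]` while its regulator is on the permissive side
#' of the threshold, and decays with first-order rate constant `alpha[i]`.
#' `K[i]` is the threshold at which species i switches production of its
#' target on or off.
#'
#' Concentrations and times are dimensionless: no unit system is imposed.
#' Species indices are 1-based throughout the public interface.
#'
#' @param alpha numeric vector of n decay rate constants (1/time), all > 0.
#' @param beta numeric vector of n production rate constants
#'   (concentration/time), all > 0.
#' @param K numeric vector of n switching thresholds (concentration), all > 0.
#' @return An object of class `osc_params` with fields `n`, `alpha`, `beta`,
#'   `K`.
#' @examples
#' p <- osc_params(alpha = c(1, 1, 1), beta = c(1, 1, 1), K = c(0.5, 0.5, 0.5))
#' validate_params(p)$oscillatory
#' @export
osc_params <- function(alpha, beta, K) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  K <- as.numeric(K)
  n <- length(alpha)
  if (n < 1L) stop("need at least one species")
  if (length(beta) != n || length(K) != n) {
    stop(sprintf("length mismatch: alpha has %d entries, beta %d, K %d",
                 n, length(beta), length(K)))
  }
  for (fld in c("alpha", "beta", "K")) {
    v <- get(fld)
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf("%s[%d] must be a positive finite number (got %s)",
                   fld, bad[1L], format(v[bad[1L]])))
    }
  }
  structure(list(n = n, alpha = alpha, beta = beta, K = K),
            class = "osc_params")
}

#' @export
print.osc_params <- function(x, ...) {
  cat(sprintf("Negative-feedback oscillator, n = %d species\n", x$n))
  df <- data.frame(i = seq_len(x$n), alpha = x$alpha, beta = x$beta, K = x$K,
                   rho = rho_ratio(x))
  print(df, row.names = FALSE)
  v <- validate_params(x)
  cat(if (v$oscillatory) "oscillatory: yes\n" else
    paste0("oscillatory: no (", paste(v$diagnostics, collapse = "; "), ")\n"))
  invisible(x)
}

#' Check the oscillation conditions
#'
#' The ring sustains a limit cycle iff the loop length is at least 3 and every
#' threshold is attainable, i.e. `K[i] < beta[i]/alpha[i]` for all i
#' (equivalently every threshold ratio rho lies in (0,1)).
#'
#' @param p an [osc_params()] object.
#' @return A list with `oscillatory` (logical) and `diagnostics`, a character
#'   vector naming every violated condition (empty when oscillatory).
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "osc_params"))
  diagnostics <- character()
  if (p$n < 3L) {
    diagnostics <- c(diagnostics, sprintf(
      "loop length n = %d < 3: a ring this short cannot sustain oscillations",
      p$n))
  }
  xmax <- p$beta / p$alpha
  bad <- which(p$K >= xmax)
  for (i in bad) {
    diagnostics <- c(diagnostics, sprintf(
      "K[%d] = %g is not below the attainable maximum beta/alpha = %g",
      i, p$K[i], xmax[i]))
  }
  list(oscillatory = length(diagnostics) == 0L, diagnostics = diagnostics)
}

#' Unit step function
#'
#' `theta_step(a, b)` is 0 when a < b and 1 when a >= b; an exact tie counts
#' as "on". This is the sharp limit of a sigmoidal (Hill) regulation
#' function, with the threshold playing the role of the half-maximum
#' concentration.
#'
#' @param a,b non-negative numerics (vectorized).
#' @return 0/1 integer vector.
#' @export
theta_step <- function(a, b) {
  as.integer(a >= b)
}

#' Threshold ratio rho
#'
#' `rho[i] = K[i] * alpha[i] / beta[i]` is the threshold expressed as a
#' fraction of the maximal attainable concentration `beta[i]/alpha[i]`. It
#' must lie in (0,1) for oscillation and is the key determinant of period
#' robustness.
#'
#' @param p an [osc_params()] object.
#' @param i optional species index (1-based); when omitted the full vector is
#'   returned.
#' @return numeric scalar or vector of threshold ratios.
#' @export
rho_ratio <- function(p, i = NULL) {
  stopifnot(inherits(p, "osc_params"))
  r <- p$K * p$alpha / p$beta
  if (is.null(i)) return(r)
  if (!all(i %in% seq_len(p$n))) {
    stop(sprintf("species index out of range 1..%d", p$n))
  }
  r[i]
}

#' Regulation state implied by a concentration vector
#'
#' Returns the vector s of production switches: `s[1] = theta_step(K[n],
#' x[n])` (the last species represses the first) and `s[i] =
#' theta_step(x[i-1], K[i-1])` for i > 1 (each species activates its
#' successor).
#'
#' @param p an [osc_params()] object.
#' @param x numeric vector of n non-negative concentrations.
#' @return integer 0/1 vector of length n.
#' @export
regulation_state <- function(p, x) {
  stopifnot(inherits(p, "osc_params"))
  if (length(x) != p$n) {
    stop(sprintf("x has %d entries but the model has n = %d species",
                 length(x), p$n))
  }
  if (any(!is.finite(x) | x < 0)) stop("concentrations must be finite and >= 0")
  n <- p$n
  s <- integer(n)
  s[1L] <- theta_step(p$K[n], x[n])
  if (n > 1L) s[-1L] <- theta_step(x[-n], p$K[-n])
  s
}

#' Read oscillator parameters from a JSON file
#'
#' The file must contain fields `alpha`, `beta` and `K` (and optionally `n`,
#' which is checked against the vector lengths). Length mismatches and
#' non-positive entries are rejected.
#'
#' @param path path to a JSON parameter file.
#' @return an [osc_params()] object.
#' @export
read_osc_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("alpha", "beta", "K")) {
    if (is.null(obj[[fld]])) stop(sprintf("parameter file lacks field '%s'", fld))
  }
  p <- osc_params(obj$alpha, obj$beta, obj$K)
  if (!is.null(obj$n) && as.integer(obj$n) != p$n) {
    stop(sprintf("declared n = %s does not match vector length %d",
                 obj$n, p$n))
  }
  p
}

#' Write oscillator parameters to a JSON file
#'
#' @param p an [osc_params()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_osc_params <- function(p, path) {
  stopifnot(inherits(p, "osc_params"))
  jsonlite::write_json(list(n = p$n, alpha = p$alpha, beta = p$beta, K = p$K),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
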