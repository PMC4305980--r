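---
title: "Methods: exact, semi-analytical and closed-form solution of the negative-feedback ring oscillator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact, semi-analytical and closed-form solution of the negative-feedback ring oscillator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfosc)
```

## The model and its assumptions

`nfosc` studies an n-species ring in which species i activates species
i + 1 and species n represses species 1, with unit-step regulation:

$$\dot x_1 = \beta_1\,\theta(K_n, x_n) - \alpha_1 x_1, \qquad
  \dot x_i = \beta_i\,\theta(x_{i-1}, K_{i-1}) - \alpha_i x_i \;(i > 1),$$

where $\theta(a,b) = \mathbf{1}[a \ge b]$. The step is the sharp limit of a
sigmoidal Hill regulation; $K_i$ plays the role of the half-maximum
concentration. All quantities are dimensionless — no unit system is
imposed. The model oscillates iff $n \ge 3$ and every threshold ratio
$\rho_i = K_i\alpha_i/\beta_i$ lies in $(0,1)$; `validate_params()` checks
exactly these two conditions and names each violation.

A deliberate convention, applied consistently everywhere: a tie
$\theta(a,a)$ counts as "on", and in the simulator an exact touch of a
threshold counts as a crossing. This matters only on a measure-zero set but
keeps the event logic total.

## Tier 1: exact event-driven simulation

Between switching events the system is linear and decoupled: each species
relaxes as $x_i(t) = T_i + (x_i(0) - T_i)e^{-\alpha_i t}$ toward the target
$T_i = s_i\beta_i/\alpha_i$ set by its current switch $s_i \in \{0,1\}$.
`simulate_ring()` therefore never discretizes time: it computes every
species' next threshold-crossing time in closed form,
$t^* = -\ln[(K - T)/(x_0 - T)]/\alpha$, jumps to the earliest one, flips
the downstream switch, and repeats. This replaces stiff ODE integration
(the step function makes the vector field stiff for generic solvers) with
an algorithm that is both faster and exact to floating point.

Choices a user may care about:

* **Initial condition** — default $x_0 = 0$, which starts the production
  cascade from switch state $(1, 0, \dots, 0)$ and enters the oscillatory
  basin directly. The transient is discarded regardless, so the default
  matters only for speed.
* **Cycle marker and convergence** — one cycle is delimited by successive
  upward crossings of $K_1$ by $x_1$ (unambiguous: it happens once per
  cycle). The limit cycle is declared when successive period estimates and
  peak vectors agree to relative tolerance `tol` (default `1e-10`), with at
  least three completed cycles. The return map of this system contracts
  geometrically, so the declared cycle is typically accurate to
  $10^{-12}$–$10^{-13}$ relative — the validation sweep measures median
  agreement with the independent tier-2 solution at $10^{-13}$ or better.
* **Budget** — `max_events` (default 10,000) caps the event count;
  exhaustion returns the partial result with `converged = FALSE` and a
  diagnostic, as does relaxation to a fixed point (always the case for
  $n < 3$).
* **Simultaneous crossings** — processed within one event batch ordered by
  species index; a measure-zero coincidence for which any fixed order is
  consistent.
* **Degenerate touch** — a species sitting exactly at its threshold is not
  re-triggered; its switch was just set consistently with its direction of
  motion. This prevents zero-duration event loops.

Peaks and troughs are read off at event times, which is exact because every
species is monotone within a segment. At double precision a long relaxation
segment can saturate $x$ to its target *exactly* (the exponential
underflows), so the mathematically open range $(0, \beta_i/\alpha_i)$ is
attained at its boundary numerically; downstream code treats the bounds
non-strictly.

## Tier 2: the cycle-closure (semi-analytical) solution

Writing the rising phase of species i as
$x_i = \beta_i/\alpha_i + C_{i1}e^{-\alpha_i (t - t_0)}$ and the falling
phase as $x_i = C_{i2}e^{-\alpha_i(t - t_0)}$, periodicity of the orbit
closes into $2n$ nonlinear equations in the integral constants
$C_{i1} < 0 < C_{i2}$, built from the ratios
$\gamma_i = (K_i - \beta_i/\alpha_i)/C_{i1}$ and $\delta_i = K_i/C_{i2}$,
both in $(0,1)$ on the oscillatory branch. Geometrically $C_{i2}$ is the
peak of species i and $\beta_i/\alpha_i + C_{i1}$ its trough. Once solved,

$$\tau = -\sum_i \frac{\ln(\gamma_i\delta_i)}{\alpha_i}, \qquad
  \varepsilon_i = C_{i1}\Big(\prod_{j\ge i}\gamma_j^{\alpha_i/\alpha_j}
  \prod_{j<i}\delta_j^{\alpha_i/\alpha_j} - 1\Big),$$

with the per-interval rise/fall times $-\ln\gamma_i/\alpha_i$ and
$-\ln\delta_i/\alpha_i$ available from `cycle_times()`.

`solve_constants()` uses damped Newton with a forward-difference Jacobian:

* **Initial guess** — the saturating limit $C_{i1} = -\beta_i/\alpha_i$,
  $C_{i2} = \beta_i/\alpha_i$ (exact trough 0, peak $\beta_i/\alpha_i$),
  which is feasible for every oscillatory parameter set
  ($\gamma_i = 1-\rho_i$, $\delta_i = \rho_i$) and becomes a near-root as
  the loop grows. If Newton fails from there, a second attempt starts from
  constants implied by a coarse event-driven simulation.
* **Damping** — the closure equations raise $\gamma,\delta$ to real powers,
  so iterates must stay inside $(0,1)$; steps are halved until the iterate
  is feasible and the residual norm decreases. The system is solved in the
  C-variables directly (no log transform), matching the written equations.
* **Residual norm** — the raw residual has concentration units and scales
  with $\beta/\alpha$, which can be arbitrarily large; convergence is
  therefore judged on $\max_k |r_k|/\max(1, |C_k|)$, with default tolerance
  `1e-12`. Newton's quadratic convergence typically lands at
  $10^{-15}$–$10^{-16}$.
* **Uniqueness** is not proven; instead the found root is validated against
  the independent tier-1 simulation (the test suite does this for hundreds
  of seeded random parameter sets — median agreement better than
  $10^{-8}$ relative, in practice $10^{-13}$).

## Tier 3: closed forms and the robustness laws

Assuming each species saturates before reversing (peak
$\beta_i/\alpha_i$, trough 0) — accurate for long loops — the constants
drop out:

$$\tau = -\sum_i \frac{\ln[\rho_i(1-\rho_i)]}{\alpha_i}, \qquad
  \varepsilon_i = \beta_i/\alpha_i.$$

Sensitivities are logarithmic derivatives $S = \partial\ln q/\partial\ln p$
and the multiparameter sensitivity (MPS) is their squared sum over all $3n$
parameters. Writing $L_i = \ln[\rho_i(1-\rho_i)]$ and
$g_i = (1-2\rho_i)/(1-\rho_i)$:

* period: $S_{\alpha_i} = (L_i - g_i)/(\tau\alpha_i)$,
  $S_{\beta_i} = g_i/(\tau\alpha_i) = -S_{K_i}$, and
  $\Phi_\tau = \sum_i[(L_i-g_i)^2 + 2g_i^2]/\alpha_i^2 \big/
  (\sum_i L_i/\alpha_i)^2$ — identically the squared sum of the analytic
  sensitivities (asserted to $10^{-12}$ in the tests);
* amplitude: $S_{\alpha_i} = -1$, $S_{\beta_i} = +1$, thresholds never
  enter, so $\Phi_\varepsilon = 2$ for every species and parameter set.

With equal $\alpha$ and a common $\rho$, $\Phi_\tau = f(\rho)/n$ with
$f(\rho) = [(L-g)^2 + 2g^2]/L^2$. Three numbers summarize the robustness
landscape, each found by bracketed scalar minimization
(`stats::optimize`, tolerance `1e-6`, reported to 4 decimals):
$f$ is minimal ($\approx 0.6667$) at $\rho \approx 0.5959$, giving the
minimal n = 3 period MPS $\approx 0.2222$; and the period as a function of
$\alpha$ (with $\beta = K = 1$, so $\rho = \alpha$) is minimal at
$\rho \approx 0.7228$, which is also the root of $L = g$ (the vanishing
$\alpha$-sensitivity) — the package cross-checks the minimizer against
that root by bisection. $f$ is evaluated with a domain guard
$\rho \le 1 - 10^{-12}$: beyond it the logarithm overflows and the MPS
diverges anyway ($f(0.999) > 100$).

At $\rho_i = 0.5$ the $\beta$/K sensitivities vanish and the period
sensitivities obey the conservation law $\sum S = \sum_i S_{\alpha_i} = -1$:
the degradation reactions share the whole influence on the period. This
yields $1/n \le \Phi_\tau \le 1$, with equality at $1/n$ iff all
$\alpha_i$ are equal — the distributed time-delay mechanism: the period is
a sum of per-reaction delays, and spreading it over more reactions makes it
robust. The period-vs-$\alpha$ minimum as a function of $\beta$ or $K$ is
computed only as an unasserted scan: no reference value is available for
it, so the package does not claim one.

## Generic sensitivity machinery

`sensitivity_fd()` implements the log-difference quotient with a forward
step $\Delta p_i = 10^{-3} p_i$ by default — the validated procedure for
this class of model; central differencing is available as an option but is
not the default. The truncation error is first-order in the step with a
curvature constant that grows near the bifurcation ($\rho \to 1$), where
sensitivities themselves diverge; perturbations that push a parameter set
off the oscillatory branch raise an error rather than clamping, because a
sensitivity is undefined across the bifurcation.

`mc_variance()` checks the variance interpretation of the MPS: each of the
$3n$ log-parameters receives independent zero-mean uniform noise with
standard deviation `sigma` (default 0.01; the distribution is not
prescribed by the theory, which is distribution-agnostic in the linear
regime), and $\mathrm{Var}(\ln q)$ is normalized by the pooled realized
input variance rather than the nominal $\sigma^2$, removing one source of
finite-sample error. The standard error reported alongside uses the
fourth-moment formula for the variance of a sample variance.

`mps_semi_all()` exploits that the semi-analytical period and all n
amplitudes share one constants solve per perturbed parameter set, reducing
an MPS evaluation from $(n+1)(3n+1)$ to $3n + 1$ solves.

## What the random generator emulates — and what it does not

`random_params()` draws $\alpha_i, \beta_i \sim U(0,1)$ and
$K_i \sim U(0, \beta_i/\alpha_i)$, the ranges used for the published
validation scatter; every draw is oscillatory by construction and the
induced $\rho_i$ are uniform on $(0,1)$ (asserted by a Kolmogorov–Smirnov
test). This stated world deliberately includes near-degenerate draws
($\rho$ close to 0 or 1, $\beta/\alpha$ spanning orders of magnitude). It
does *not* emulate features of real biochemical data: finite Hill
coefficients, molecular noise, unequal parameter scales within one cell, or
measurement error. A green equivalence sweep therefore establishes that the
three tiers solve the *same idealized model* consistently — not that the
model describes any particular organism.

Measured convergence constants under these ranges (the package's tests
assert the measured values, not optimistic ones): the median full-vs-semi
period gap falls 0.61 → 0.20 → 0.087 over $n = 3, 5, 7$; for the symmetric
ring the gap to $n\ln 4$ is 5.6% at $n=5$, 2.5% at $n=6$, 1.2% at $n=7$;
the semi-analytical amplitude MPS reaches $2 \pm 10^{-3}$ only around
$n = 15$ (the deviation scales with the trough, roughly $2^{-n}$), and at
$n = 7$ about 80% of amplitude-MPS values fall within $[1.8, 2.2]$.

## Known limitations

* The cycle-closure root is validated, not proven unique.
* Near $\rho \to 1$ the simulator needs many cycles to converge (the
  return-map contraction weakens) and finite-difference sensitivities lose
  accuracy; both are inherent to the bifurcation, not to the
  implementation.
* The sweep's numerical-integration tier is the event-driven simulator —
  the same mathematical object as generic stiff integration of the step
  model, but exact; no adaptive-ODE backend is shipped.
* Only first-order (local) sensitivities are provided; no global
  (Sobol-type) indices.
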