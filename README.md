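# nfosc

Exact, semi-analytical and closed-form solutions for the period, amplitude
and parameter robustness of negative-feedback ring oscillators.

## The problem

Many biological clocks — circadian rhythms, cell cycles, synthetic gene
rings — are built on one structural motif: a cascade of n species in which
each species activates the next and the last represses the first. `nfosc`
studies the idealized (piecewise-linear) version of this motif, in which
regulation is a unit step: species i is produced at rate βᵢ while its
regulator is on the permissive side of a threshold, and decays with rate
constant αᵢ,

    dx₁/dt = β₁·θ(Kₙ, xₙ) − α₁x₁
    dxᵢ/dt = βᵢ·θ(xᵢ₋₁, Kᵢ₋₁) − αᵢxᵢ      (i = 2…n)

with θ(a,b) = 1 if a ≥ b and 0 otherwise. The ring oscillates iff n ≥ 3 and
every threshold is attainable, Kᵢ < βᵢ/αᵢ — equivalently every **threshold
ratio** ρᵢ = Kᵢαᵢ/βᵢ lies in (0,1).

The package answers two kinds of questions:

1. **What are the period τ and amplitudes εᵢ of the limit cycle?** Three
   tiers of increasing approximation:
   - *exact simulation* — between switching events every species relaxes
     exponentially in closed form, so `simulate_ring()` integrates the
     system event-to-event with no discretization error;
   - *semi-analytical* — the cycle closes into 2n nonlinear equations for
     the integral constants Cᵢ₁, Cᵢ₂ of the rising/falling exponential
     phases; `solve_constants()` finds them by damped Newton iteration and
     `period_semi()`/`amplitude_semi()` evaluate
     τ = −Σ ln(γᵢδᵢ)/αᵢ with γᵢ = (Kᵢ−βᵢ/αᵢ)/Cᵢ₁, δᵢ = Kᵢ/Cᵢ₂;
   - *full analytical* — assuming each species saturates (peak βᵢ/αᵢ,
     trough 0), everything is closed-form:
     τ = −Σ ln[ρᵢ(1−ρᵢ)]/αᵢ and εᵢ = βᵢ/αᵢ.
2. **How robust are τ and εᵢ to parameter fluctuations?** Single-parameter
   sensitivities S = ∂ln q/∂ln p and their squared sum, the
   **multiparameter sensitivity** (MPS) Φ — equal to the normalized output
   variance under small simultaneous random perturbations of all 3n kinetic
   parameters. Closed forms: the amplitude MPS is identically 2; the period
   MPS reduces to f(ρ)/n for a symmetric ring, is minimized at ρ ≈ 0.596,
   diverges as ρ → 1, and decreases as 1/n with loop length — the
   distributed time-delay robustness mechanism.

## Worked example

```r
library(nfosc)
p <- osc_params(alpha = c(1, 1, 1), beta = c(1, 1, 1), K = c(0.5, 0.5, 0.5))

sim <- simulate_ring(p)          # exact event-driven integration
print(sim$cycle)
#> Converged limit cycle: period = 2.88727095 (9 transient cycles)
#>   peaks:      0.80901699 0.80901699 0.80901699
#>   troughs:    0.19098301 0.19098301 0.19098301
#>   amplitude:  0.61803399 0.61803399 0.61803399

C <- solve_constants(p)          # cycle-closure constants (Newton)
period_semi(p, C)                # 2.887271  — matches the simulator
period_full(p)                   # 4.158883  = 3 ln 4; saturating approximation
period_mps_full(p)               # 0.3333333 = 1/n at rho = 0.5
amplitude_mps_full()             # 2, for every species and parameter set

minima_report()
#>                                              quantity     value
#>                             rho at minimal period MPS 0.5958925
#>                                        minimal f(rho) 0.6666667
#>               minimal period MPS (n = 3, equal alpha) 0.2222222
#>  rho at minimal period vs alpha (n = 3, beta = K = 1) 0.7228126
```

The simulated and semi-analytical periods agree to ~1e-12 relative (both
are exact for this piecewise-linear model); the closed form overestimates
the period at n = 3 and converges onto the other tiers as the loop grows
(`run_sweep(c(3, 5, 7), sets_per_n = 200)` reproduces this across random
parameter draws). The minima table is the design rule of thumb: keep every
ρᵢ near 0.6 and lengthen the loop to make the period robust.

## Command line

```sh
Rscript -e 'nfosc::nfosc_cli()' simulate --params ring.json --out run
Rscript -e 'nfosc::nfosc_cli()' analyze  --params ring.json
Rscript -e 'nfosc::nfosc_cli()' sweep --n 3,5,7 --sets 200 --seed 1 --out sweep.tsv
Rscript -e 'nfosc::nfosc_cli()' minima
Rscript -e 'nfosc::nfosc_cli()' loop-study --n 3,4,5,6,7 --with-sim
```

Parameter files are JSON: `{"n": 3, "alpha": [1,1,1], "beta": [1,1,1],
"K": [0.5,0.5,0.5]}`. A `--config file.json` can preset any flag.

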