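# pwmalnut

Simulation and analysis of a four-compartment malnutrition model with
*crossover* dynamics: the model's law changes regime over time, from a
classical ODE phase through a fractional-memory phase (power-law,
exponential-decay or Mittag-Leffler kernel, order Λ ∈ (0,1]) to a stochastic
phase with multiplicative white noise.  The package is aimed at
epidemiological modellers who want the published piecewise
Adams–Bashforth/Newton-polynomial scheme family as tested, reusable code
rather than figure-only results.

## The model

Compartments: susceptible females `Sf`, malnourished boys `Mb`, malnourished
girls `Mg`, underweight individuals `U` (person-counts; all rates per day):

```
dSf/dt = (B + ε) − (λ_b·Mb + λ_g·Mg + ϑ)·Sf + δ_g·Mg
dMb/dt = λ_b·Sf·Mb − (ϑ_b + γ_b + ϑ)·Mb + χ_b·U
dMg/dt = λ_g·Sf·Mg − (γ_g + δ_g + ϑ)·Mg + χ_g·U
dU/dt  = γ_b·Mb + γ_g·Mg − (χ_b + χ_g + ϑ)·U
```

with stochastic version `dX_k = drift_k dt + σ_k X_k dW_k`.  Core
quantities: the basic reproduction number `R0` (closed form, plus the
next-generation-matrix spectral radius as a separately reported
cross-check), the stochastic persistence threshold

```
R0^s = λ_g λ_b / [(λ_b+ϑ−σ1²/2)(ϑ_b+γ_b−σ2²/2)(γ_g+δ_g+ϑ−σ3²/2)]
```

(`R0^s > 1` ⇒ unique ergodic stationary distribution), the disease-free
equilibrium `((B+ε)/ϑ, 0, 0, 0)`, a numerically located endemic
equilibrium, and the Lyapunov constants `ψ1..ψ3, ψ5`.

## Worked example

```r
library(pwmalnut)

sc <- baseline_scenario()          # the printed design point
threshold_report(sc)
#> Threshold report: baseline
#>   R0 (closed form)      = 0.07703038674
#>   NGM spectral radius   = 0.0753680565
#>   R0^s                  = 1.125984541
#>   psi1, psi2, psi3      = 0.0558943, 0.0359536, 0.0372881
#>   psi5                  = 0.00132479
#>   classification        = persists
```

`R0 < 1` says the disease-free state is stable for the deterministic model
at these rates, while `R0^s > 1` says the *stochastic* system persists: the
noise-adjusted threshold, not the deterministic one, governs the perturbed
system, and `psi5 > 0` is its Lyapunov-level witness.

A full three-regime run (classical on [0,10], power-law memory with
Λ = 0.95 on [10,20], stochastic on [20,30]):

```r
tr <- piecewise_solve(sc$params, sc$noise, sc$y0,
                      piecewise_schedule(dz = 0.01, T1 = 10, T2 = 20, T = 30),
                      order = 0.95, kernel = "power_law", seed = 7)
tail(tr, 3)
#>       time     regime        Sf         Mb        Mg        U
#> 2999 29.98 stochastic 0.2379751 0.07115735 0.1486212 1.138464
#> 3000 29.99 stochastic 0.2270760 0.07245854 0.1483398 1.097301
#> 3001 30.00 stochastic 0.2376736 0.07072870 0.1511439 1.100881
positivity_check(tr)$clean
#> [1] TRUE
write_trajectory(tr, "baseline_run")   # CSV + JSON metadata sidecar
```

Susceptibles collapse from 30 towards the endemic level within a few days;
the stochastic tail fluctuates around it.  Ensembles and stationary
diagnostics:

```r
ens <- run_ensemble(sc, piecewise_schedule(0.01, 3, 6, 10),
                    order = 0.95, n_paths = 500, seed = 1)
terminal_histogram(ens, "U", 10, n_bins = 20)   # counts + fitted N(mean, var)
```

A thin CLI over the same functions lives at `inst/cli/pwmalnut-cli.R`
(subcommands `simulate`, `ensemble`, `thresholds`, `scenarios`), reading the
flat `key = value` configuration format; the packaged baseline file is
`inst/extdata/table1_baseline.cfg`.

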