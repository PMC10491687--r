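---
title: "A piecewise classical–fractional–stochastic malnutrition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A piecewise classical–fractional–stochastic malnutrition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmalnut)
```

## The model

`pwmalnut` simulates a four-compartment model of malnutrition among pregnant
women and their children: susceptible females $S_f$, malnourished boys
$\bar M_b$, malnourished girls $\bar M_g$ and underweight individuals
$\bar U$.  The deterministic field is

$$
\begin{aligned}
\dot S_f &= (B+\epsilon) - (\lambda_b \bar M_b + \lambda_g \bar M_g + \vartheta)S_f + \delta_g \bar M_g,\\
\dot{\bar M}_b &= \lambda_b S_f \bar M_b - (\vartheta_b+\gamma_b+\vartheta)\bar M_b + \chi_b \bar U,\\
\dot{\bar M}_g &= \lambda_g S_f \bar M_g - (\gamma_g+\delta_g+\vartheta)\bar M_g + \chi_g \bar U,\\
\dot{\bar U} &= \gamma_b \bar M_b + \gamma_g \bar M_g - (\chi_b+\chi_g+\vartheta)\bar U,
\end{aligned}
$$

with all rates per day and states as continuous person-counts (the ODE
limit).  Summing the four equations gives the total-population drift
$(B+\epsilon) - \vartheta N - \vartheta_b \bar M_b$, an identity the test
suite checks over $10^4$ random states.  The stochastic variant perturbs
each compartment multiplicatively, $\sigma_k X_k\,dW_k$, with four
independent Brownian motions.

The distinguishing feature is *crossover*: the dynamical law changes regime
over time.  On $[0, T_1]$ the classical ODE applies; on $[T_1, T_2]$ a
fractional-memory operator of order $\Lambda \in (0,1]$ (power-law,
exponential-decay or Mittag-Leffler kernel); on $[T_2, T]$ the stochastic
system.  `piecewise_solve()` integrates the three regimes consecutively,
each initialized at the previous regime's terminal state, so trajectories
are continuous at both interfaces by construction.

## Thresholds

Two threshold quantities summarize long-run behaviour:

* the **basic reproduction number**, evaluated from its closed form
  $$R_0 = \frac{\lambda_g (B+\epsilon)\left[(\vartheta+\vartheta_b)(\vartheta+\chi_b+\chi_g)+\gamma_b(\vartheta+\chi_g)\right]}
  {\vartheta(\vartheta+\vartheta_b)\left[\vartheta(\vartheta+\gamma_g+\delta_g+\chi_b+\chi_g)+\chi_b(\gamma_g+\delta_g)+\chi_g\delta_g\right]};$$
* the **stochastic threshold**
  $$R_0^s = \frac{\lambda_g\lambda_b}{(\lambda_b+\vartheta-\sigma_1^2/2)(\vartheta_b+\gamma_b-\sigma_2^2/2)(\gamma_g+\delta_g+\vartheta-\sigma_3^2/2)},$$
  whose exceedance of 1 is the sufficient condition for a unique ergodic
  stationary distribution (persistence).

The next-generation-matrix route is exposed separately as
`ngm_spectral_radius()`, which builds the published $4\times4$ $F$ and $V$
matrices literally and returns $\rho(FV^{-1})$.  The two published objects
are mutually inconsistent (the closed form contains $\lambda_g$ but not
$\lambda_b$, while $F$ contains both), so the package reproduces both
faithfully and never asserts their equality; the closed form is treated as
the canonical threshold.  At the baseline design point the closed form gives
$R_0 = 0.0770$, the matrix route $0.0754$.

The design-point value of the stochastic threshold deserves a note: with the
baseline rates and $\sigma = (0.08, 0.09, 0.1, 0.12)$ the formula evaluates
to $R_0^s = 1.12598\ldots$, which is $>1$ (persistence), and this is the
number the package reports.  A published companion value of $1.245$ is not
reproducible from the formula at these inputs; since no alternative inputs
are stated, the package computes the formula and does not guess which inputs
produced the other value.

The Lyapunov constants $\psi_1,\psi_2,\psi_3$ (each $(B+\epsilon)$ over one
denominator factor of $R_0^s$) and
$\psi_5 = 4(B+\epsilon)[(R_0^s)^{1/4}-1]$ are exposed as diagnostics;
$\psi_5 > 0$ exactly when $R_0^s > 1$.

```{r thresholds}
threshold_report(baseline_scenario())
```

## Kernel machinery

The Mittag-Leffler function $E_\Lambda(z)=\sum_k z^k/\Gamma(\Lambda k+1)$ is
evaluated by three routes: `exp(z)` at $\Lambda = 1$; direct series with
term-ratio stopping at $10^{-16}$ for $z \ge -1$ (and up to $z = 15$, beyond
which an error is signalled rather than silently losing accuracy); and the
complete-monotonicity spectral integral for $z < -1$, where the alternating
series cancels catastrophically in double precision (at $z=-10$,
$\Lambda=0.3$ the largest term exceeds $10^{40}$ while the sum is
$\approx 0.07$).  The combination agrees with a 50-digit
arbitrary-precision series oracle to better than $10^{-13}$ on
$\Lambda \in \{0.3, 0.5, 0.7, 0.95, 1\}$, $z \in [-10, 3]$.

The operator normalizations are the printed ones: $\bar M(\Lambda) =
2/(2-\Lambda)$ for the exponential-decay kernel — used everywhere even
though it gives $\bar M(1) = 2$, contradicting the accompanying claim
$\bar M(1) = 1$ — and $ABC(\Lambda) = 1-\Lambda+\Lambda/\Gamma(\Lambda)$
for the Mittag-Leffler kernel, with exact endpoints
$ABC(0^+)=ABC(1)=1$.

## Numerical schemes and the choices behind them

All regimes share one multistep family: three-point Newton-polynomial
(Adams–Bashforth-type) quadrature, fully explicit — the value at grid point
$m+1$ uses field values at points $\le m$.

**Classical regime.** Standard AB3 with weights $(23/12, -16/12, 5/12)
\Delta\zeta$.  Empirical order 3 on the linear test, exact on constant
fields (the weights sum to 1).

**Fractional regimes.** The power-law branch accumulates three
$\Im$-weighted history sums with prefactors
$\Delta\zeta^\Lambda/\Gamma(\Lambda+1)$,
$\Delta\zeta^\Lambda/\Gamma(\Lambda+2)$ and
$\Lambda\Delta\zeta^\Lambda/(2\Gamma(\Lambda+3))$, retaining the full
history ($O(n^2)$ work; desk-scale horizons make that acceptable and no
short-memory truncation is used).  Four deliberate numerical choices:

* *Step-size power.* The published scheme carries
  $\Delta\zeta^{\Lambda-1}$; that factor is dimensionally inconsistent
  (at $\Lambda = 1$ every step would add $\Phi \cdot 1$ instead of
  $\Phi\,\Delta\zeta$, and the scheme diverges as the grid is refined).
  The package uses $\Delta\zeta^{\Lambda}$, the factor the quadrature
  derivation of this scheme family produces, which reduces exactly to AB3
  at $\Lambda = 1$.
* *Weight signs.* $\Im_1$ is implemented as
  $(w-\varsigma+1)^\Lambda-(w-\varsigma)^\Lambda$ and $\Im_3$ with its two
  bracketed terms joined by "−".  The published "$-1$" index in $\Im_1$
  raises a negative base to a fractional power at $\varsigma = w$ (complex),
  and the published "+" join in $\Im_3$ makes the weight grow like
  $(w-\varsigma)^{\Lambda+2}$ so the history sum diverges; with "−" the
  $\Lambda=1$ weight is exactly 23 and the branch collapses to the 23/12
  AB3 weight.  Both literal forms remain available behind
  `as_printed`/`weights_as_printed` switches, which error on complex
  output.
* *Startup.* The printed sums begin at $\varsigma = 2$, leaving $y^1, y^2$
  unspecified and the kernel quadrature over the first two grid cells
  uncovered.  The first two steps of every regime are bootstrapped with
  classical RK4 substeps at $\Delta\zeta/10$, and the missing quadrature
  over $[T_1, T_1+2\Delta\zeta]$ is added via exact kernel moments against
  the Lagrange polynomial through $\Phi^0,\Phi^1,\Phi^2$ (Simpson's rule at
  $\Lambda = 1$).  Without the correction the $\Lambda = 1$ branch would
  permanently miss the first two steps' increments.
* *Verification.* On $D^\Lambda y = -y$, $\Lambda = 0.7$, $[0, 2]$, the
  branch is within 1.3% of $E_\Lambda(-t^\Lambda)$ at
  $\Delta\zeta = 10^{-3}$, with error decreasing monotonically under step
  halving (2.97% at $4\times10^{-3}$, 1.92% at $2\times10^{-3}$); the
  residual is dominated by the early-time classical bootstrap, where the
  exact solution has an infinite derivative.

The exponential-decay branch combines a pointwise term
$(1-\Lambda)/\bar M(\Lambda)\,\Phi$ with a
$\Lambda/\bar M(\Lambda)$-scaled AB3 sum.  The pointwise term enters
through its increment between consecutive grid points (equivalently, the
baseline value $\Phi(T_1)$ is subtracted), which is what the operator's own
integral form requires for consistency at the regime start; at
$\Lambda = 1$ the pointwise term vanishes and the branch equals AB3 applied
to the half-field $\Phi/\bar M(1) = \Phi/2$, exactly as the printed
coefficients collapse.

The Mittag-Leffler branch reuses the power-law history machinery scaled by
$\Lambda/ABC(\Lambda)$, plus a pointwise term.  Its published coefficient
is $\Lambda/ABC(\Lambda)$, but the operator's integral carries
$(1-\Lambda)/ABC(\Lambda)$, and only the latter vanishes at $\Lambda = 1$
so that the branch then agrees with the power-law branch to machine
precision — a reduction the package treats as non-negotiable.  The default
is therefore `local_term = "standard"`; the published coefficient is kept
behind `local_term = "as_printed"`, and the two differ by exactly
$(2\Lambda-1)/ABC(\Lambda)\,\Phi$ in each step's pointwise term.

**Stochastic regime.** The deterministic AB3 update plus noise terms
pairing Brownian increments at lags $(\varsigma,\varsigma-1,\varsigma-2)$
with $\sigma_k y_k$ at the same lags and the AB3 weights (each increment is
revisited by three consecutive steps with weights summing to 1, a
consistent discretization of $\int \sigma y\,dW$).  The published backward
summation is re-indexed as a forward recursion from $T_2$; the two
bootstrap steps use the RK4 deterministic bootstrap plus a plain
Euler–Maruyama noise term, since the lagged increments do not yet exist.
With $\sigma = 0$ the branch is bit-identical to the classical one.  An
independent Euler–Maruyama solver (`euler_maruyama_integrate()`, strong
order 0.5, verified on geometric Brownian motion) serves as the
cross-validation oracle.

None of the schemes is positivity-preserving and none clips: negativity is
audited by `positivity_check()`, never enforced, so the theoretical
positivity property can be tested rather than assumed.

## Synthetic data: what the generators emulate

No field data exist for this model; every input is a printed constant.  The
generators therefore emulate the study's design:

* `baseline_scenario()` is the exact printed configuration — rates
  $B=0.01$, $\epsilon=0.001$, $\lambda_b=0.1$, $\lambda_g=0.2$,
  $\vartheta=0.1$, $\vartheta_b=0.3$, $\gamma_b=0.01$, $\gamma_g=0.1$,
  $\chi_b=0.014$, $\chi_g=0.01$, $\delta_g=0.1$ per day, initial state
  $(30, 2, 4, 1)$, $\sigma=(0.08,0.09,0.1,0.12)$.  The placeholders
  $\vartheta_1,\vartheta_2$ appear in the parameter table with range
  $[0,1]$ but in no equation; they are stored (as 0) and never used.
* `brownian_increments()` draws the four independent
  $\mathcal N(0,\Delta\zeta)$ increment sequences, fully reproducible from
  a seed; one root seed spawns per-path subseeds so ensemble members are
  independent yet reproducible.
* `perturbed_scenarios()` multiplies each rate by an independent log-normal
  factor with median 1 and a chosen relative standard deviation.  The
  median-preserving log-normal is this package's choice (the study varies
  nothing around its design point): it preserves positivity by
  construction and makes the baseline the exact median of the ensemble.

Passing tests on these inputs demonstrate internal correctness of the
schemes and thresholds — they cannot demonstrate that the model describes
any real population, since no empirical series enters anywhere.

## Ensemble and ergodicity diagnostics

`run_ensemble()` shares the deterministic prefix across paths, accumulates
per-time moments with Welford's streaming algorithm (cross-checked against
a two-pass computation to $10^{-10}$ in the tests) and keeps the full value
array for order-statistic quantiles (linear interpolation, type 7) and for
`terminal_histogram()`, which reports equal-width bins over the observed
range with moment-fitted normal parameters — the frequency-plot analogue of
the stationary-distribution figures; comparisons there are structural, not
numeric, because the published plots state no sample sizes or axes.
`ergodic_average_check()` compares the time average of a statistic along
one long stochastic path against the terminal ensemble average, the
checkable consequence of the ergodic-average property; it is asserted
quantitatively only for the Ornstein–Uhlenbeck oracle (stationary variance
$\sigma^2/2a$ within 10% at 2000 paths, time average within 3 standard
errors over $T=500$), and reported as a diagnostic for the malnutrition
system itself.

## Problem sizes

The shipped verification uses: $\Delta\zeta = 10^{-3}$ on $[0,2]$ for the
fractional relaxation test (2000 steps, full-history sums);
$\Delta\zeta = 0.01$, $T_1=10$, $T_2=20$, $T=30$ for the end-to-end
baseline run (3001 grid points); 1000 paths at $\Delta\zeta = 0.01$,
$T = 10$ for the small-noise ensemble consistency check; 2000 paths for the
OU stationary law and 200 paths for the strong-order estimate.  These sizes
were chosen so that Monte-Carlo error bars are a few percent of the
quantities they bound while a full verification run stays in the
couple-of-minutes range on one core.

## Known limitations

* The fractional schemes are the explicit published family; no
  predictor–corrector, adaptive stepping, stiff solver or Milstein variant
  is provided.
* Full-history fractional sums cost $O(n^2)$; horizons of $10^5$ steps or
  more in the fractional regime become slow.
* The stochastic threshold theory gives a sufficient condition for
  persistence only; `threshold_report()` therefore classifies
  $R_0^s \le 1$ as "inconclusive", never as extinction.
* $T_1$ and $T_2$ for the published figures are never stated, so
  figure-level comparisons are qualitative.
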