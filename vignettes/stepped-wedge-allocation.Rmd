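---
title: "Optimal allocation in individually randomized stepped-wedge trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal allocation in individually randomized stepped-wedge trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swalloc)
```

## The design problem

An individually randomized stepped-wedge trial assigns each participant to
one of `J` treatment sequences. All sequences start in the control
condition; at the beginning of each of the `T = J + 1` periods one
sequence crosses over to the intervention, so sequence `j` is on treatment
from period `j + 1` onward and everyone ends on treatment. A measurement
is taken at the end of every period. The design question this package
answers is: *what fraction `p_j` of the participants should each sequence
receive* so that the treatment effect is estimated as precisely as
possible?

## Model and assumptions

The outcome model is linear with fixed period effects and a sustained
treatment effect:

$$Y_{ijt} = \beta + \tau_t + x_{jt}\,\gamma + \varepsilon_{ijt},
\qquad \tau_1 = 0,$$

with `x_{jt} = 1` exactly when `t >= j + 1`. The assumptions that matter:

* **Sustained effect.** `gamma` does not depend on time since crossover.
  Designs optimal for time-varying effects can differ; they are outside
  this package's scope.
* **Exponential-decay correlation.** Within an individual,
  `cor(eps_t, eps_t') = rho^|t - t'|` with `0 <= rho < 1` and common
  residual variance `sigma^2`. Measurements further apart in time are less
  correlated, which is usually more realistic for repeated measurements on
  a person than compound symmetry. `rho = 1` makes the covariance singular
  and is rejected.
* **Known covariance at the design stage.** `rho` and `sigma^2` are design
  inputs (from the literature or expert knowledge), not estimated from the
  trial being planned. `sigma^2` is a pure scale factor of
  `var(gamma_hat)`: it cancels from the optimal allocation and from every
  relative efficiency, so its default of 1 is harmless; it matters only
  when simulating data on an absolute scale.
* **Monotone, completely-random dropout.** Between any two adjacent
  periods an individual still in the study leaves with probability `r`,
  independently of their outcomes; once gone they do not return, and
  everyone contributes at least the period-1 measurement.

### Coefficient parameterization

The coefficient vector is `(beta, tau_2, ..., tau_T, gamma)`, of length
`T + 1`: period 1 is the reference category (its effect is fixed at zero
for identifiability), so the design matrix has an intercept column,
`T - 1` period dummies and the treatment column, and the treatment
parameter is the **last** entry. All variances quoted by the package are
the corresponding last diagonal entry of the inverted information.

### Attrition weighting

The probability that an individual's last observation is at the end of
period `t` is `w_t = (1-r)^{t-1} - (1-r)^t` for `t < T`. At the final
period this package uses the survival mass `w_T = (1-r)^{T-1}`: an
individual observed at period `T` is a completer, there is no later period
to drop out before. With this convention the `w_t` form a proper
probability distribution (they sum to one), so expected headcounts add up
to the total sample size. Applying the geometric-decrement formula at
`t = T` as well would instead discard a further factor `(1-r)` of the
completers' information; since rescaling all weights by a constant changes
neither the optimal allocation nor any relative efficiency, the completer
convention is the only substantive choice, and it is the one consistent
with mass conservation.

An individual last observed at period `t` contributes the information of
their first `t` measurements, so the expected per-individual information
of sequence `j` is

$$A_j = \sum_{t=1}^{T} w_t\, X_{jt}' V_t^{-1} X_{jt},$$

with `X_{jt}` and `V_t` the leading `t`-row (and `t`-column) truncations.
For an allocation `p` and total sample size `n`, the GLS estimator has
`cov(theta_hat) = (n \sum_j p_j A_j)^{-1}`, and the optimality criterion
is its last diagonal entry, `var(gamma_hat)`.

## Optimization

The feasible set is the simplex `sum p_j = 1` intersected with optional
per-sequence boxes `L_j <= p_j <= U_j` (feasible when
`sum L_j <= 1 <= sum U_j`). Writing `M(p) = sum_j p_j A_j`, the objective
`e' M(p)^{-1} e` is a matrix-fractional function and therefore **convex**
in `p` over the region where `M(p)` is positive definite. This has two
practical consequences: any converged local solution is global, and
gradient-based methods are well behaved, since the gradient is available
in closed form, `d var / d p_j = -(u' A_j u)` with `u = M(p)^{-1} e`.

`optimize_allocation()` works as follows:

* the equality constraint is eliminated by optimizing over the first
  `J - 1` proportions with the last one implied;
* box constraints are handled by a log-barrier interior method
  (`stats::constrOptim` with BFGS and the analytic gradient; barrier
  tolerance `1e-12`, objective relative tolerance `1e-14`);
* a floor of `1e-9` keeps every implied proportion strictly positive;
* the solver is started from the uniform allocation (or, when the uniform
  point violates the boxes, from a strictly interior feasible point) plus
  `n_starts = 10` randomized starts drawn from a flat Dirichlet and
  blended into the feasible box; the multistart is redundant under
  convexity but guards against numerical stalls, and a fixed `seed`
  (default 2023) makes runs bit-for-bit reproducible;
* because a barrier method approaches but never touches a bound, solutions
  within `1e-5` of a box bound are snapped onto it and the remaining free
  coordinates re-optimized (repeated until the active set is stable); the
  polished point is kept only if it is at least as good;
* ties between starts within `1e-12` in the objective are broken toward
  the lexicographically smallest allocation, for determinism;
* the reported optimum is always `treatment_variance()` recomputed at the
  reported `p*`, never the solver's internal value.

Degenerate inputs: bounds that collapse the feasible region to a single
point return that point directly; infeasible bounds fail before any
optimization; allocations that make the total information singular (for
example `p = (1, 0)` with two sequences, which leaves a lone sequence that
cannot separate period from treatment effects) raise an error rather than
returning an infinite variance, and an information matrix with reciprocal
condition number below `1e-12` triggers a warning.

`grid_oracle()` provides an independent exhaustive search on an integer
lattice of the simplex, used by the test suite to confirm the optimizer is
never beaten at lattice resolution 0.01–0.02 for `J` of 3 and 4.

## What the results look like

Without attrition the optimum is symmetric (`p*_j = p*_{J+1-j}`) — a
time-reversal symmetry of the design that the variance inherits — and the
edge sequences, whose crossover happens at the extremes of the time axis,
get the largest shares. Attrition breaks the symmetry in favour of
early-switching sequences: later sequences spend their intervention
periods where fewer participants remain. The uniform allocation's relative
efficiency `RE = var(gamma_hat; p*) / var(gamma_hat; 1/J)` improves with
`rho` when attrition is light, and over the default grid
(`J` in 3–6, `rho` in 0.1–0.9, `r` in {0, 0.05, 0.2}) its minimum —
recomputed by `scripts/acceptance.R` — is 0.802, at `J = 6`, `rho = 0.1`,
`r = 0.2`: the uniform allocation never needs more than about 25% extra
sample.

One empirical subtlety: under heavy attrition (`r = 0.2`) the relative
efficiency is no longer monotone in `rho`. For `J = 4` the curve computed
here rises to a flat maximum at `rho = 0.7` (RE 0.9826, against 0.9801 at
`rho = 0.6` and 0.9824 at 0.8) and declines thereafter; for `J = 6` the
peak sits at `rho = 0.6`. The location of this peak is sensitive to how
the completer mass is weighted: with the geometric-decrement weight
applied at the final period as well, the `J = 4` peak moves to 0.6, but
the grid-minimum efficiency then drops to 0.794. The package reports what
the mass-conserving convention gives.

## The simulator, and what passing tests show

`simulate_trial()` generates data exactly under the model above:
multivariate-normal residual vectors with the exponential-decay
covariance, integer headcounts by largest-remainder apportionment, and
each individual's last observed period drawn from the attrition weights
independently of the outcomes. `fit_gls()` then estimates the
coefficients with the covariance treated as known, exactly as the
design-stage variance formula assumes. Monte Carlo agreement between the
empirical and analytic `var(gamma_hat)` (`monte_carlo_variance()`)
therefore validates the algebra — the attrition-truncated information
accumulation and its inversion — not the model. Real trials can deviate in
ways the simulator deliberately does not emulate: dropout related to
outcomes or to treatment (informative or arm-dependent attrition),
attrition rates that change over time, residual correlation that is not
exponential-decay, non-normal or non-continuous outcomes, and effects that
wane after crossover. A passing test suite says nothing about those; the
analytic variance uses expected dropout counts, and the comparison is made
against that expected-information value (realized-count information is
available from the fit as a diagnostic).

The test suite uses Monte Carlo problem sizes of 300 participants and
1000 replicates per design for the acceptance-level checks (standard error
of the variance about 4.5% of its value, so a 3-standard-error band is a
meaningful test), and smaller sizes for smoke tests; the law-of-large-
numbers check of realized dropout fractions uses 100,000 participants at
tolerance 0.01.

## Known limitations

* The optimum is *locally* optimal in the design-parameter sense: it
  depends on the assumed `rho` and `r`. A sensitivity analysis over
  plausible values (e.g. with `efficiency_grid()`) is advisable; formal
  maximin/robust designs are out of scope.
* One sequence per switch time. Designs where several sequences share a
  crossover point, incomplete (planned-missingness) designs, transition
  periods, and cluster-level randomization are not supported.
* Proportions are continuous; converting `p* n` to whole people is left to
  `apportion()`, and the efficiency loss from rounding is not analyzed.
* Binary or count outcomes, random slopes, and estimation of `rho` from
  pilot data are not covered.
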