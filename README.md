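# swalloc

Optimal allocation of individuals to treatment sequences in **individually
randomized stepped-wedge trials**, with within-person correlation and
attrition taken into account.

In a stepped-wedge trial with `J` treatment sequences and `T = J + 1`
measurement periods, everyone starts in the control condition; at the start
of each period one sequence crosses over to the intervention, and by the
final period everyone is on the intervention. When individuals (rather than
clusters) are randomized to sequences, the conventional choice of assigning
an equal share `1/J` to every sequence is usually not the most efficient.
`swalloc` finds the allocation that estimates the treatment effect with the
highest precision — and tells you how much a uniform allocation costs you.

Intended users: trial statisticians planning an individually randomized
stepped-wedge study who have a priori estimates of the within-person
correlation and the expected dropout rate.

## Model

The outcome of individual `i` in sequence `j` at the end of period `t` is

```
Y_ijt = beta + tau_t + x_jt * gamma + eps_ijt,     tau_1 = 0,
```

where `x_jt` indicates whether sequence `j` is on the intervention in
period `t` (`x_jt = 1` iff `t >= j + 1`), `gamma` is a sustained treatment
effect, and the residuals of an individual follow an exponential-decay
(AR(1)) correlation structure, `cor(eps_ijt, eps_ijt') = rho^|t - t'|`,
with variance `sigma^2`. Dropout is monotone with a constant per-period
rate `r`: the probability that an individual's last observation falls at
the end of period `t` is `(1 - r)^(t-1) - (1 - r)^t` for `t < T`, and
completers have mass `(1 - r)^(T-1)`.

With the residual covariance `V` treated as known, generalized least
squares gives

```
cov(theta_hat) = ( sum_j sum_t  n_jt  X_jt' V_t^{-1} X_jt )^{-1},
```

where `X_jt` and `V_t` are truncated to an individual's first `t` periods
and `n_jt` is the number of individuals in sequence `j` last observed at
period `t`. The optimality criterion is `var(gamma_hat)`, the diagonal
entry for the treatment parameter. For an allocation `p` on the simplex
(`sum p_j = 1`, optionally `L_j <= p_j <= U_j`), `swalloc` minimizes this
variance; the objective is a matrix-fractional function of `p` and hence
convex, so the interior-point optimization is reliable. The relative
efficiency of any allocation `p` is
`RE = var(gamma_hat; p*) / var(gamma_hat; p) <= 1`, and `(1/RE - 1) * 100`
is the percent extra sample the allocation `p` needs to match the optimum.

## Worked example

Four sequences, within-person correlation 0.4, no dropout:

```r
library(swalloc)
d   <- sw_design(J = 4, rho = 0.4, r = 0)
opt <- optimize_allocation(d)
print(opt)
#> Optimal allocation (J = 4, rho = 0.4, r = 0)
#>  sequence proportion
#>         1     0.3276
#>         2     0.1724
#>         3     0.1724
#>         4     0.3276
#> var(gamma_hat) per unit total n: 1.5585413
```

A third of the individuals go to each of the first and last sequences and
one-sixth to each middle sequence — the edge sequences carry the most
information about the treatment effect. The uniform allocation is only
mildly inefficient here:

```r
re <- relative_efficiency(uniform_allocation(4), d, optimal = opt)
round(re, 3)                       #> 0.974
round(sample_size_inflation(re), 1)  #> 2.7  (percent extra sample needed)
```

If assigning a third of the sample to one sequence is impractical, bound
every proportion to `[0.15, 0.35]`; at `rho = 0.2` the constrained optimum
sits exactly on the bounds:

```r
optimize_allocation(sw_design(4, rho = 0.2), lower = 0.15, upper = 0.35)
#>  sequence proportion at_bound
#>         1       0.35    upper
#>         2       0.15    lower
#>         3       0.15    lower
#>         4       0.35    upper
```

The analytic variance can be checked by simulation — trials are generated
under the model, fitted by GLS, and the empirical variance of `gamma_hat`
compared with the analytic one:

```r
mc <- monte_carlo_variance(sw_design(3, rho = 0.4, r = 0.2),
                           uniform_allocation(3), n_total = 300,
                           gamma = 0.3, n_reps = 500, seed = 42)
print(mc)
#> Monte Carlo variance check (500 replicates, n = 300)
#>   empirical var(gamma_hat): 0.00919545 (SE 0.000582)
#>   analytic  var(gamma_hat): 0.00920837
#>   standardized discrepancy z = -0.02 -> agreement (within 3 SE)
```

## Command line

A thin CLI wraps the same functions (`exec/swalloc` after installation, or
`Rscript -e 'swalloc::run_cli(...)'`):

```sh
swalloc optimize -J 4 --rho 0.4 -r 0 --out opt.json
swalloc grid     -J 3,4,5,6 --rho 0.1,0.5,0.9 -r 0,0.2 --out grid.csv
swalloc validate -J 3 --rho 0.4 -r 0.2 --n-total 300 --reps 1000 --out report.txt
```

Exit codes: 0 success, 2 usage error or infeasible bounds, 3 numerical
failure. Every output embeds the tool version, the resolved parameters and
the seed.

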