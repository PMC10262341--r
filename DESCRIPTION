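Package: swalloc
Title: Optimal Allocation to Treatment Sequences in Individually
    Randomized Stepped-Wedge Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for individually randomized stepped-wedge trials
    with repeated measurements on the same individuals. Computes the variance
    of the generalized least squares treatment-effect estimator under an
    exponential-decay (first-order autoregressive) within-person correlation
    structure and monotone attrition, finds the allocation of individuals to
    treatment sequences that minimizes this variance (optionally subject to
    per-sequence lower and upper bounds), evaluates the efficiency of the
    uniform allocation relative to the optimal one, and validates the
    analytic variance by Monte Carlo simulation of trial data. A command-line
    interface exposes optimization, efficiency grids and simulation checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
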