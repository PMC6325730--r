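# chartsize

Precision-based sample size calculations for descriptive retrospective
studies — chart reviews and other burden-of-illness designs whose goal is a
sufficiently *narrow confidence interval*, not power for a hypothesis test.

Chart extraction is expensive (often hours per chart), so the design
question runs in both directions: how many charts are needed to hit a
precision target, and what precision does a fixed, feasibility-driven
number of charts buy? `chartsize` answers both for the two outcome
families that dominate these studies.

**Categorical outcomes** (treatment received yes/no, comorbidity present),
under a binomial model for frequency *p* in *n* charts:

- expected observed count: *n p*
- 95% CI half-width (Wald): *z* √(*p*(1−*p*)/*n*), with the literal
  *z* = 1.96 so published planning tables reproduce digit-for-digit
- probability the treatment is seen at least once: 1 − (1−*p*)ⁿ

each with an inverse solver (`n_for_halfwidth()`, `n_for_detection()`,
`min_detectable_p()`), plus the Clopper–Pearson `exact_interval()` as the
reference when *n p* is small.

**Cost outcomes**, via a standard deviation σ or — when none is available —
the coefficient of variation *c*ᵥ = σ/μ:

- half-width: *W* = *z* σ/√*n* = *z* *c*ᵥ μ/√*n*
- required *n* for an absolute width *W*: ⌈(*z* *c*ᵥ μ/*W*)²⌉
- required *n* for a width of ±*V*·100% of the mean: ⌈(*z* *c*ᵥ/*V*)²⌉ —
  needing neither μ nor σ
- subgroup inflation: ⌈*n*/fraction⌉

`estimate_cv()` derives *c*ᵥ from pilot cost data (optionally excluding
zeros and/or log-transforming — the standard mitigations for heavy skew),
and `melody_cv()` ships the 18 observed cv values (range 0.26–4.30, median
0.72) from a multinational advanced-melanoma chart review as a calibration
reference.

A seeded Monte Carlo engine (`simulate_detection()`,
`simulate_wald_coverage()`, `simulate_cost_precision()`,
`generate_costs()` with moment-matched lognormal / gamma / zero-inflated
two-part families) validates the closed forms and quantifies where the
normal-theory cost interval under-covers for skewed data.

## Worked example

A review of 200 charts for a treatment given to ~5% of patients:

```r
library(chartsize)
glance(binomial_design(200, 0.05))
#> # A tibble: 1 × 7
#>       n     p expected_count detection_prob halfwidth ci_lower ci_upper
#>   <int> <dbl>          <dbl>          <dbl>     <dbl>    <dbl>    <dbl>
#> 1   200  0.05             10          1.000    0.0302   0.0198   0.0802
```

Ten treated patients are expected, the treatment is essentially certain to
be observed at least once, and the proportion estimate will be precise to
about ±0.03 — an expected 95% CI of (0.02, 0.08). For a cost outcome at
the reference dispersion, precise to within ±10% of the mean:

```r
n_for_relative_width(cv = 0.72, target_relative_width = 0.10)
#> [1] 200
subgroup_inflation(200, 0.20)   # same precision inside a 20% subgroup
#> [1] 1000
```

And the honesty check — the z-interval's actual coverage under lognormal
costs:

```r
simulate_cost_precision(200, mu = 1000, cv = 0.72, seed = 1)$estimate
#> [1] 0.9429
simulate_cost_precision(50, mu = 1000, cv = 4.3, seed = 1)$estimate
#> [1] 0.7565
```

Near-nominal at n = 200 and moderate dispersion; badly optimistic for a
small sample of a highly skewed cost category.

The full planning table prints with `cat(render_grid(precision_grid()))`,
plots with `autoplot()`, and everything is also reachable from a shell via
the installed `exec/chartsize` script (subcommands `categorical`,
`continuous`, `cv-estimate`, `grid`, `curve`, `simulate`; try
`chartsize categorical --n 200 --p 0.05`).

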