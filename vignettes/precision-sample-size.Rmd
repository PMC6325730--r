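---
title: "Precision-based sample size for descriptive chart reviews: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision-based sample size for descriptive chart reviews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chartsize)
library(dplyr)
```

## The design problem

Retrospective burden-of-illness studies — chart reviews in particular — are
descriptive: they estimate the proportion of patients receiving each
treatment, the spectrum of therapies in use, and the distribution of
resource-use costs. The usual hypothesis-testing power calculation answers
the wrong question for such studies. The relevant question is one of
*precision*: how many charts must be extracted so that the resulting
estimates carry usefully narrow confidence intervals, and so that even rare
treatments have a realistic chance of appearing in the sample at all?
Because each chart can cost hours of clinician-supervised extraction, both
directions of the calculation matter: solve for $n$ given a precision goal,
or report the achievable precision given a fixed, feasibility-driven $n$.

`chartsize` implements both directions for the two outcome families that
dominate these studies, plus a Monte Carlo engine that quantifies where the
closed-form approximations are trustworthy.

## Categorical outcomes

For a treatment received with probability $p$, a review of $n$ charts under
a binomial model gives three planning quantities:

* the expected number of treated patients observed, $n p$
  (`expected_count()`);
* the half-width of the Wald confidence interval for $p$,
  $z \sqrt{p(1-p)/n}$ (`wald_halfwidth()`);
* the probability that the treatment is observed at least once,
  $1 - (1-p)^n$ (`detection_probability()`).

Each has an inverse: `n_for_halfwidth()` and `n_for_detection()` return the
smallest integer $n$ meeting a width or detection target, and
`min_detectable_p()` gives the smallest treatment frequency a fixed $n$ can
be expected to surface. `precision_grid()` crosses sample sizes with
frequencies to reproduce the familiar planning lookup table:

```{r grid}
cat(render_grid(precision_grid()))
```

### Numerical conventions

* **Critical value.** The planning literature pairs the 95% level with the
  literal 1.96, and the tabled values only reproduce digit-for-digit with
  that literal; `z_value()` therefore returns exactly 1.96 at
  `conf_level = 0.95` and the true normal quantile for any other level (or
  with `exact = TRUE`).
* **Display rounding.** Counts are rounded half *up* to integers
  (`round_half_up()`: 2.5 charts → 3) and probabilities/widths to two
  decimals; that convention is what makes the printed table reproducible.
  Full-precision values are always available programmatically, and the CSV
  and JSON renderings carry them losslessly (17 significant digits).
* **Inverse solvers** return the ceiling — the smallest integer satisfying
  the constraint — because fractional charts do not exist, and verify the
  analytic ceiling by a local integer search so floating-point boundary
  cases (targets met with exact equality) cannot shift the answer by one.
* **Degenerate inputs.** $p = 0$ and $p = 1$ are rejected rather than
  returned: a precision query about a treatment that is never or always
  given indicates a specification error, not a zero-width interval.
  Likewise a detection target of exactly 1 is unreachable with finite $n$
  and is refused.
* **Clamping.** Expected intervals are truncated to $[0,1]$; the reported
  `ci_upper - ci_lower` can therefore be less than twice the half-width
  near the boundary.

The Wald width is used *as a planning device*, with no continuity
correction, because that is the closed form the sizing formulas invert. Its
known anti-conservatism at small $n p$ is surfaced rather than hidden:
`exact_interval()` provides the Clopper–Pearson reference, and
`simulate_wald_coverage()` measures the realized coverage (about 92–93% at
$n = 50, p = 0.05$; far lower at $n p \le 1$).

## Cost outcomes

For a mean cost $\mu$ with standard deviation $\sigma$, the normal-theory
interval half-width is $W = z\sigma/\sqrt n$ (`cost_halfwidth()`), inverted
by `n_for_cost_width()` as $n = \lceil z^2\sigma^2/W^2\rceil$. Note the
$\sigma^2$: the inversion follows from squaring the width equation, and the
implementation uses the dimensionally correct square throughout.

Pilot estimates of $\sigma$ are rarely available, so the formulas are also
parameterized by the coefficient of variation $c_v = \sigma/\mu$:

* absolute target width: $n = \lceil (z c_v \mu / W)^2 \rceil$
  (`n_for_absolute_width_cv()`);
* relative target width $V = W/\mu$: $n = \lceil (z c_v / V)^2 \rceil$
  (`n_for_relative_width()`), which needs *neither* $\mu$ nor $\sigma$.

Both parameterizations are exposed because published descriptions of the
absolute-width case are easy to misread; they are linked by the exact
identity `n_for_absolute_width_cv(cv, mu, W) == n_for_relative_width(cv,
W/mu)`, which the test suite asserts across scales. $V$ is a fraction in
$(0, 1]$: $V = 1$ places the lower confidence bound at zero cost, and
anything larger is meaningless for a non-negative outcome, so the CLI
accepts `10%`-style percent strings but rejects bare numbers above 1 as
ambiguous rather than guessing a denominator.

At the reference dispersion $c_v = 0.72$ (the median observed across 18
cost categories in a multinational advanced-melanoma chart review, shipped
as `melody_cv()`), a 95% interval within ±10% of the mean needs
`r n_for_relative_width(0.72, 0.10)` charts; at the most dispersed category
observed ($c_v = 4.3$–$4.5$) the same precision needs thousands, which is
the practical argument for switching to administrative data when zero-heavy
cost categories must be characterized precisely. `samplesize_curve()`
traces the full $n(c_v)$ relationship; a $c_v$ of exactly 0 is mapped to
$n = 1$ (a degenerate no-variability case) so curves can start at the
origin of the dispersion axis.

`estimate_cv()` computes $c_v$ from pilot data as sample SD (the $n-1$
denominator, the standard unbiased-variance convention; the ratio's own
small-sample bias is not corrected) over sample mean, with two documented
mitigation options for heavy skew: excluding zero-cost records (which
re-targets the estimate to users of the category) and/or estimating on
log-transformed values. Both flags are carried in the result so a sizing
report can state which variant produced its input. A cv of exactly 0 is
returned with a warning rather than an error — it is a legitimate summary
of constant pilot data — but the solvers refuse it, since it implies
$n = 0$.

Subgroup analyses size the subgroup first and inflate:
`subgroup_inflation(n, f)` $= \lceil n/f \rceil$, so a subgroup forming 20%
of the population multiplies the overall requirement fivefold.

## The Monte Carlo engine

The closed forms rest on two approximations — the Wald interval for
proportions and normality of the mean for costs — and real cost data are
right-skewed and frequently zero-inflated. The `simulate_*` functions
quantify both, and also serve as brute-force oracles for the formulas
themselves.

`generate_costs()` draws from three moment-matched families, chosen because
they are the standard stylizations of health-cost data:

* **lognormal**: $\sigma_{\log}^2 = \ln(1 + c_v^2)$,
  $\mu_{\log} = \ln\mu - \sigma_{\log}^2/2$;
* **gamma**: shape $= 1/c_v^2$, scale $= \mu c_v^2$ ($c_v = 1$ is the
  exponential);
* **two-part**: zero with probability $q$, otherwise lognormal with the
  positive part matched so the *overall* mean and cv equal the targets.
  The match is feasible only for $q < c_v^2/(1+c_v^2)$; infeasible requests
  raise an error stating that bound instead of silently changing the
  moments.

The parameterizations are stated exactly so results are reproducible across
implementations. Every simulator takes an integer seed, restores the
caller's RNG state afterwards, and is bit-reproducible: identical inputs
give identical results.

`simulate_cost_precision()` builds the $z$-interval
$\bar x \pm z s/\sqrt n$ — deliberately $z$, not Student-$t$, to match the
planning formula; a $t$ option exists for comparison — and reports the
coverage of the true mean. At $n = 200$ and $c_v = 0.72$ the coverage is
within about a point of nominal, supporting the "±10% of the mean at
$n \approx 200$" planning claim; at $n = 50$ and $c_v = 4.3$ it collapses
to roughly 75%, which is the quantitative content of the warning that
normal-theory sizing is optimistic for highly skewed, zero-heavy cost
outcomes. The degradation is monotone in $c_v$ at fixed $n$ in the tested
range.

### What is the right oracle for a width formula?

A subtlety worth recording: the *mean realized plug-in half-width* is a
biased estimate of the planning half-width, because
$E[\sqrt{\hat p(1-\hat p)}] < \sqrt{p(1-p)}$ (and similarly $E[s] < \sigma$
for skewed data) — at $n = 200$, $p = 0.05$ the bias is about 1%, many
times the Monte Carlo standard error at $10^5$ replicates. The simulators
therefore report two width summaries: `mean_halfwidth` (what an analyst
would see on average, compared loosely) and `se_halfwidth`, $z$ times the
empirical standard deviation of the estimator across replicates, which
estimates the planning width itself without plug-in bias and is the
quantity tested against the closed form at 3 Monte Carlo standard errors.
The standard error of that SD-based oracle is computed with the estimator's
excess kurtosis, $\mathrm{se}(\hat\sigma) \approx
\sigma\sqrt{(2+\gamma_2)/(4R)}$.

### What the generator does and does not emulate

The synthetic families reproduce the mean, dispersion, skewness-by-family
and zero-inflation of cost data. They do not emulate multimodality from
distinct treatment pathways, censoring from incomplete follow-up,
correlation between cost categories, or currency/jurisdiction effects —
the fixture's cv values span jurisdictions precisely because the cv is the
scale-free carrier of dispersion information. Passing coverage results
therefore validate the formulas *under the stated families*, not for any
particular real dataset.

## Problem sizes and defaults

Default replicate counts are $10^5$ for binomial simulations and $10^4$
for cost simulations, chosen so the Monte Carlo standard error of a
coverage estimate (≈0.07 and 0.22 percentage points respectively) sits
below the two-decimal display resolution while a full validation run
completes in seconds on a single core. The randomized solver round-trip
sweep uses 1000 parameter draws per solver. The default curve resolution
is 200 points; the published-table defaults are
$n \in \{50, 100, 200, 300, 500, 1000\}$ and
$p \in \{0.01, 0.05, 0.10, 0.25, 0.50, 0.75\}$.

## Known limitations

* Count outcomes (hospitalization episodes, visit counts) are not given
  their own Poisson/negative-binomial formulas; the continuous machinery
  can approximate them through a normal approximation, with the usual
  caveats.
* The multinomial problem of several treatments jointly is not addressed;
  each treatment is sized marginally.
* Two-part *analysis* models, bootstrap inference and transformation-based
  analysis are analysis-stage techniques, out of scope for sizing; the
  package's contribution at the design stage is to let the cv be estimated
  in a way (`exclude_zeros`, `log_transform`) consistent with the planned
  analysis.
* The cv fixture transcribes printed two-decimal values; its per-category
  means and SDs are carried for context only.
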