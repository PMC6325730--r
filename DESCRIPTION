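Package: chartsize
Title: Precision-Based Sample Size Calculations for Retrospective Chart
    Review Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward precision calculations and inverse sample-size solvers
    for descriptive (burden-of-illness) studies, where the design goal is a
    sufficiently narrow confidence interval rather than power for a
    hypothesis test. Covers categorical outcomes (probability of observing a
    treatment at least once, Wald interval half-width, expected counts under
    a binomial model) and continuous cost outcomes (half-widths from a
    standard deviation or a coefficient of variation, absolute or relative
    target widths, subgroup inflation), plus coefficient-of-variation
    estimation from pilot cost data and a Monte Carlo engine that checks the
    closed-form approximations under skewed, zero-inflated cost
    distributions. Ships the observed coefficient-of-variation values from a
    multinational advanced-melanoma chart review as a reference fixture,
    reproduces the associated precision lookup table and sample-size curves,
    and provides a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
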