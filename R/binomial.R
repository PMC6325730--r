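#' Expected number of observed patients receiving a treatment
#'
#' Under a binomial model for receiving a treatment with probability `p` in a
#' chart review of `n` charts, the expected number of patients observed on
#' the treatment is `n * p` (unrounded).
#'
#' @param n Number of charts (positive integer, vectorized).
#' @param p Probability of receiving the treatment, in (0, 1) (vectorized).
#' @return Expected count, a non-negative numeric vector.
#' @examples
#' expected_count(200, 0.05)   # 10
#' expected_count(50, 0.01)    # 0.5 charts-worth; displayed tables round to 1
#' @family binomial precision
#' @export
expected_count <- function(n, p) {
  check_count(n)
  check_open_unit(p)
  n * p
}

#' Wald half-width of the confidence interval for a proportion
#'
#' The expected half-width ("precision") of the normal-approximation
#' (Wald) confidence interval for a proportion `p` estimated from `n`
#' charts: `z * sqrt(p * (1 - p) / n)`. Symmetric in `p` and `1 - p`,
#' maximal at `p = 0.5`, and shrinks like `1/sqrt(n)`.
#'
#' No continuity correction is applied. The Wald interval is known to be
#' anti-conservative when `n * p` is small; see [simulate_wald_coverage()]
#' and [exact_interval()] for quantifying this.
#'
#' @inheritParams expected_count
#' @param conf_level Confidence level, default 0.95.
#' @param z Optional explicit critical value; defaults to [z_value()] of
#'   `conf_level` (the literal 1.96 at the 0.95 level).
#' @return Half-width, a non-negative numeric vector on the proportion scale.
#' @examples
#' wald_halfwidth(200, 0.05)   # 0.0302 -> the tabled +/-0.03
#' wald_halfwidth(400, 0.5)    # exactly half of wald_halfwidth(100, 0.5)
#' @family binomial precision
#' @export
wald_halfwidth <- function(n, p, conf_level = 0.95, z = NULL) {
  check_count(n)
  check_open_unit(p)
  z <- resolve_z(z, conf_level)
  z * sqrt(p * (1 - p) / n)
}

#' Probability of observing a treatment at least once
#'
#' The probability that a treatment received with frequency `p` appears in
#' at least one of `n` reviewed charts: `1 - (1 - p)^n`. Strictly increasing
#' in both arguments; equals `p` at `n = 1` and tends to 1 as `n` grows.
#'
#' @inheritParams expected_count
#' @return Detection probability in \[0, 1\].
#' @examples
#' detection_probability(50, 0.01)    # 0.395: a 1%-frequency treatment is
#'                                    # missed in ~60% of 50-chart reviews
#' detection_probability(300, 0.01)   # 0.951
#' @family binomial precision
#' @export
detection_probability <- function(n, p) {
  check_count(n)
  check_open_unit(p)
  -expm1(n * log1p(-p))
}

#' Full precision summary for a categorical outcome design
#'
#' Combines the three binomial precision quantities -- expected count,
#' detection probability, and Wald half-width -- and forms the expected
#' confidence interval `p +/- halfwidth`, truncated to \[0, 1\].
#'
#' @inheritParams wald_halfwidth
#' @return A tibble with one row per design and columns `n`, `p`,
#'   `expected_count`, `detection_prob`, `halfwidth`, `ci_lower`,
#'   `ci_upper`. Bounds are clamped to \[0, 1\], so
#'   `ci_upper - ci_lower <= 2 * halfwidth` with equality unless clamping
#'   occurred.
#' @examples
#' expected_ci(200, 0.05)   # expected 95% CI (0.02, 0.08)
#' expected_ci(50, 0.01)    # lower bound clamped to 0
#' @family binomial precision
#' @export
expected_ci <- function(n, p, conf_level = 0.95, z = NULL) {
  hw <- wald_halfwidth(n, p, conf_level, z)
  nn <- as.integer(n + 0 * p)
  pp <- p + 0 * n
  tibble::tibble(
    n = nn,
    p = pp,
    expected_count = nn * pp,
    detection_prob = detection_probability(nn, pp),
    halfwidth = hw,
    ci_lower = pmax(0, pp - hw),
    ci_upper = pmin(1, pp + hw)
  )
}

#' Sample size for a target Wald half-width
#'
#' The smallest number of charts `n` such that the expected Wald half-width
#' for a proportion `p` is at most `target_halfwidth`. The analytic form is
#' `ceiling(z^2 * p * (1 - p) / W^2)`; a local integer search around the
#' ceiling guards against floating-point boundary error, so the returned
#' `n` always satisfies the forward constraint while `n - 1` does not
#' (when `n > 1`).
#'
#' @param p Anticipated proportion, in (0, 1).
#' @param target_halfwidth Desired half-width `W`, in (0, 1).
#' @inheritParams wald_halfwidth
#' @return Required sample size (positive integer, vectorized over `p` and
#'   `target_halfwidth`).
#' @examples
#' n_for_halfwidth(0.5, 0.07)    # 196
#' n_for_halfwidth(0.05, 0.03)   # 203
#' @family binomial solvers
#' @export
n_for_halfwidth <- function(p, target_halfwidth, conf_level = 0.95, z = NULL) {
  check_open_unit(p)
  check_open_unit(target_halfwidth, "target_halfwidth")
  z <- resolve_z(z, conf_level)
  solve1 <- function(p1, w1) {
    n0 <- max(1, ceiling(z^2 * p1 * (1 - p1) / w1^2))
    cand <- max(1, n0 - 2):(n0 + 2)
    ok <- z * sqrt(p1 * (1 - p1) / cand) <= w1
    as.integer(min(cand[ok]))
  }
  out <- mapply(solve1, p, target_halfwidth)
  as.integer(out)
}

#' Sample size to observe a treatment with given probability
#'
#' The smallest `n` such that a treatment with frequency `p` is observed at
#' least once with probability at least `target_prob`; analytically
#' `ceiling(log(1 - target_prob) / log(1 - p))`, again verified by local
#' integer search.
#'
#' @param p Treatment frequency, in (0, 1).
#' @param target_prob Desired detection probability, in (0, 1). A target of
#'   1 is rejected: it is unreachable with finite `n`.
#' @return Required sample size (positive integer, vectorized).
#' @examples
#' n_for_detection(0.01, 0.95)   # 299
#' n_for_detection(0.05, 0.99)   # 90
#' @family binomial solvers
#' @export
n_for_detection <- function(p, target_prob) {
  check_open_unit(p)
  check_open_unit(target_prob, "target_prob")
  solve1 <- function(p1, g1) {
    n0 <- max(1, ceiling(log1p(-g1) / log1p(-p1)))
    cand <- max(1, n0 - 2):(n0 + 2)
    ok <- -expm1(cand * log1p(-p1)) >= g1
    as.integer(min(cand[ok]))
  }
  as.integer(mapply(solve1, p, target_prob))
}

#' Minimum detectable treatment frequency for a fixed sample size
#'
#' When the number of available charts is fixed, the smallest treatment
#' frequency `p*` that would still be observed at least once with
#' probability `target_prob`: `p* = 1 - (1 - target_prob)^(1/n)`. Exact
#' inverse of [detection_probability()].
#'
#' @param n Fixed sample size (positive integer, vectorized).
#' @param target_prob Desired detection probability, in (0, 1).
#' @return Frequency in (0, 1).
#' @examples
#' min_detectable_p(299, 0.95)   # ~0.00997
#' detection_probability(299, min_detectable_p(299, 0.95))  # 0.95 exactly
#' @family binomial solvers
#' @export
min_detectable_p <- function(n, target_prob) {
  check_count(n)
  check_open_unit(target_prob, "target_prob")
  -expm1(log1p(-target_prob) / n)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The equal-tailed exact interval for a proportion, from beta quantiles.
#' Provided as the reference against which the Wald-based planning
#' quantities can be judged: when `n * p` is small the Wald interval is
#' anti-conservative while this interval keeps nominal coverage.
#'
#' @param successes Observed number of events (non-negative integer,
#'   at most `n`).
#' @param n Number of trials (positive integer).
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with columns `successes`, `n`, `estimate`, `ci_lower`,
#'   `ci_upper`. The interval always contains `successes / n`.
#' @examples
#' exact_interval(10, 200)   # compare with the Wald-based (0.02, 0.08)
#' exact_interval(0, 10)     # lower bound exactly 0
#' @family binomial precision
#' @export
exact_interval <- function(successes, n, conf_level = 0.95) {
  check_count(n)
  if (!is.numeric(successes) || anyNA(successes) || any(successes < 0) ||
      any(successes != floor(successes))) {
    stop_domain("successes", "must be a non-negative integer")
  }
  if (any(successes > n)) {
    stop_domain("successes", "must not exceed `n`")
  }
  check_open_unit(conf_level, "conf_level")
  alpha <- 1 - conf_level
  lo <- ifelse(successes == 0, 0,
               qbeta(alpha / 2, successes, n - successes + 1))
  hi <- ifelse(successes == n, 1,
               qbeta(1 - alpha / 2, successes + 1, n - successes))
  tibble::tibble(
    successes = as.integer(successes + 0 * n),
    n = as.integer(n + 0 * successes),
    estimate = successes / n,
    ci_lower = lo,
    ci_upper = hi
  )
}
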