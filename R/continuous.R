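#' Confidence interval half-width for a mean cost
#'
#' Under a normal approximation for the sampling distribution of a mean
#' cost with standard deviation `sigma`, the half-width of the confidence
#' interval from `n` charts is `W = z * sigma / sqrt(n)`.
#'
#' @param n Number of charts (positive integer, vectorized).
#' @param sigma Standard deviation of the cost outcome, in currency units.
#' @param conf_level Confidence level, default 0.95.
#' @param z Optional explicit critical value (default: [z_value()]).
#' @return Half-width in the same currency units as `sigma`.
#' @examples
#' cost_halfwidth(100, 100)   # 19.6
#' @family cost precision
#' @export
cost_halfwidth <- function(n, sigma, conf_level = 0.95, z = NULL) {
  check_count(n)
  check_positive(sigma, "sigma")
  z <- resolve_z(z, conf_level)
  z * sigma / sqrt(n)
}

#' Sample size for a target absolute cost half-width
#'
#' Smallest `n` with `cost_halfwidth(n, sigma) <= W`; analytic form
#' `ceiling(z^2 * sigma^2 / W^2)`, verified by local integer search.
#'
#' @param sigma Standard deviation of the cost outcome.
#' @param target_width Desired half-width `W`, currency units.
#' @inheritParams cost_halfwidth
#' @return Required sample size (positive integer, vectorized).
#' @examples
#' n_for_cost_width(100, 10)      # 385
#' n_for_cost_width(0.72, 0.10)   # 200 (sigma and W as fractions of the mean)
#' @family cost solvers
#' @export
n_for_cost_width <- function(sigma, target_width, conf_level = 0.95, z = NULL) {
  check_positive(sigma, "sigma")
  check_positive(target_width, "target_width")
  z <- resolve_z(z, conf_level)
  solve1 <- function(s1, w1) {
    n0 <- max(1, ceiling((z * s1 / w1)^2))
    cand <- max(1, n0 - 2):(n0 + 2)
    ok <- z * s1 / sqrt(cand) <= w1
    as.integer(min(cand[ok]))
  }
  as.integer(mapply(solve1, sigma, target_width))
}

#' Cost half-width from a coefficient of variation
#'
#' When no standard deviation estimate exists, write `sigma = cv * mu` and
#' the half-width becomes `z * cv * mu / sqrt(n)`. Identical to
#' `cost_halfwidth(n, cv * mu)`; linear in `mu`.
#'
#' @inheritParams cost_halfwidth
#' @param cv Coefficient of variation `sigma / mu` (dimensionless, > 0).
#' @param mu Mean cost, currency units.
#' @return Half-width in currency units.
#' @examples
#' cv_halfwidth(200, 0.72, 1000)   # ~99.8: within +/-10% of the mean
#' @family cost precision
#' @export
cv_halfwidth <- function(n, cv, mu, conf_level = 0.95, z = NULL) {
  check_positive(cv, "cv")
  check_positive(mu, "mu")
  cost_halfwidth(n, cv * mu, conf_level, z)
}

#' Sample size for a relative cost half-width
#'
#' The half-width can be targeted as a fraction `V = W / mu` of the mean,
#' which removes `mu` from the calculation entirely: the required sample
#' size is `ceiling((z * cv / V)^2)`, depending only on the coefficient of
#' variation. `V = 1` corresponds to an interval whose lower bound is 0;
#' values above 1 are rejected.
#'
#' @param cv Coefficient of variation (> 0).
#' @param target_relative_width Desired half-width as a fraction of the
#'   mean, `V` in (0, 1\].
#' @inheritParams cost_halfwidth
#' @return Required sample size (positive integer, vectorized).
#' @examples
#' n_for_relative_width(0.72, 0.10)   # 200
#' n_for_relative_width(4.5, 0.10)    # 7780
#' @family cost solvers
#' @export
n_for_relative_width <- function(cv, target_relative_width,
                                 conf_level = 0.95, z = NULL) {
  check_positive(cv, "cv")
  v <- target_relative_width
  if (!is.numeric(v) || length(v) < 1 || anyNA(v) || any(v <= 0) || any(v > 1)) {
    stop_domain("target_relative_width", "must lie in (0, 1]")
  }
  z <- resolve_z(z, conf_level)
  solve1 <- function(c1, v1) {
    n0 <- max(1, ceiling((z * c1 / v1)^2))
    cand <- max(1, n0 - 2):(n0 + 2)
    ok <- z * c1 / sqrt(cand) <= v1
    as.integer(min(cand[ok]))
  }
  as.integer(mapply(solve1, cv, v))
}

#' Sample size for an absolute cost half-width via the coefficient of variation
#'
#' With a mean estimate `mu` available, an absolute target width `W` maps to
#' the relative target `V = W / mu`; the required sample size is
#' `ceiling((z * cv * mu / W)^2)` and equals
#' `n_for_relative_width(cv, W / mu)` exactly.
#'
#' @inheritParams n_for_relative_width
#' @param mu Mean cost, currency units.
#' @param target_width Desired absolute half-width `W`, currency units.
#' @return Required sample size (positive integer, vectorized).
#' @examples
#' n_for_absolute_width_cv(0.72, 1000, 100)   # 200
#' n_for_absolute_width_cv(1.0, 500, 98)      # 100 exactly
#' @family cost solvers
#' @export
n_for_absolute_width_cv <- function(cv, mu, target_width,
                                    conf_level = 0.95, z = NULL) {
  check_positive(cv, "cv")
  check_positive(mu, "mu")
  check_positive(target_width, "target_width")
  n_for_cost_width(cv * mu, target_width, conf_level, z)
}

#' Inflate a subgroup sample size to the full population
#'
#' If precision requirements are set for a subgroup comprising a fraction
#' `subgroup_fraction` of the population, sampling the overall population
#' requires `ceiling(n_subgroup / subgroup_fraction)` charts: a subgroup
#' making up 20% of patients needs a 5x larger overall sample.
#'
#' @param n_subgroup Required sample size within the subgroup (positive
#'   integer, vectorized).
#' @param subgroup_fraction Fraction of the population in the subgroup, in
#'   (0, 1\].
#' @return Required overall sample size (positive integer).
#' @examples
#' subgroup_inflation(200, 0.20)   # 1000
#' @family cost solvers
#' @export
subgroup_inflation <- function(n_subgroup, subgroup_fraction) {
  check_count(n_subgroup, "n_subgroup")
  f <- subgroup_fraction
  if (!is.numeric(f) || length(f) < 1 || anyNA(f) || any(f <= 0) || any(f > 1)) {
    stop_domain("subgroup_fraction", "must lie in (0, 1]")
  }
  as.integer(ceiling(n_subgroup / f))
}
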