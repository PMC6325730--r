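# Monte Carlo validation engine. Each simulator returns a one-row tibble of
# class "sim_result" holding the empirical estimate, its Monte Carlo
# standard error, and the closed-form value it checks, so closed form vs
# simulation comparisons are uniform across outcome types.

sim_result <- function(mode, estimate, mc_se, replicates, seed, closed_form,
                       ...) {
  out <- tibble::tibble(
    mode = mode,
    estimate = estimate,
    mc_se = mc_se,
    replicates = as.integer(replicates),
    seed = as.integer(seed),
    closed_form = closed_form,
    ...
  )
  class(out) <- c("sim_result", class(out))
  out
}

#' Monte Carlo check of the detection-probability formula
#'
#' Draws `replicates` binomial(`n`, `p`) chart-review outcomes and records
#' the fraction in which the treatment was observed at least once; the
#' closed form being checked is `1 - (1 - p)^n`.
#'
#' @param n Number of charts (positive integer).
#' @param p Treatment frequency, in (0, 1).
#' @param replicates Number of simulated reviews (default 100000, which
#'   keeps the Monte Carlo standard error below the two-decimal display
#'   resolution).
#' @param seed Integer seed; the run is bit-reproducible given the seed,
#'   and the caller's RNG state is left untouched.
#' @return A `sim_result` tibble with columns `mode`, `estimate` (empirical
#'   detection probability), `mc_se` (`sqrt(est * (1 - est) / replicates)`),
#'   `replicates`, `seed`, `closed_form`.
#' @examples
#' simulate_detection(50, 0.01, replicates = 10000, seed = 1)
#' @family simulation
#' @export
simulate_detection <- function(n, p, replicates = 1e5, seed = 1) {
  check_count(n)
  check_open_unit(p)
  check_count(replicates, "replicates")
  est <- local_rng(seed, {
    mean(rbinom(replicates, n, p) >= 1)
  })
  sim_result(
    mode = "detection",
    estimate = est,
    mc_se = sqrt(est * (1 - est) / replicates),
    replicates = replicates,
    seed = seed,
    closed_form = detection_probability(n, p)
  )
}

#' Monte Carlo coverage and width of the Wald interval for a proportion
#'
#' Per replicate, draws `x ~ binomial(n, p)`, forms the plug-in Wald
#' interval `p_hat +/- z * sqrt(p_hat * (1 - p_hat) / n)`, and records
#' whether the true `p` is covered and the realized half-width. The
#' empirical coverage quantifies the Wald interval's known
#' anti-conservatism at small `n * p`, which the closed-form planning
#' tables cannot see.
#'
#' Two width summaries are returned. `mean_halfwidth` is the average
#' realized plug-in half-width (what an analyst reports); it is biased
#' slightly below the planning formula because
#' `E[sqrt(p_hat * (1 - p_hat))] < sqrt(p * (1 - p))`. `se_halfwidth` is
#' `z` times the empirical standard deviation of `p_hat` across
#' replicates, the brute-force estimate of the planning half-width
#' `z * sqrt(p * (1 - p) / n)` itself, and is the oracle the closed form
#' is tested against.
#'
#' @inheritParams simulate_detection
#' @param conf_level Nominal confidence level (default 0.95).
#' @param z Optional explicit critical value (default: [z_value()]).
#' @return A `sim_result` tibble; `estimate` is the empirical coverage,
#'   `closed_form` the nominal level, plus `mean_halfwidth`,
#'   `se_halfwidth` and `planned_halfwidth` (the formula value at the true
#'   `p`).
#' @examples
#' simulate_wald_coverage(200, 0.5, replicates = 5000, seed = 1)
#' # anti-conservative at small n * p:
#' simulate_wald_coverage(50, 0.01, replicates = 5000, seed = 1)
#' @family simulation
#' @export
simulate_wald_coverage <- function(n, p, replicates = 1e5, seed = 1,
                                   conf_level = 0.95, z = NULL) {
  check_count(n)
  check_open_unit(p)
  check_count(replicates, "replicates")
  z <- resolve_z(z, conf_level)
  res <- local_rng(seed, {
    phat <- rbinom(replicates, n, p) / n
    hw <- z * sqrt(phat * (1 - phat) / n)
    list(
      coverage = mean(abs(phat - p) <= hw),
      mean_hw = mean(hw),
      se_hw = z * sd(phat)
    )
  })
  sim_result(
    mode = "wald_coverage",
    estimate = res$coverage,
    mc_se = sqrt(res$coverage * (1 - res$coverage) / replicates),
    replicates = replicates,
    seed = seed,
    closed_form = conf_level,
    mean_halfwidth = res$mean_hw,
    se_halfwidth = res$se_hw,
    planned_halfwidth = wald_halfwidth(n, p, conf_level, z)
  )
}

# Moment-matched parameterizations: the generated family hits a requested
# population mean and cv exactly.
lognormal_params <- function(mu, cv) {
  sdlog2 <- log1p(cv^2)
  list(meanlog = log(mu) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

gamma_params <- function(mu, cv) {
  list(shape = 1 / cv^2, scale = mu * cv^2)
}

# Positive-part moments for a two-part (zero-inflated) mixture whose
# OVERALL mean and cv are (mu, cv): feasible only while the implied
# positive-part variance stays positive, i.e. zero_prob < cv^2/(1+cv^2).
two_part_params <- function(mu, cv, zero_prob) {
  cv_pos_sq <- (1 + cv^2) * (1 - zero_prob) - 1
  if (cv_pos_sq <= 0) {
    stop_infeasible(sprintf(paste(
      "two_part moment match infeasible: with cv = %g the zero probability",
      "must be below cv^2 / (1 + cv^2) = %.4f (got %g)"),
      cv, cv^2 / (1 + cv^2), zero_prob))
  }
  list(mu_pos = mu / (1 - zero_prob), cv_pos = sqrt(cv_pos_sq))
}

#' Generate synthetic cost data with a target mean and coefficient of variation
#'
#' Draws `n` non-negative costs from a right-skewed family moment-matched
#' so the population mean is `mu` and the population cv is `cv`:
#' lognormal (`meanlog = log(mu) - log(1 + cv^2)/2`,
#' `sdlog = sqrt(log(1 + cv^2))`), gamma (`shape = 1/cv^2`,
#' `scale = mu * cv^2`; cv = 1 is the exponential), or a two-part mixture
#' that is zero with probability `zero_prob` and otherwise lognormal,
#' matched so the overall mean and cv still equal (`mu`, `cv`) -- the
#' "many zero responses plus a few large outliers" shape typical of
#' per-person resource-use costs.
#'
#' @param n Number of values to generate (positive integer).
#' @param mu Target population mean (> 0).
#' @param cv Target population coefficient of variation (> 0).
#' @param family `"lognormal"` (default), `"gamma"`, or `"two_part"`.
#' @param zero_prob Probability of a zero cost (two-part family only;
#'   must satisfy `zero_prob < cv^2 / (1 + cv^2)` for the moment match to
#'   be feasible, otherwise an infeasibility error states the bound).
#' @param seed Optional integer seed for a reproducible sample; `NULL`
#'   uses (and advances) the caller's RNG stream.
#' @return Numeric vector of `n` non-negative costs.
#' @examples
#' x <- generate_costs(1000, mu = 1000, cv = 0.72, seed = 7)
#' mean(x); sd(x) / mean(x)
#' @family simulation
#' @export
generate_costs <- function(n, mu, cv,
                           family = c("lognormal", "gamma", "two_part"),
                           zero_prob = 0, seed = NULL) {
  check_count(n)
  check_positive(mu, "mu")
  check_positive(cv, "cv")
  family <- match.arg(family)
  if (!is.numeric(zero_prob) || length(zero_prob) != 1 || is.na(zero_prob) ||
      zero_prob < 0 || zero_prob >= 1) {
    stop_domain("zero_prob", "must lie in [0, 1)")
  }
  if (zero_prob > 0 && family != "two_part") {
    stop_domain("zero_prob", "is only meaningful for family = \"two_part\"")
  }
  local_rng(seed, draw_costs(n, mu, cv, family, zero_prob))
}

draw_costs <- function(n, mu, cv, family, zero_prob) {
  switch(family,
    lognormal = {
      pars <- lognormal_params(mu, cv)
      rlnorm(n, pars$meanlog, pars$sdlog)
    },
    gamma = {
      pars <- gamma_params(mu, cv)
      rgamma(n, shape = pars$shape, scale = pars$scale)
    },
    two_part = {
      if (zero_prob == 0) {
        # degenerate mixture: identical machinery to the pure positive family
        pars <- lognormal_params(mu, cv)
        rlnorm(n, pars$meanlog, pars$sdlog)
      } else {
        pp <- two_part_params(mu, cv, zero_prob)
        pars <- lognormal_params(pp$mu_pos, pp$cv_pos)
        nonzero <- runif(n) >= zero_prob
        x <- numeric(n)
        x[nonzero] <- rlnorm(sum(nonzero), pars$meanlog, pars$sdlog)
        x
      }
    }
  )
}

#' Monte Carlo coverage of the normal-theory cost interval under skewed data
#'
#' The cost sizing formulas assume the sample mean is normal with known
#' width; real cost data are skewed and often zero-inflated. Per replicate
#' this draws a cost sample of size `n` from the requested family, forms
#' the z-interval `mean +/- z * sd / sqrt(n)` (matching the planning
#' formula; set `interval = "t"` to compare against the Student-t
#' interval), and records whether the true mean `mu` was covered.
#' Coverage below the nominal level quantifies when the normal
#' approximation -- and hence the planning formula -- is optimistic for a
#' given (`n`, `cv`).
#'
#' As in [simulate_wald_coverage()], `mean_halfwidth` is the mean realized
#' plug-in half-width while `se_halfwidth` (`z` times the empirical SD of
#' the replicate sample means) is the brute-force estimate of the planning
#' half-width `z * cv * mu / sqrt(n)` reported in `planned_halfwidth`.
#'
#' @inheritParams generate_costs
#' @param replicates Number of simulated studies (default 10000).
#' @param seed Integer seed (default 1); bit-reproducible.
#' @param conf_level Nominal confidence level (default 0.95).
#' @param zcrit Optional explicit critical value.
#' @param interval `"z"` (default, matches the planning formula) or `"t"`.
#' @return A `sim_result` tibble; `estimate` is the empirical coverage of
#'   the true mean, `closed_form` the nominal level, plus
#'   `mean_halfwidth`, `se_halfwidth`, `planned_halfwidth`.
#' @examples
#' simulate_cost_precision(200, mu = 1000, cv = 0.72,
#'                         replicates = 2000, seed = 1)
#' @family simulation
#' @export
simulate_cost_precision <- function(n, mu, cv,
                                    family = c("lognormal", "gamma",
                                               "two_part"),
                                    zero_prob = 0, replicates = 1e4,
                                    seed = 1, conf_level = 0.95,
                                    zcrit = NULL, interval = c("z", "t")) {
  check_count(n)
  check_positive(mu, "mu")
  check_positive(cv, "cv")
  check_count(replicates, "replicates")
  family <- match.arg(family)
  interval <- match.arg(interval)
  z <- resolve_z(zcrit, conf_level)
  crit <- if (interval == "t") {
    stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  } else {
    z
  }
  if (family == "two_part" && zero_prob > 0) {
    two_part_params(mu, cv, zero_prob)  # fail fast if infeasible
  }
  res <- local_rng(seed, {
    x <- matrix(draw_costs(n * replicates, mu, cv, family, zero_prob),
                nrow = n)
    means <- colMeans(x)
    sds <- sqrt((colSums(x^2) - n * means^2) / (n - 1))
    hw <- crit * sds / sqrt(n)
    list(
      coverage = mean(abs(means - mu) <= hw),
      mean_hw = mean(hw),
      se_hw = z * sd(means)
    )
  })
  sim_result(
    mode = "cost_precision",
    estimate = res$coverage,
    mc_se = sqrt(res$coverage * (1 - res$coverage) / replicates),
    replicates = replicates,
    seed = seed,
    closed_form = conf_level,
    mean_halfwidth = res$mean_hw,
    se_halfwidth = res$se_hw,
    planned_halfwidth = cv_halfwidth(n, cv, mu, conf_level, z)
  )
}
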