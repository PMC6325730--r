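test_that("cost half-width follows z * sigma / sqrt(n)", {
  expect_equal(cost_halfwidth(100, 100), 19.6)
  expect_equal(cost_halfwidth(400, 100), cost_halfwidth(100, 100) / 2)
  # at the reference dispersion cv = 0.72, n = 199 gives almost exactly
  # one tenth of the mean
  expect_equal(cost_halfwidth(199, 0.72), 0.1001, tolerance = 1e-3)
  expect_domain_error(cost_halfwidth(100, -1), "sigma")
})

test_that("n_for_cost_width inverts the width formula with sigma squared", {
  expect_identical(n_for_cost_width(1, 1.96), 1L)
  expect_identical(n_for_cost_width(0.72, 0.10), 200L)
  expect_identical(n_for_cost_width(100, 10), 385L)
  # dimensional sanity: scaling sigma and W together leaves n unchanged
  expect_identical(n_for_cost_width(720, 100), n_for_cost_width(0.72, 0.10))
})

test_that("cv-based width equals the sigma-based width with sigma = cv * mu", {
  expect_equal(cv_halfwidth(200, 0.72, 1000), cost_halfwidth(200, 720))
  expect_equal(cv_halfwidth(200, 0.72, 1000), 99.79, tolerance = 1e-3)
  expect_equal(cv_halfwidth(100, 0.5, 200), 19.6)
  # linear in mu
  expect_equal(cv_halfwidth(150, 0.9, 2), 2 * cv_halfwidth(150, 0.9, 1))
})

test_that("relative-width sample size is (z cv / V)^2 rounded up, mu-free", {
  expect_identical(n_for_relative_width(0.72, 0.10), 200L)
  expect_identical(n_for_relative_width(4.5, 0.10), 7780L)
  expect_identical(n_for_relative_width(0.3 / 1.96, 0.3), 1L)
  expect_domain_error(n_for_relative_width(0.72, 0), "target_relative_width")
  expect_domain_error(n_for_relative_width(0.72, 1.2), "target_relative_width")
  expect_domain_error(n_for_relative_width(0, 0.1), "cv")
})

test_that("absolute-width-via-cv solver agrees with the relative form through V = W/mu", {
  expect_identical(n_for_absolute_width_cv(0.72, 1000, 100), 200L)
  expect_identical(n_for_absolute_width_cv(1.0, 500, 98), 100L)
  for (mu in c(0.5, 1, 37, 1000, 5e5)) {
    expect_identical(n_for_absolute_width_cv(0.9, mu, 0.2 * mu),
                     n_for_relative_width(0.9, 0.2))
  }
})

test_that("required n rises with dispersion and falls with allowed width", {
  cvs <- c(0.1, 0.3, 0.72, 1.5, 3, 4.5)
  expect_true(all(diff(n_for_relative_width(cvs, 0.10)) > 0))
  vs <- c(0.05, 0.10, 0.25, 0.5, 1)
  expect_true(all(diff(n_for_relative_width(2, vs)) < 0))
})

test_that("inverse cost solvers satisfy their forward constraint tightly", {
  set.seed(42)
  for (i in 1:200) {
    cv <- runif(1, 0.05, 5)
    v <- runif(1, 0.01, 1)
    n <- n_for_relative_width(cv, v)
    expect_lte(1.96 * cv / sqrt(n), v)
    if (n > 1) expect_gt(1.96 * cv / sqrt(n - 1), v)
  }
})

test_that("subgroup inflation divides by the population fraction, rounded up", {
  expect_identical(subgroup_inflation(200, 0.20), 1000L)
  expect_identical(subgroup_inflation(100, 0.33), 304L)
  expect_identical(subgroup_inflation(123, 1.0), 123L)
  expect_domain_error(subgroup_inflation(100, 0), "subgroup_fraction")
  expect_domain_error(subgroup_inflation(100, 1.1), "subgroup_fraction")
})

test_that("estimate_cv computes sd/mean with the n-1 denominator", {
  x <- c(120, 80, 310, 45, 220)
  est <- estimate_cv(x)
  expect_s3_class(est, "cv_estimate")
  expect_equal(est$cv, sd(x) / mean(x))
  expect_identical(est$n_obs, 5L)
  expect_false(est$zeros_excluded)
  # scale invariance
  expect_equal(estimate_cv(3.7 * x)$cv, est$cv)
})

test_that("zero handling and log transformation behave as documented", {
  x <- c(0, 0, 150, 90, 400, 0, 60)
  with_zeros <- estimate_cv(x)
  per_user <- estimate_cv(x, exclude_zeros = TRUE)
  expect_identical(per_user$n_obs, 4L)
  expect_true(per_user$zeros_excluded)
  # zeros inflate the cv; excluding them shrinks it
  expect_lt(per_user$cv, with_zeros$cv)
  # log of zero is refused with a pointer to zero exclusion
  expect_domain_error(estimate_cv(x, log_transform = TRUE))
  logged <- estimate_cv(x, exclude_zeros = TRUE, log_transform = TRUE)
  expect_equal(logged$cv, sd(log(c(150, 90, 400, 60))) /
                 mean(log(c(150, 90, 400, 60))))
  expect_true(logged$log_transformed)
})

test_that("estimate_cv rejects unusable input and warns on zero variance", {
  expect_error(estimate_cv(c(5)), class = "chartsize_insufficient_data_error")
  expect_error(estimate_cv(c(0, 0, 0, 5), exclude_zeros = TRUE),
               class = "chartsize_insufficient_data_error")
  expect_domain_error(estimate_cv(c(-1, 2, 3)))
  expect_warning(est <- estimate_cv(c(5, 5, 5, 5)), "cv is 0")
  expect_equal(est$cv, 0)
})

test_that("estimate_cv recovers the population cv of a lognormal sample", {
  # population cv of a lognormal is sqrt(exp(sdlog^2) - 1); with
  # sdlog^2 = log(1 + 0.72^2) the population cv is exactly 0.72
  set.seed(1905)
  x <- rlnorm(10000, log(1000) - log(1 + 0.72^2) / 2, sqrt(log(1 + 0.72^2)))
  est <- estimate_cv(x)
  expect_equal(est$cv, 0.72, tolerance = 0.05)
})

test_that("the data-frame method estimates one cv per numeric column", {
  df <- data.frame(hosp = c(0, 500, 1200, 0, 800),
                   outpt = c(60, 80, 75, 90, 66),
                   site = letters[1:5])
  est <- estimate_cv(df, exclude_zeros = TRUE)
  expect_identical(est$label, c("hosp", "outpt"))
  expect_identical(est$n_obs, c(3L, 5L))
  # NA cells (ragged CSV columns) are dropped
  df$hosp[2] <- NA
  expect_identical(estimate_cv(df, exclude_zeros = TRUE)$n_obs[1], 2L)
})

test_that("summarize_cv reports order statistics with the even-count median", {
  expect_equal(summarize_cv(c(0.5, 0.7, 0.9, 1.1))$cv_median, 0.8)
  one <- summarize_cv(tibble::tibble(cv = 0.9))
  expect_equal(unlist(one[1, c("cv_min", "cv_median", "cv_max")]),
               c(cv_min = 0.9, cv_median = 0.9, cv_max = 0.9))
  expect_domain_error(summarize_cv(numeric(0)))
  expect_domain_error(summarize_cv(tibble::tibble(x = 1)))
})

test_that("the packaged melanoma cv fixture is intact", {
  mel <- melody_cv()
  expect_identical(nrow(mel), 18L)
  expect_identical(sort(unique(mel$jurisdiction)), c("France", "Italy", "UK"))
  expect_identical(sort(unique(mel$basis)), c("per_person", "per_user"))
  # each printed cv agrees with its printed mean and sd at 2-decimal rounding
  expect_true(all(abs(mel$sd / mel$mean - mel$cv) < 0.0151))
  # per-person dispersion exceeds per-user dispersion category by category
  wide <- tidyr::pivot_wider(mel[, c("jurisdiction", "category", "basis", "cv")],
                             names_from = "basis", values_from = "cv")
  expect_true(all(wide$per_person >= wide$per_user))
})
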