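test_that("expected counts are n * p, unrounded", {
  expect_equal(expected_count(200, 0.05), 10)
  expect_equal(expected_count(300, 0.05), 15)
  expect_equal(expected_count(1, 0.5), 0.5)
  expect_equal(expected_count(c(50, 100), 0.01), c(0.5, 1))
})

test_that("degenerate or malformed designs are rejected with the offending field", {
  expect_domain_error(expected_count(0, 0.5), "n")
  expect_domain_error(expected_count(2.5, 0.5), "n")
  expect_domain_error(expected_count(10, 0), "p")
  expect_domain_error(expected_count(10, 1), "p")
  expect_domain_error(wald_halfwidth(10, -0.1), "p")
  expect_domain_error(wald_halfwidth(10, 0.5, z = -2), "z")
  expect_domain_error(detection_probability(10, 1.2), "p")
})

test_that("Wald half-width follows z * sqrt(p(1-p)/n)", {
  expect_equal(wald_halfwidth(200, 0.05), 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_equal(round(wald_halfwidth(200, 0.05), 2), 0.03)
  expect_equal(round(wald_halfwidth(50, 0.01), 4), 0.0276)
  # 1/sqrt(n) scaling: quadrupling n halves the width exactly
  expect_equal(wald_halfwidth(400, 0.5), wald_halfwidth(100, 0.5) / 2)
  # symmetric in p <-> 1 - p
  expect_equal(wald_halfwidth(123, 0.2), wald_halfwidth(123, 0.8))
})

test_that("Wald half-width is decreasing in n and maximized at p = 0.5", {
  ns <- c(10, 20, 50, 100, 500, 1000)
  hw <- wald_halfwidth(ns, 0.3)
  expect_true(all(diff(hw) < 0))
  ps <- seq(0.05, 0.95, by = 0.05)
  hw_p <- wald_halfwidth(100, ps)
  expect_equal(ps[which.max(hw_p)], 0.5)
})

test_that("the literal 1.96 is used at the 0.95 level, exact quantile on request", {
  expect_identical(z_value(), 1.96)
  expect_equal(z_value(exact = TRUE), qnorm(0.975))
  expect_equal(z_value(0.90), qnorm(0.95))
  expect_equal(wald_halfwidth(100, 0.5, conf_level = 0.90),
               qnorm(0.95) * 0.05)
})

test_that("detection probability is 1 - (1-p)^n with the expected behaviour", {
  expect_equal(detection_probability(50, 0.01), 1 - 0.99^50)
  expect_equal(round(detection_probability(50, 0.01), 2), 0.39)
  expect_equal(round(detection_probability(100, 0.01), 2), 0.63)
  # one chart: detection equals the frequency itself
  expect_equal(detection_probability(1, 0.25), 0.25)
  # strictly increasing in n and p, limiting to 1
  expect_true(all(diff(detection_probability(c(1, 5, 20, 100, 1000), 0.1)) > 0))
  expect_true(all(diff(detection_probability(80, c(0.01, 0.05, 0.2, 0.7))) > 0))
  expect_equal(detection_probability(1e6, 0.05), 1, tolerance = 1e-12)
})

test_that("expected_ci composes count, detection and a clamped interval", {
  res <- expected_ci(200, 0.05)
  expect_s3_class(res, "tbl_df")
  expect_equal(round(res$ci_lower, 2), 0.02)
  expect_equal(round(res$ci_upper, 2), 0.08)
  expect_equal(res$ci_upper - res$ci_lower, 2 * res$halfwidth)

  # lower bound clamps to 0 when p - halfwidth < 0
  low <- expected_ci(50, 0.01)
  expect_identical(low$ci_lower, 0)
  expect_true(low$ci_upper - low$ci_lower < 2 * low$halfwidth)

  # symmetric about 0.5 and clamped within [0, 1] for tiny n
  sym <- expected_ci(4, 0.5)
  expect_true(sym$ci_lower >= 0 && sym$ci_upper <= 1)
  expect_equal(sym$ci_lower + sym$ci_upper, 1)
})

test_that("n_for_halfwidth returns the smallest satisfying integer", {
  expect_identical(n_for_halfwidth(0.5, 0.07), 196L)
  expect_identical(n_for_halfwidth(0.05, 0.03), 203L)
  expect_identical(n_for_halfwidth(0.5, 0.99), 1L)
  expect_domain_error(n_for_halfwidth(0.5, 0), "target_halfwidth")
  expect_domain_error(n_for_halfwidth(0.5, 1), "target_halfwidth")
})

test_that("n_for_detection returns the smallest satisfying integer", {
  expect_identical(n_for_detection(0.01, 0.95), 299L)
  expect_identical(n_for_detection(0.05, 0.99), 90L)
  expect_identical(n_for_detection(0.5, 0.5), 1L)
  # a certain-detection target is unreachable with finite n
  expect_domain_error(n_for_detection(0.1, 1), "target_prob")
})

test_that("min_detectable_p inverts detection_probability exactly", {
  expect_equal(min_detectable_p(1, 0.25), 0.25)
  expect_equal(min_detectable_p(299, 0.95), 0.00997, tolerance = 1e-3)
  expect_equal(min_detectable_p(459, 0.99), 0.01, tolerance = 2e-3)
  for (n in c(1, 7, 50, 299, 459, 10000)) {
    for (g in c(0.1, 0.5, 0.9, 0.95, 0.99)) {
      expect_equal(detection_probability(n, min_detectable_p(n, g)), g,
                   tolerance = 1e-12)
    }
  }
  expect_domain_error(min_detectable_p(100, 1), "target_prob")
})

test_that("exact interval matches the classical equal-tailed construction", {
  # boundary cases
  zero <- exact_interval(0, 10)
  expect_identical(zero$ci_lower, 0)
  full <- exact_interval(10, 10)
  expect_identical(full$ci_upper, 1)
  # mirroring successes -> n - successes reflects the interval about 0.5
  a <- exact_interval(3, 10)
  b <- exact_interval(7, 10)
  expect_equal(a$ci_lower, 1 - b$ci_upper)
  expect_equal(a$ci_upper, 1 - b$ci_lower)
  # independent oracle: stats::binom.test
  for (x in c(0, 1, 10, 100, 200)) {
    ref <- binom.test(x, 200)$conf.int
    got <- exact_interval(x, 200)
    expect_equal(got$ci_lower, ref[1], tolerance = 1e-10)
    expect_equal(got$ci_upper, ref[2], tolerance = 1e-10)
    expect_true(got$ci_lower <= x / 200 && x / 200 <= got$ci_upper)
  }
  expect_domain_error(exact_interval(11, 10), "successes")
})

test_that("the exact interval exposes Wald anti-conservatism at small n*p", {
  # at 10/200 observed, the exact interval is wider than the planning Wald
  exact <- exact_interval(10, 200)
  wald <- expected_ci(200, 0.05)
  expect_true(exact$ci_upper - exact$ci_lower >
              wald$ci_upper - wald$ci_lower)
})
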