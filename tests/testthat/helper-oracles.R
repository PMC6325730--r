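# Brute-force oracles, independent of the solver implementations.

# Smallest n meeting a forward half-width constraint, by linear scan.
scan_n_relative <- function(cv, v, z = 1.96) {
  n <- 1
  while (z * cv / sqrt(n) > v) n <- n + 1
  n
}

# Monte Carlo standard error of an empirical-SD estimate of scale `s`
# from R replicates of an estimator with excess kurtosis gamma2.
mc_se_sd <- function(s, replicates, gamma2 = 0) {
  s * sqrt((2 + gamma2) / (4 * replicates))
}

expect_domain_error <- function(expr, field = NULL) {
  err <- expect_error(expr, class = "chartsize_domain_error")
  if (!is.null(field)) expect_identical(err$field, field)
  invisible(err)
}
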