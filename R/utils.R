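# Internal validation and numeric helpers shared across modules.

stop_domain <- function(field, msg) {
  abort(sprintf("`%s` %s", field, msg),
        class = "chartsize_domain_error", field = field)
}

stop_usage <- function(msg, ...) {
  abort(msg, class = "chartsize_usage_error", ...)
}

stop_infeasible <- function(msg, ...) {
  abort(msg, class = "chartsize_infeasible_error", ...)
}

check_count <- function(n, field = "n") {
  if (!is.numeric(n) || length(n) < 1 || anyNA(n) ||
      any(n < 1) || any(n != floor(n))) {
    stop_domain(field, "must be a positive integer (>= 1)")
  }
  invisible(n)
}

check_open_unit <- function(p, field = "p") {
  if (!is.numeric(p) || length(p) < 1 || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop_domain(field, "must lie strictly between 0 and 1")
  }
  invisible(p)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) < 1 || anyNA(x) || any(x <= 0)) {
    stop_domain(field, "must be a positive number")
  }
  invisible(x)
}

#' Critical value for a two-sided confidence level
#'
#' By convention in the sample-size literature the 95% level is paired with
#' the literal critical value 1.96, and every tabulated result here is
#' computed with that literal so printed tables reproduce digit-for-digit.
#' `z_value()` returns 1.96 for `conf_level = 0.95` unless `exact = TRUE`,
#' in which case the true normal quantile (1.959964...) is used. Any other
#' confidence level always uses the exact quantile.
#'
#' @param conf_level Two-sided confidence level in (0, 1). Default 0.95.
#' @param exact If `TRUE`, return `qnorm(1 - (1 - conf_level)/2)` even at
#'   the 0.95 level.
#' @return A positive scalar critical value.
#' @examples
#' z_value()                 # 1.96
#' z_value(exact = TRUE)     # 1.959964
#' z_value(0.90)             # 1.644854
#' @export
z_value <- function(conf_level = 0.95, exact = FALSE) {
  check_open_unit(conf_level, "conf_level")
  if (!exact && isTRUE(all.equal(conf_level, 0.95))) {
    return(1.96)
  }
  qnorm(1 - (1 - conf_level) / 2)
}

# Resolve the critical value from an explicit z or a confidence level.
resolve_z <- function(z, conf_level = 0.95) {
  if (is.null(z)) {
    return(z_value(conf_level))
  }
  check_positive(z, "z")
  z
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published precision tables round half
#' up (2.5 charts -> 3). Used for all display rounding; full-precision values
#' are always available programmatically.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(2.5, 37.5))      # 3, 38
#' round_half_up(0.125, 2)          # 0.13
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m + 0.5 * sign(x)) / m
}

# sprintf-style fixed display used by the table renderers.
fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_rng <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  check_seed(seed)
  withr::with_seed(as.integer(seed), force(code))
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != floor(seed)) {
    stop_domain("seed", "must be a single integer")
  }
  invisible(seed)
}
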