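#' Specify a categorical-outcome (treatment pattern) design
#'
#' Bundles the design parameters for a categorical chart-review outcome --
#' number of charts and anticipated treatment frequency -- into an object
#' with [tidy()] / [glance()] methods, so a design can be stated once and
#' summarized with the full set of precision quantities.
#'
#' @param n Number of charts (positive integer).
#' @param p Anticipated probability of receiving the treatment, in (0, 1).
#'   Degenerate values 0 and 1 are rejected: a precision query about a
#'   treatment that is never or always given is a specification error.
#' @param conf_level Confidence level, default 0.95.
#' @param z Optional explicit critical value (default [z_value()]).
#' @return An object of class `binomial_design`.
#' @examples
#' d <- binomial_design(200, 0.05)
#' glance(d)
#' @family design objects
#' @export
binomial_design <- function(n, p, conf_level = 0.95, z = NULL) {
  check_count(n)
  check_open_unit(p)
  check_open_unit(conf_level, "conf_level")
  structure(
    list(n = as.integer(n), p = p, conf_level = conf_level,
         z = resolve_z(z, conf_level)),
    class = "binomial_design"
  )
}

#' Specify a continuous-cost design
#'
#' Bundles the parameters for a cost outcome. Dispersion may be given as a
#' standard deviation `sigma`, a coefficient of variation `cv`, or both
#' (in which case they must agree: `sigma = cv * mu`).
#'
#' @param n Number of charts (positive integer), or `NULL` when the design
#'   is to be solved for `n`.
#' @param mu Mean cost (> 0), or `NULL` if only relative precision is of
#'   interest.
#' @param sigma Standard deviation (> 0), or `NULL`.
#' @param cv Coefficient of variation (> 0), or `NULL`.
#' @param conf_level Confidence level, default 0.95.
#' @param z Optional explicit critical value.
#' @return An object of class `cost_design` with any derivable missing
#'   member (`sigma` from `cv * mu` or vice versa) filled in.
#' @examples
#' d <- cost_design(n = 200, mu = 1000, cv = 0.72)
#' glance(d)
#' @family design objects
#' @export
cost_design <- function(n = NULL, mu = NULL, sigma = NULL, cv = NULL,
                        conf_level = 0.95, z = NULL) {
  if (!is.null(n)) check_count(n)
  if (!is.null(mu)) check_positive(mu, "mu")
  if (!is.null(sigma)) check_positive(sigma, "sigma")
  if (!is.null(cv)) check_positive(cv, "cv")
  if (!is.null(sigma) && !is.null(cv) && !is.null(mu)) {
    if (abs(sigma - cv * mu) > 1e-9 * max(sigma, cv * mu)) {
      stop_domain("sigma", "disagrees with cv * mu; provide consistent values")
    }
  }
  if (is.null(sigma) && !is.null(cv) && !is.null(mu)) sigma <- cv * mu
  if (is.null(cv) && !is.null(sigma) && !is.null(mu)) cv <- sigma / mu
  structure(
    list(n = if (is.null(n)) NULL else as.integer(n), mu = mu, sigma = sigma,
         cv = cv, conf_level = conf_level, z = resolve_z(z, conf_level)),
    class = "cost_design"
  )
}

#' @export
print.binomial_design <- function(x, ...) {
  cat(sprintf(
    "<binomial_design> n = %d, p = %g, conf_level = %g (z = %g)\n",
    x$n, x$p, x$conf_level, x$z))
  invisible(x)
}

#' @export
print.cost_design <- function(x, ...) {
  show <- function(v) if (is.null(v)) "?" else format(v)
  cat(sprintf(
    "<cost_design> n = %s, mu = %s, sigma = %s, cv = %s, conf_level = %g\n",
    show(x$n), show(x$mu), show(x$sigma), show(x$cv), x$conf_level))
  invisible(x)
}

#' Tidy a design object into its parameters
#'
#' @param x A [binomial_design()] or [cost_design()].
#' @param ... Unused.
#' @return A one-row tibble of the design parameters (`NA` where unset).
#' @family design objects
#' @export
tidy.binomial_design <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, conf_level = x$conf_level, z = x$z)
}

#' @rdname tidy.binomial_design
#' @export
tidy.cost_design <- function(x, ...) {
  tibble::tibble(
    n = x$n %||% NA_integer_,
    mu = x$mu %||% NA_real_,
    sigma = x$sigma %||% NA_real_,
    cv = x$cv %||% NA_real_,
    conf_level = x$conf_level,
    z = x$z
  )
}

#' One-row precision summary of a design
#'
#' For a categorical design: the expected count, detection probability,
#' half-width and expected interval. For a cost design with `n` and
#' dispersion available: the expected half-width, in currency units (and,
#' when `mu` is present, as a fraction of the mean).
#'
#' @param x A [binomial_design()] or [cost_design()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @family design objects
#' @export
glance.binomial_design <- function(x, ...) {
  expected_ci(x$n, x$p, x$conf_level, x$z)
}

#' @rdname glance.binomial_design
#' @export
glance.cost_design <- function(x, ...) {
  if (is.null(x$n) || is.null(x$sigma)) {
    stop_domain("x", "needs both `n` and a dispersion (sigma or cv + mu) for a precision summary")
  }
  hw <- cost_halfwidth(x$n, x$sigma, x$conf_level, x$z)
  tibble::tibble(
    n = x$n,
    mu = x$mu %||% NA_real_,
    sigma = x$sigma,
    cv = x$cv %||% NA_real_,
    halfwidth = hw,
    relative_halfwidth = if (is.null(x$mu)) NA_real_ else hw / x$mu,
    ci_lower = if (is.null(x$mu)) NA_real_ else x$mu - hw,
    ci_upper = if (is.null(x$mu)) NA_real_ else x$mu + hw
  )
}
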