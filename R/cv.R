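#' Estimate a coefficient of variation from pilot cost data
#'
#' Computes `cv = sd / mean` (sample standard deviation, `n - 1`
#' denominator) from pilot observations of a cost outcome, with the two
#' tail-taming options used when raw cost data are too skewed to yield a
#' feasible sample size: excluding zero-cost records (sizing "per user" of
#' a resource category rather than per person) and/or log-transforming the
#' retained values before computing the ratio. Both choices are recorded in
#' the result so downstream reports can state how the cv was obtained.
#'
#' @param x A numeric vector of non-negative costs, or a data frame whose
#'   numeric columns are cost categories (one estimate per column; `NA`
#'   cells are dropped).
#' @param ... Passed between methods.
#' @param exclude_zeros Drop zero values before estimating. Default `FALSE`.
#' @param log_transform Estimate on `log(x)` of the retained values; all
#'   retained values must then be positive (exclude zeros first). Default
#'   `FALSE`.
#' @param label Free-text label for the estimate (e.g. cost category);
#'   defaults to the column name for data frames, `""` for vectors.
#' @return A tibble of class `cv_estimate` with columns `label`, `cv`,
#'   `n_obs`, `mean`, `sd`, `zeros_excluded`, `log_transformed`. A cv of 0
#'   (all retained values equal) is returned with a warning, since the
#'   sizing formulas require cv > 0.
#' @examples
#' estimate_cv(c(120, 80, 0, 310, 45), exclude_zeros = TRUE)
#' estimate_cv(data.frame(hosp = c(0, 500, 1200), outpt = c(60, 80, 75)))
#' @family coefficient of variation
#' @export
estimate_cv <- function(x, ...) {
  UseMethod("estimate_cv")
}

#' @rdname estimate_cv
#' @export
estimate_cv.numeric <- function(x, exclude_zeros = FALSE,
                                log_transform = FALSE, label = "", ...) {
  vals <- x[!is.na(x)]
  if (any(vals < 0)) {
    stop_domain("x", "must contain only non-negative costs")
  }
  if (exclude_zeros) {
    vals <- vals[vals != 0]
  }
  if (length(vals) < 2) {
    abort("fewer than 2 usable values after filtering; cannot estimate a cv",
          class = c("chartsize_insufficient_data_error",
                    "chartsize_domain_error"))
  }
  if (log_transform) {
    if (any(vals == 0)) {
      stop_domain("x", paste(
        "contains zero values; log-transformation requires positive values",
        "(set exclude_zeros = TRUE first)"))
    }
    vals <- log(vals)
  }
  m <- mean(vals)
  if (m <= 0) {
    stop_domain("x", "has non-positive mean after filtering/transformation")
  }
  s <- sd(vals)
  cv <- s / m
  if (cv == 0) {
    warn("estimated cv is 0 (no variability); sizing formulas require cv > 0")
  }
  out <- tibble::tibble(
    label = label,
    cv = cv,
    n_obs = length(vals),
    mean = m,
    sd = s,
    zeros_excluded = exclude_zeros,
    log_transformed = log_transform
  )
  class(out) <- c("cv_estimate", class(out))
  out
}

#' @rdname estimate_cv
#' @export
estimate_cv.data.frame <- function(x, exclude_zeros = FALSE,
                                   log_transform = FALSE, ...) {
  cols <- x[vapply(x, is.numeric, logical(1))]
  if (ncol(cols) == 0) {
    stop_domain("x", "has no numeric columns to estimate from")
  }
  out <- purrr::map2(cols, names(cols), function(v, nm) {
    estimate_cv(v, exclude_zeros = exclude_zeros,
                log_transform = log_transform, label = nm)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("cv_estimate", class(out))
  out
}

#' Summarize a collection of coefficient-of-variation estimates
#'
#' Order statistics of a set of cv values, as used to report the plausible
#' dispersion range from a reference study. The median of an even count is
#' the mean of the two central values.
#'
#' @param data A data frame with a `cv` column (e.g. from [estimate_cv()]
#'   or [melody_cv()]), or a bare numeric vector of cv values.
#' @return A one-row tibble with columns `cv_min`, `cv_median`, `cv_max`,
#'   `n`.
#' @examples
#' summarize_cv(melody_cv())   # 0.26 / 0.72 / 4.30 over 18 categories
#' @family coefficient of variation
#' @export
summarize_cv <- function(data) {
  cv <- if (is.data.frame(data)) {
    if (!"cv" %in% names(data)) {
      stop_domain("data", "must contain a `cv` column")
    }
    data$cv
  } else {
    data
  }
  cv <- cv[!is.na(cv)]
  if (length(cv) == 0) {
    stop_domain("data", "contains no cv values")
  }
  check_positive(cv, "cv")
  tibble::tibble(
    cv_min = min(cv),
    cv_median = median(cv),
    cv_max = max(cv),
    n = length(cv)
  )
}

#' Observed coefficients of variation from the MELODY melanoma chart review
#'
#' The 18 coefficient-of-variation values for medical cost categories
#' observed in a multinational (UK, Italy, France) retrospective chart
#' review of advanced melanoma (n = 655), transcribed from the published
#' summary table. Costs were summarized both per person (all patients,
#' zeros included) and per user (the subset with non-zero use of the
#' category); per-person cv values are systematically larger. These values
#' calibrate what "plausible dispersion" looks like for cost outcomes when
#' no pilot data exist: the cv ranges 0.26-4.30 with median 0.72.
#'
#' @return A tibble with 18 rows and columns `jurisdiction`, `category`,
#'   `basis` (`"per_person"` or `"per_user"`), `mean`, `sd`, `cv` (means
#'   and SDs in the original currencies; only `cv` is dimensionless and
#'   comparable across jurisdictions).
#' @examples
#' summarize_cv(melody_cv())
#' @family coefficient of variation
#' @export
melody_cv <- function() {
  path <- system.file("extdata", "melody_cv.csv", package = "chartsize",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
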