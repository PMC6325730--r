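#' Precision lookup grid for categorical outcomes
#'
#' Crosses candidate sample sizes with candidate treatment frequencies and
#' computes, for every cell, the expected number of observed patients, the
#' probability of observing the treatment at least once, and the expected
#' Wald half-width with its interval. The defaults reproduce the published
#' 6 x 6 planning table (n in \{50, 100, 200, 300, 500, 1000\}, p in
#' \{0.01, 0.05, 0.10, 0.25, 0.50, 0.75\}).
#'
#' @param ns Increasing vector of sample sizes.
#' @param ps Increasing vector of treatment frequencies in (0, 1).
#' @param conf_level Confidence level, default 0.95.
#' @param z Optional explicit critical value.
#' @return A tibble of class `precision_grid` in long form, one row per
#'   (p, n) cell, with the columns of [expected_ci()].
#' @examples
#' grid <- precision_grid()
#' dplyr::filter(grid, n == 200, p == 0.05)
#' cat(render_grid(grid))
#' @family presentation
#' @export
precision_grid <- function(ns = c(50L, 100L, 200L, 300L, 500L, 1000L),
                           ps = c(0.01, 0.05, 0.10, 0.25, 0.50, 0.75),
                           conf_level = 0.95, z = NULL) {
  check_count(ns, "ns")
  check_open_unit(ps, "ps")
  if (is.unsorted(ns, strictly = TRUE)) {
    stop_domain("ns", "must be strictly increasing")
  }
  if (is.unsorted(ps, strictly = TRUE)) {
    stop_domain("ps", "must be strictly increasing")
  }
  cells <- tidyr::expand_grid(p = ps, n = as.integer(ns))
  out <- expected_ci(cells$n, cells$p, conf_level, z)
  attr(out, "conf_level") <- conf_level
  attr(out, "z") <- resolve_z(z, conf_level)
  class(out) <- c("precision_grid", class(out))
  out
}

#' Required sample size as a function of the coefficient of variation
#'
#' Evaluates the relative-width sample size formula
#' `n = ceiling((z * cv / V)^2)` over a range of cv values, producing the
#' data behind a sample-size-versus-dispersion curve. A cv of exactly 0
#' (no variability) is mapped to n = 1 so curves may start at the origin
#' of the cv axis.
#'
#' @param cv_min,cv_max Curve range, `0 <= cv_min < cv_max`.
#' @param target_relative_width Desired half-width as a fraction of the
#'   mean, in (0, 1\].
#' @param points Number of evaluation points (default 200), equally spaced
#'   and strictly increasing in cv.
#' @inheritParams precision_grid
#' @return A tibble of class `samplesize_curve` with columns `cv` and `n`
#'   (`n` non-decreasing in `cv`).
#' @examples
#' crv <- samplesize_curve(0, 4.5, target_relative_width = 0.10)
#' dplyr::filter(crv, abs(cv - 0.72) < 0.02)
#' @family presentation
#' @export
samplesize_curve <- function(cv_min = 0, cv_max = 4.5,
                             target_relative_width = 0.10, points = 200L,
                             conf_level = 0.95, z = NULL) {
  if (!is.numeric(cv_min) || !is.numeric(cv_max) || length(cv_min) != 1 ||
      length(cv_max) != 1 || is.na(cv_min) || is.na(cv_max) ||
      cv_min < 0 || cv_min >= cv_max) {
    stop_domain("cv_min", "and `cv_max` must satisfy 0 <= cv_min < cv_max")
  }
  check_count(points, "points")
  cvs <- seq(cv_min, cv_max, length.out = points)
  n <- integer(points)
  pos <- cvs > 0
  n[!pos] <- 1L
  if (any(pos)) {
    n[pos] <- n_for_relative_width(cvs[pos], target_relative_width,
                                   conf_level, z)
  }
  out <- tibble::tibble(cv = cvs, n = n)
  attr(out, "target_relative_width") <- target_relative_width
  attr(out, "z") <- resolve_z(z, conf_level)
  class(out) <- c("samplesize_curve", class(out))
  out
}

#' Render a precision grid as a table
#'
#' Serializes a [precision_grid()] deterministically. The `"text"` and
#' `"markdown"` formats mimic the published cell style
#' `"count (detection) ±halfwidth"` at display rounding (counts half-up to
#' integers, probabilities and widths to two decimals); `"csv"` and
#' `"json"` are long-form machine formats carrying full-precision values
#' that parse back losslessly.
#'
#' @param grid A `precision_grid`.
#' @param format One of `"text"`, `"csv"`, `"markdown"`, `"json"`.
#' @return A single string.
#' @examples
#' cat(render_grid(precision_grid(), "markdown"))
#' @family presentation
#' @export
render_grid <- function(grid, format = c("text", "csv", "markdown", "json")) {
  if (!inherits(grid, "precision_grid") || nrow(grid) == 0) {
    stop_domain("grid", "must be a populated precision_grid")
  }
  if (!is.character(format) || !all(format %in%
        c("text", "csv", "markdown", "json"))) {
    stop_usage(paste("unknown format; valid formats are:",
                     "text, csv, markdown, json"))
  }
  format <- match.arg(format)
  switch(format,
    text = render_grid_cells(grid, markdown = FALSE),
    markdown = render_grid_cells(grid, markdown = TRUE),
    csv = render_csv(grid),
    json = jsonlite::toJSON(as.data.frame(grid), dataframe = "rows",
                            digits = I(17), pretty = TRUE)
  )
}

grid_cell_label <- function(expected_count, detection_prob, halfwidth) {
  sprintf("%d (%s) ±%s",
          as.integer(round_half_up(expected_count)),
          fmt2(detection_prob), fmt2(halfwidth))
}

render_grid_cells <- function(grid, markdown) {
  wide <- grid |>
    dplyr::mutate(cell = grid_cell_label(.data$expected_count,
                                         .data$detection_prob,
                                         .data$halfwidth),
                  n = paste0("n = ", .data$n)) |>
    dplyr::select("p", "n", "cell") |>
    tidyr::pivot_wider(names_from = "n", values_from = "cell") |>
    dplyr::mutate(p = sprintf("p = %.2f", .data$p))
  mat <- as.matrix(wide)
  colnames(mat)[1] <- ""
  widths <- pmax(nchar(colnames(mat)), apply(nchar(mat), 2, max))
  pad <- function(row) mapply(formatC, row, width = widths, flag = "-")
  if (markdown) {
    lines <- c(
      paste0("| ", paste(pad(colnames(mat)), collapse = " | "), " |"),
      paste0("|", paste(strrep("-", widths + 2), collapse = "|"), "|"),
      apply(mat, 1, function(r) {
        paste0("| ", paste(pad(r), collapse = " | "), " |")
      })
    )
  } else {
    lines <- c(
      paste(pad(colnames(mat)), collapse = "  "),
      apply(mat, 1, function(r) paste(pad(r), collapse = "  "))
    )
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

# Full-precision CSV serialization (17 significant digits round-trips
# doubles exactly).
render_csv <- function(df) {
  df <- as.data.frame(df)
  fmt_col <- function(x) {
    if (is.double(x)) formatC(x, digits = 17, format = "g") else as.character(x)
  }
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(df[i, , drop = FALSE], fmt_col, character(1)),
          collapse = ",")
  }, character(1))
  paste0(paste(c(paste(names(df), collapse = ","), body), collapse = "\n"),
         "\n")
}
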