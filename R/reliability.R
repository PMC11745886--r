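#' Intra-rater reliability: ICC, SEM and categories
#'
#' Test-retest reliability of repeated acquisitions or analyses is
#' summarised by the intraclass correlation coefficient and the standard
#' error of measurement, `SEM = SD * sqrt(1 - ICC)`.
#'
#' @name reliability
NULL

validate_reliability_table <- function(table) {
  table <- as.matrix(table)
  if (!is.numeric(table) || any(!is.finite(table))) {
    stop("reliability table must be numeric with no missing cells")
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("reliability table needs >= 2 subjects (rows) and >= 2 sessions (columns)")
  }
  table
}

#' Intraclass correlation coefficient, ICC(3,1)
#'
#' Two-way mixed-effects, single-measures, consistency form:
#' `ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS)`, where `BMS` is the
#' between-subjects mean square and `EMS` the residual mean square of the
#' two-way (subject x session) ANOVA decomposition. This is the standard
#' form for intra-rater test-retest designs with a fixed rater.
#'
#' @param table Numeric matrix: rows = subjects (`n >= 2`), columns =
#'   sessions/repeats (`k >= 2`), no missing cells.
#' @param form Reliability model; only `"two_way_mixed_consistency"`
#'   (ICC(3,1)) is implemented.
#' @return ICC estimate in `(-1, 1]`. A zero between-subject variance
#'   triggers a degenerate-table warning but still returns the computed
#'   value.
#' @export
icc <- function(table, form = "two_way_mixed_consistency") {
  form <- match.arg(form, "two_way_mixed_consistency")
  x <- validate_reliability_table(table)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  if (bms <= .Machine$double.eps * ss_tot) {
    warning("zero between-subject variance: ICC is degenerate")
  }
  (bms - ems) / (bms + (k - 1) * ems)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`, with SD the standard deviation over all
#' cells of the reliability table. Expressed in the units of the measure.
#'
#' @inheritParams icc
#' @param icc_value ICC estimate (`<= 1`).
#' @return SEM (`>= 0`).
#' @export
sem <- function(table, icc_value) {
  x <- validate_reliability_table(table)
  if (!is.finite(icc_value) || icc_value > 1) {
    stop("icc_value must be finite and <= 1")
  }
  stats::sd(as.vector(x)) * sqrt(1 - icc_value)
}

#' Categorical interpretation of an ICC value
#'
#' poor `< 0.4`; fair `0.4-0.7` (both endpoints included); good
#' `(0.7, 0.9]`; excellent `> 0.9`.
#'
#' @param icc_value Finite ICC estimate.
#' @return One of `"poor"`, `"fair"`, `"good"`, `"excellent"`.
#' @export
classify_icc <- function(icc_value) {
  if (!is.finite(icc_value)) stop("icc_value must be finite")
  if (icc_value < 0.4) "poor"
  else if (icc_value <= 0.7) "fair"
  else if (icc_value <= 0.9) "good"
  else "excellent"
}

#' Full reliability summary of a subjects-by-sessions table
#'
#' @inheritParams icc
#' @param measure_name Label carried into the result.
#' @return A list of class `reliability_result`: `icc`, `sem`, `category`,
#'   `n`, `k`, `measure_name`.
#' @export
reliability_summary <- function(table, measure_name = "measure") {
  x <- validate_reliability_table(table)
  r <- icc(x)
  structure(list(icc = r, sem = sem(x, r), category = classify_icc(r),
                 n = nrow(x), k = ncol(x), measure_name = measure_name),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability '%s'> ICC(3,1) = %.3f (%s), SEM = %.4f (n=%d, k=%d)\n",
              x$measure_name, x$icc, x$category, x$sem, x$n, x$k))
  invisible(x)
}
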