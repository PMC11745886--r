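#' Group summary triplet
#'
#' `(mean, sd, n)` for one group, the unit of the summary-statistics ANOVA.
#'
#' @param label Group label.
#' @param mean,sd Sample mean and standard deviation (`sd >= 0`).
#' @param n Sample size (`>= 2`).
#' @return A list of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0) {
    stop("mean must be finite and sd finite and >= 0")
  }
  if (n < 2) stop("group '", label, "' needs n >= 2")
  structure(list(label = as.character(label), mean = mean, sd = sd,
                 n = as.integer(n)), class = "group_summary")
}

#' Shapiro-Wilk normality gate
#'
#' Runs a Shapiro-Wilk test per group; the gate passes when every group's
#' p-value exceeds `alpha`, licensing the parametric ANOVA path.
#'
#' @param samples Named list of numeric vectors, each of length `>= 3`.
#' @param alpha Gate level.
#' @return A list: `p_values` (named), `pass`.
#' @export
shapiro_wilk_gate <- function(samples, alpha = 0.05) {
  if (!is.list(samples) || length(samples) < 1L) {
    stop("samples must be a non-empty list of numeric vectors")
  }
  p <- vapply(samples, function(x) {
    if (length(x) < 3L) stop("Shapiro-Wilk needs n >= 3 per group")
    if (stats::sd(x) == 0) stop("constant sample: Shapiro-Wilk undefined")
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  list(p_values = p, pass = all(p > alpha))
}

anova_build <- function(ssb, ssw, df1, df2, labels, means, ns) {
  msb <- ssb / df1
  msw <- ssw / df2
  if (msw <= 0) stop("zero within-group variance: ANOVA is degenerate")
  f <- msb / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  eta2 <- if (ssb + ssw > 0) ssb / (ssb + ssw) else 0
  ci <- eta_squared_ci(f, df1, df2)
  # Bonferroni-adjusted pairwise t-tests with the pooled within-group
  # variance from the full ANOVA (Fisher-protected form)
  g <- length(labels)
  m <- g * (g - 1) / 2
  ph <- NULL
  if (g >= 2) {
    rows <- list()
    for (i in seq_len(g - 1)) for (j in (i + 1):g) {
      se <- sqrt(msw * (1 / ns[i] + 1 / ns[j]))
      t <- (means[i] - means[j]) / se
      praw <- 2 * stats::pt(abs(t), df2, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = labels[i], group2 = labels[j], t = t, p = praw,
        p_adj = min(1, m * praw), stringsAsFactors = FALSE)
    }
    ph <- do.call(rbind, rows)
  }
  structure(list(f = f, df_between = df1, df_within = df2, p = p,
                 eta_squared = eta2, eta_ci = ci, posthoc = ph,
                 ssb = ssb, ssw = ssw,
                 groups = data.frame(label = labels, mean = means, n = ns,
                                     stringsAsFactors = FALSE)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova> F(%d, %d) = %.3f, p = %.4f, eta^2 = %.3f [%.3f, %.3f]\n",
              x$df_between, x$df_within, x$f, x$p, x$eta_squared,
              x$eta_ci[1], x$eta_ci[2]))
  invisible(x)
}

#' One-way ANOVA with eta-squared and Bonferroni post hoc
#'
#' Classical fixed-effects between-subjects decomposition: `F = MSB / MSW`,
#' `eta^2 = SSB / SST` with a 95% noncentral-F confidence interval, and
#' all-pairs pooled-variance t-tests with Bonferroni adjustment
#' (`p_adj = min(1, m p)`, `m = g(g-1)/2`).
#'
#' @param groups Named list of numeric vectors (`g >= 2` groups, each
#'   `n >= 2`).
#' @return An `anova_result`: `f`, `df_between`, `df_within`, `p`,
#'   `eta_squared`, `eta_ci`, `posthoc` data.frame, `ssb`, `ssw`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs n >= 2")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  means <- vapply(groups, mean, numeric(1))
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  anova_build(ssb, ssw, length(groups) - 1L, sum(ns) - length(groups),
              labels, means, ns)
}

#' One-way ANOVA from published summary statistics
#'
#' Reconstructs the between-subjects decomposition from `(mean, sd, n)`
#' triplets: `SSB = sum n_i (mean_i - grand)^2`,
#' `SSW = sum (n_i - 1) sd_i^2`. When the inputs are rounded published
#' values (as in a results table), the reconstructed F inherits that
#' rounding error; eta-squared is much less sensitive.
#'
#' @param groups List of [group_summary] objects (`g >= 2`).
#' @return An `anova_result` (see [anova_oneway()]).
#' @export
anova_from_summary <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  ok <- vapply(groups, inherits, logical(1), "group_summary")
  if (!all(ok)) stop("groups must be group_summary objects")
  ns <- vapply(groups, `[[`, integer(1), "n")
  means <- vapply(groups, `[[`, numeric(1), "mean")
  sds <- vapply(groups, `[[`, numeric(1), "sd")
  labels <- vapply(groups, `[[`, character(1), "label")
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  anova_build(ssb, ssw, length(groups) - 1L, sum(ns) - length(groups),
              labels, means, ns)
}

#' Noncentral-F confidence interval for eta-squared
#'
#' Inverts the noncentral-F CDF at the observed `F` for the noncentrality
#' bounds at `(1 - level)/2` and `1 - (1 - level)/2`, then maps
#' `lambda -> eta^2 = lambda / (lambda + df1 + df2 + 1)`. The lower bound is
#' clipped at 0 (an F below its null median has no positive lower
#' noncentrality).
#'
#' @param f Observed F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param level Confidence level.
#' @return `c(lo, hi)` on the eta-squared scale.
#' @export
eta_squared_ci <- function(f, df1, df2, level = 0.95) {
  if (df1 < 1 || df2 < 1) stop("invalid degrees of freedom")
  if (!is.finite(f) || f < 0) stop("f must be finite and >= 0")
  alpha <- (1 - level) / 2
  ncp_solve <- function(target_p) {
    # find lambda with pf(f, df1, df2, ncp = lambda) == target_p
    if (stats::pf(f, df1, df2, ncp = 0) <= target_p) return(0)
    hi <- 1
    while (stats::pf(f, df1, df2, ncp = hi) > target_p && hi < 1e7) hi <- hi * 2
    stats::uniroot(function(l) stats::pf(f, df1, df2, ncp = l) - target_p,
                   c(0, hi), tol = 1e-10)$root
  }
  lam_lo <- ncp_solve(1 - alpha)
  lam_hi <- ncp_solve(alpha)
  lam_to_eta <- function(l) l / (l + df1 + df2 + 1)
  c(lam_to_eta(lam_lo), lam_to_eta(lam_hi))
}

#' Exact two-sample t-test power (noncentral t)
#'
#' @param n Per-group sample size.
#' @param d Standardised effect size (Cohen's d, `> 0`).
#' @param alpha Type-I level.
#' @param tails `"two"` or `"one"`.
#' @return Power in `(0, 1)`.
#' @export
power_two_sample_t <- function(n, d, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (tails == "two") {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Sample size for a two-sample t-test (exact noncentral-t)
#'
#' Smallest per-group `n >= 2` whose exact noncentral-t power
#' (`df = 2n - 2`, noncentrality `d sqrt(n/2)`) reaches the requested
#' power, found by monotone upward search.
#'
#' @param effect_size_d Cohen's d (`> 0`).
#' @param alpha Type-I level.
#' @param power Target power.
#' @param tails `"two"` or `"one"`.
#' @return A list: `n_per_group`, `n_total`, `achieved_power`.
#' @export
sample_size_two_sample_t <- function(effect_size_d, alpha = 0.05,
                                     power = 0.80,
                                     tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (effect_size_d <= 0) stop("effect_size_d must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  n <- 2L
  repeat {
    pw <- power_two_sample_t(n, effect_size_d, alpha, tails)
    if (pw >= power) break
    n <- n + 1L
  }
  list(n_per_group = n, n_total = 2L * n, achieved_power = pw)
}
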