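# Method-comparison statistics: paired t, Fisher-z correlation intervals,
# the 10 % consistency grouping, 2x2 chi-square, rank-sum subgroup tests and
# observer-agreement ICC.

#' Paired t-test of two measurement series
#'
#' Classical paired t on `d = x - y`: `t = mean(d) / (sd(d) / sqrt(n))`,
#' two-sided p and a 95 % confidence interval from the t distribution with
#' `n - 1` degrees of freedom.  A zero-variance difference series is handled
#' as a degenerate limit (p = 1 when the mean difference is 0, p = 0
#' otherwise) and flagged.
#'
#' @param x,y Paired readings of equal length (n >= 2).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `"paired_comparison"`: `n`, `mean_diff`,
#'   `ci` (length 2), `t`, `p`, `degenerate`.
#' @export
paired_ttest <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) {
    mrlap_error("`x` and `y` must be paired (equal length)", "mrlap_domain_error")
  }
  n <- length(x)
  if (n < 2) mrlap_error("need at least 2 pairs", "mrlap_domain_error")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  if (degenerate) {
    tt <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    ci <- c(m, m)
  } else {
    ht <- stats::t.test(x, y, paired = TRUE, conf.level = conf)
    tt <- unname(ht$statistic)
    p <- ht$p.value
    ci <- as.numeric(ht$conf.int)
  }
  structure(list(n = n, mean_diff = m, ci = ci, t = tt, p = p,
                 degenerate = degenerate),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired t-test (n = %d): mean difference %.3f, 95%% CI (%.3f, %.3f), t = %.3f, P = %.3g%s\n",
              x$n, x$mean_diff, x$ci[1], x$ci[2], x$t, x$p,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pearson r with a confidence interval from the Fisher z transform
#' (`atanh(r) ± z * 1/sqrt(n - 3)`) and a two-sided p value from the t
#' transform of r.
#'
#' @param x,y Paired readings, n >= 4, neither constant.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `"correlation_result"`: `r`, `ci`, `p`, `n`.
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) {
    mrlap_error("`x` and `y` must be paired (equal length)", "mrlap_domain_error")
  }
  n <- length(x)
  if (n < 4) mrlap_error("need at least 4 pairs", "mrlap_domain_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    mrlap_error("correlation undefined for constant input", "mrlap_undefined_correlation")
  }
  r <- stats::cor(x, y)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (abs(r) < 1) {
    zr <- atanh(r)
    ci <- tanh(c(zr - z / sqrt(n - 3), zr + z / sqrt(n - 3)))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    ci <- c(r, r)
    p <- 0
  }
  structure(list(r = r, ci = ci, p = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (%.3f, %.3f), P = %.3g, n = %d\n",
              x$r, x$ci[1], x$ci[2], x$p, x$n))
  invisible(x)
}

#' Consistency grouping of two LAP series
#'
#' A subject is "consistent" when the sphygmomanometer estimate lies within
#' 10 % of the catheter reading: `|lap_bp - lap_c| / lap_c < 0.10` (strict;
#' catheter value as denominator).  Optionally cross-tabulates the labels
#' against a stratum variable (e.g. disease group) into a 2x2 table.
#'
#' @param lap_bp,lap_c Paired readings; `lap_c` must be positive.
#' @param stratum Optional factor-like stratum per subject (2 levels for the
#'   table).
#' @param rel_tol Consistency threshold (default 0.10).
#' @return A list: `consistent` (logical per subject), `rate`, and, when a
#'   stratum is supplied, `table` (stratum x consistency counts).
#' @export
consistency_grouping <- function(lap_bp, lap_c, stratum = NULL, rel_tol = 0.10) {
  if (length(lap_bp) != length(lap_c)) {
    mrlap_error("readings must be paired", "mrlap_domain_error")
  }
  if (any(lap_c <= 0)) {
    mrlap_error("catheter readings must be > 0 (denominator of the rule)",
                "mrlap_domain_error")
  }
  consistent <- abs(lap_bp - lap_c) / lap_c < rel_tol
  out <- list(consistent = consistent, rate = mean(consistent))
  if (!is.null(stratum)) {
    out$table <- table(stratum = stratum,
                       consistency = factor(ifelse(consistent, "consistent", "inconsistent"),
                                            levels = c("consistent", "inconsistent")))
  }
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param tab 2x2 matrix/table of non-negative counts.
#' @param correct Apply the Yates continuity correction (default `TRUE`,
#'   standard at small expected counts).
#' @return List with `statistic`, `p`, `df`, `expected`, `correct`.
#' @export
chi_square_2x2 <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0)) {
    mrlap_error("`tab` must be a 2x2 table of non-negative counts", "mrlap_domain_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    mrlap_error("degenerate table: a zero marginal leaves the test undefined",
                "mrlap_degenerate_table")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       expected = ht$expected, correct = correct)
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison of two groups
#'
#' Rank-sum U with the tie-corrected normal approximation for the p value —
#' the default two-group test for the cohort's median (IQR) rows.
#'
#' @param a,b Readings of the two groups (non-empty).
#' @return List with `U` (number of (a, b) pairs with a > b, ties counted
#'   half), `p`, and the group sizes.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    mrlap_error("both groups must be non-empty", "mrlap_domain_error")
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  list(U = unname(ht$statistic), p = ht$p.value, n1 = length(a), n2 = length(b))
}

#' Intraclass correlation for absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC (the
#' conventional form for inter-observer agreement), computed from the
#' standard mean-squares decomposition of the subject x rater grid:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings Numeric matrix, rows = subjects (n >= 5), columns = raters
#'   (k >= 2); no missing entries.
#' @return List with `icc`, `ms` (mean squares), `n`, `k`.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) {
    mrlap_error("ratings grid must be complete (no missing entries)",
                "mrlap_missing_data")
  }
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k < 2 || n < 5) {
    mrlap_error("need >= 2 raters and >= 5 subjects", "mrlap_domain_error")
  }
  gm <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, ms = c(MSR = msr, MSC = msc, MSE = mse), n = n, k = k)
}
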