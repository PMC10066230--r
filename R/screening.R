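#' Classify a p-value into the study's significance bands
#'
#' `p < 0.05` is significant; `0.05 <= p < 0.20` is a trend (a tendency worth
#' reporting at field-experiment sample sizes); anything else is none. The
#' trend band is right-open: `p = 0.20` is none.
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector: `"significant"`, `"trend"` or `"none"`.
#' @export
classify_significance <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  ifelse(p < 0.05, "significant", ifelse(p < 0.20, "trend", "none"))
}

#' Two-group comparison with normality-driven test selection
#'
#' The univariate cascade applied to every feature: Shapiro-Wilk on each
#' group (gate at p < 0.05); if both groups pass, a two-sided F test on the
#' variances selects the pooled-variance t test (F-test p >= 0.05) or the
#' Welch t test; if either group fails normality, the two-sided Wilcoxon
#' rank-sum test for independent samples is used (a paired signed-rank
#' variant is available via `paired = TRUE`). The resulting p-value is
#' banded by [classify_significance()].
#'
#' Degenerate inputs: when every value in both groups is identical the
#' comparison carries no information; the result has `p_value = 1`, the
#' cascade's parametric branch recorded, and `degenerate = TRUE`. A constant
#' group (Shapiro-Wilk undefined) is otherwise treated as failing normality,
#' so two constant-but-different groups take the rank-test branch.
#'
#' @param x control-group values (>= 3 finite values).
#' @param y treated-group values (>= 3 finite values).
#' @param feature optional feature name carried into the result.
#' @param paired use the paired signed-rank / paired-t cascade variant.
#' @return object of class `group_comparison`: list with `feature`,
#'   `test_used` (`"t_equal_var"`, `"t_welch"`, `"wilcoxon_rank"`),
#'   `statistic`, `p_value`, `shapiro_p` (length 2), `f_test_p` (NA on the
#'   nonparametric branch), `significance_class`, `direction`
#'   (sign of treated mean - control mean), `degenerate`.
#' @export
compare_groups <- function(x, y, feature = NA_character_, paired = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs at least 3 finite values")
  if (paired && length(x) != length(y)) stop("paired groups must have equal length")
  degenerate <- stats::var(c(x, y)) == 0
  shp <- function(v) {
    if (stats::var(v) == 0) return(NA_real_)   # constant: normality undefined
    stats::shapiro.test(v)$p.value
  }
  shapiro_p <- c(control = shp(x), treated = shp(y))
  # constant group => non-Gaussian branch, unless both constant (degenerate)
  nonnormal <- if (degenerate) FALSE else
    any(shapiro_p < 0.05, na.rm = TRUE) || anyNA(shapiro_p)
  f_test_p <- NA_real_
  if (degenerate) {
    test_used <- "t_equal_var"; stat <- 0; p <- 1; f_test_p <- NA_real_
  } else if (nonnormal) {
    test_used <- "wilcoxon_rank"
    wt <- suppressWarnings(stats::wilcox.test(y, x, paired = paired,
                                              exact = NULL, correct = TRUE))
    stat <- unname(wt$statistic); p <- wt$p.value
  } else {
    f_test_p <- stats::var.test(x, y)$p.value
    equal <- f_test_p >= 0.05
    test_used <- if (equal) "t_equal_var" else "t_welch"
    tt <- if (paired) stats::t.test(y, x, paired = TRUE) else
      stats::t.test(y, x, var.equal = equal)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(feature = feature, test_used = test_used, statistic = stat,
                 p_value = p, shapiro_p = shapiro_p, f_test_p = f_test_p,
                 significance_class = classify_significance(p),
                 direction = sign(mean(y) - mean(x)), degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4g, p = %.4g (%s), direction %+d%s\n",
              if (is.na(x$feature)) "comparison" else x$feature, x$test_used,
              x$statistic, x$p_value, x$significance_class, x$direction,
              if (x$degenerate) " [degenerate: both groups constant]" else ""))
  invisible(x)
}

#' Screen every feature of a dataset for a treatment effect
#'
#' Applies [compare_groups()] per feature and returns a tidy table. A
#' Benjamini-Hochberg adjusted column is appended as supplementary output;
#' the significance class follows the unadjusted per-feature p, mirroring
#' per-feature reporting at field scale.
#'
#' @param dataset an [omics_dataset()].
#' @param paired passed to [compare_groups()].
#' @return data.frame with one row per feature: feature, compartment,
#'   category, test_used, statistic, p_value, p_bh, significance_class,
#'   direction, degenerate.
#' @export
screen_dataset <- function(dataset, paired = FALSE) {
  stopifnot(inherits(dataset, "omics_dataset"))
  x <- dataset$values[dataset$group == 0, , drop = FALSE]
  y <- dataset$values[dataset$group == 1, , drop = FALSE]
  rows <- lapply(colnames(dataset$values), function(f)
    compare_groups(x[, f], y[, f], feature = f, paired = paired))
  out <- data.frame(
    feature = vapply(rows, `[[`, "", "feature"),
    compartment = unname(dataset$compartment[colnames(dataset$values)]),
    category = unname(dataset$category[colnames(dataset$values)]),
    test_used = vapply(rows, `[[`, "", "test_used"),
    statistic = vapply(rows, `[[`, 0, "statistic"),
    p_value = vapply(rows, `[[`, 0, "p_value"),
    significance_class = vapply(rows, `[[`, "", "significance_class"),
    direction = vapply(rows, `[[`, 0, "direction"),
    degenerate = vapply(rows, `[[`, TRUE, "degenerate"),
    stringsAsFactors = FALSE)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Without continuity correction; `df = (r-1)(c-1)` from the declared table
#' dimensions. Cells in zero-marginal rows or columns have expected count 0
#' and contribute nothing to the statistic (a warning flags them — the
#' category is retained as declared, matching a survey design with scored
#' but unused categories). The p-value is the upper tail of the chi-square
#' distribution at the statistic, via [chisq_tail()].
#'
#' @param table r x c matrix of nonnegative integer counts.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be nonnegative")
  active_r <- rowSums(tab) > 0; active_c <- colSums(tab) > 0
  if (sum(active_r) < 2 || sum(active_c) < 2)
    stop("need at least 2 rows and 2 columns with positive marginals")
  if (!all(active_r) || !all(active_c))
    warning("zero-marginal rows/columns contribute nothing to the statistic")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  contrib <- (tab - expected)^2 / expected
  stat <- sum(contrib[expected > 0])
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p_value = chisq_tail(stat, df),
       expected = expected)
}
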