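#' Upper-tail probability of the chi-square distribution
#'
#' Survival function used for all model chi-square p-values in the package.
#' @param statistic nonnegative chi-square statistic.
#' @param df positive degrees of freedom.
#' @return upper-tail probability.
#' @export
chisq_tail <- function(statistic, df) {
  if (any(statistic < 0)) stop("negative chi-square statistic")
  if (any(df <= 0)) stop("df must be positive")
  stats::pchisq(statistic, df, lower.tail = FALSE)
}

#' The seven-index fit battery for a SEM fit
#'
#' Computes the chi-square test and the comparative/absolute fit indices
#' conventionally reported with path models:
#' \itemize{
#'   \item `chisq` = (n-1) F_ML, `p_value` = upper chi-square tail at `df`;
#'   \item `cfi` = 1 - max(T-df, 0) / max(T_b-df_b, T-df, 0);
#'   \item `tli` = (T_b/df_b - T/df) / (T_b/df_b - 1);
#'   \item `rmsea` = sqrt(max(T-df, 0) / (df (n-1)));
#'   \item `srmr` = sqrt of the mean squared standardized covariance residual
#'         over the p(p+1)/2 unique entries (sample-sd standardization);
#'   \item `gfi` = 1 - tr((Sigma^-1 S - I)^2) / tr((Sigma^-1 S)^2);
#'   \item `agfi` = 1 - (p(p+1) / (2 df)) (1 - gfi).
#' }
#' The baseline for CFI/TLI is the independence model (free variances, zero
#' covariances), whose ML discrepancy has the closed form
#' `sum(log diag S) - log|S|`. At `df = 0` (saturation) TLI, RMSEA and AGFI
#' are undefined and reported as `NA`.
#'
#' @param fit a `sem_fit`.
#' @return object of class `fit_indices` (a named list, also containing
#'   `df`, `baseline_chisq`, `baseline_df`, `saturated`).
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) warning("fit did not converge; indices may be meaningless")
  S <- fit$S; n <- fit$n; p <- nrow(S); df <- fit$df
  T_stat <- (n - 1) * fit$fml
  Fb <- sum(log(diag(S))) - 2 * sum(log(diag(chol(S))))
  Tb <- (n - 1) * max(Fb, 0)
  dfb <- p * (p - 1) / 2
  saturated <- df == 0

  p_value <- if (saturated) NA_real_ else chisq_tail(T_stat, df)
  denom <- max(Tb - dfb, T_stat - df, 0)
  cfi <- if (denom <= 0) 1 else 1 - max(T_stat - df, 0) / denom
  cfi <- min(max(cfi, 0), 1)
  tli <- if (saturated || dfb == 0) NA_real_ else {
    rb <- Tb / dfb
    if (abs(rb - 1) < .Machine$double.eps) NA_real_ else (rb - T_stat / df) / (rb - 1)
  }
  rmsea <- if (saturated) NA_real_ else sqrt(max(T_stat - df, 0) / (df * (n - 1)))

  sd <- sqrt(diag(S))
  Rstd <- (S - fit$implied_sigma) / tcrossprod(sd)
  srmr <- sqrt(mean(Rstd[upper.tri(Rstd, diag = TRUE)]^2))

  W <- solve(fit$implied_sigma, S)
  gfi <- 1 - sum(diag((W - diag(p)) %*% (W - diag(p)))) / sum(diag(W %*% W))
  agfi <- if (saturated) NA_real_ else 1 - (p * (p + 1) / (2 * df)) * (1 - gfi)

  structure(list(chisq = T_stat, df = df, p_value = p_value, cfi = cfi,
                 tli = tli, rmsea = rmsea, srmr = srmr, gfi = gfi,
                 agfi = agfi, baseline_chisq = Tb, baseline_df = dfb,
                 saturated = saturated),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "- (saturated)" else formatC(v, digits = digits, format = "f")
  cat(sprintf("chi^2 = %.3f (df = %d), p = %s\n", x$chisq, x$df,
              if (is.na(x$p_value)) "- (saturated)" else format.pval(x$p_value, digits = 4)))
  cat("CFI =", fmt(x$cfi), " TLI =", fmt(x$tli), " RMSEA =", fmt(x$rmsea), "\n")
  cat("SRMR =", fmt(x$srmr), " GFI =", fmt(x$gfi), " AGFI =", fmt(x$agfi), "\n")
  invisible(x)
}

# flat numeric row used by ranking tables
indices_row <- function(ix) {
  c(chisq = ix$chisq, df = ix$df, p_value = ix$p_value, cfi = ix$cfi,
    tli = ix$tli, rmsea = ix$rmsea, srmr = ix$srmr, gfi = ix$gfi, agfi = ix$agfi)
}
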