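#' Quasi-Bayesian causal mediation analysis for a treatment-mediator-outcome
#' triplet
#'
#' Fits the two linear models
#' \deqn{m = \alpha_0 + a t + \varepsilon_m, \qquad
#'       y = \beta_0 + c' t + b m + \varepsilon_y}
#' by least squares and propagates estimation uncertainty by drawing
#' `n_sims` coefficient vectors from the normal approximation of their
#' sampling distribution (mean = estimates, covariance = the OLS
#' variance-covariance matrices, the two models independent). Per draw the
#' average causal mediation effect is ACME = a b, the average direct effect
#' ADE = c', and total = ACME + ADE exactly (linear models without
#' treatment-mediator interaction). Points are the medians of the draws; CIs
#' the 2.5/97.5 percentiles. Degenerate regressions (constant treatment,
#' collinear design, or exactly zero residual variance) yield
#' `calculable = FALSE` with a reason rather than an error, mirroring the
#' study's "ACME not calculable" reporting.
#'
#' @param data an [omics_dataset()], data.frame or matrix containing the
#'   three columns (for an `omics_dataset`, the treatment column is the 0/1
#'   group label exposed as `"Cmp"`).
#' @param treatment,mediator,outcome column names of the triplet.
#' @param n_sims number of quasi-Bayesian draws (default 1000).
#' @param seed integer seed; fixed seed gives bit-identical draws.
#' @return object of class `mediation_result`: `acme`, `ade`, `total` (each
#'   a list with `point`, `ci`), `prop_mediated`, `n_sims`, `calculable`,
#'   `reason`, `significant` (ACME CI excludes 0), `triplet`.
#' @export
mediate <- function(data, treatment, mediator, outcome, n_sims = 1000,
                    seed = 1) {
  cols <- c(treatment, mediator, outcome)
  m <- as_variable_matrix(data, cols)
  if (nrow(m) < 6) stop("need at least 6 samples")
  triplet <- c(treatment = treatment, mediator = mediator, outcome = outcome)
  bail <- function(reason) structure(
    list(triplet = triplet, acme = NULL, ade = NULL, total = NULL,
         prop_mediated = NA_real_, n_sims = n_sims, calculable = FALSE,
         reason = reason, significant = NA),
    class = "mediation_result")
  t_ <- m[, treatment]; md <- m[, mediator]; y <- m[, outcome]
  if (stats::var(t_) == 0) return(bail("constant treatment column"))
  fm <- stats::lm(md ~ t_)
  fy <- stats::lm(y ~ t_ + md)
  if (any(is.na(stats::coef(fm))) || any(is.na(stats::coef(fy))))
    return(bail("collinear design"))
  # zero residual variance "to machine precision": an exact linear relation
  # leaves only float noise (residual sd ~ 1e-16 x data sd), while a genuine
  # noise->0 fixture keeps residuals far above this floor
  zero_resid <- function(fit, v) {
    s2 <- sum(stats::resid(fit)^2)
    s2 <= length(v) * stats::var(v) * 1e-20
  }
  if (zero_resid(fm, md) || zero_resid(fy, y))
    return(bail("zero residual variance"))

  set.seed(as.integer(seed))
  draw <- function(fit, k) {
    V <- stats::vcov(fit)
    ch <- chol((V + t(V)) / 2)
    matrix(stats::rnorm(k * ncol(V)), k) %*% ch +
      matrix(stats::coef(fit), k, ncol(V), byrow = TRUE)
  }
  dm <- draw(fm, n_sims)                  # columns: intercept, a
  dy <- draw(fy, n_sims)                  # columns: intercept, c', b
  acme_d <- dm[, 2] * dy[, 3]
  ade_d <- dy[, 2]
  total_d <- acme_d + ade_d
  pc <- function(v) list(point = stats::median(v),
                         ci = unname(stats::quantile(v, c(0.025, 0.975))))
  acme <- pc(acme_d); ade <- pc(ade_d); total <- pc(total_d)
  structure(list(triplet = triplet, acme = acme, ade = ade, total = total,
                 prop_mediated = stats::median(
                   ifelse(total_d == 0, NA_real_, acme_d / total_d)),
                 n_sims = n_sims, calculable = TRUE, reason = NA_character_,
                 significant = acme$ci[1] > 0 || acme$ci[2] < 0),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation %s -> %s -> %s\n", x$triplet["treatment"],
              x$triplet["mediator"], x$triplet["outcome"]))
  if (!x$calculable) {
    cat("ACME not calculable:", x$reason, "\n")
    return(invisible(x))
  }
  row <- function(lbl, e) cat(sprintf("%-6s %8.4f  [%8.4f, %8.4f]\n",
                                      lbl, e$point, e$ci[1], e$ci[2]))
  row("ACME", x$acme); row("ADE", x$ade); row("Total", x$total)
  cat(sprintf("prop. mediated %.3f; ACME %ssignificant (%d sims)\n",
              x$prop_mediated, if (isTRUE(x$significant)) "" else "not ",
              x$n_sims))
  invisible(x)
}

#' Mediation analysis for every directed 2-path of a path model
#'
#' Derives each triplet treatment -> mediator -> outcome from the directed
#' 2-paths of `model` that start at the treatment node and runs [mediate()]
#' on each, mirroring a per-table mediation battery over the winning model.
#'
#' @param model a `path_model` (e.g. the selection winner).
#' @param data data containing the model variables.
#' @param treatment treatment variable name.
#' @param n_sims,seed passed to [mediate()] (seed advanced per triplet for
#'   independent draws, deterministically).
#' @return data.frame, one row per triplet: mediator, outcome, acme, acme
#'   CI, ade, ade CI, total, total CI, prop_mediated, calculable,
#'   significant.
#' @export
mediate_model_paths <- function(model, data, treatment = "Cmp",
                                n_sims = 1000, seed = 1) {
  r <- model$regressions
  first <- r[r$predictor == treatment, "outcome"]
  rows <- list()
  k <- 0L
  for (med in first) for (out in r[r$predictor == med, "outcome"]) {
    k <- k + 1L
    res <- mediate(data, treatment, med, out, n_sims = n_sims,
                   seed = seed + k - 1L)
    rows[[k]] <- data.frame(
      treatment = treatment, mediator = med, outcome = out,
      acme = if (res$calculable) res$acme$point else NA_real_,
      acme_lo = if (res$calculable) res$acme$ci[1] else NA_real_,
      acme_hi = if (res$calculable) res$acme$ci[2] else NA_real_,
      ade = if (res$calculable) res$ade$point else NA_real_,
      ade_lo = if (res$calculable) res$ade$ci[1] else NA_real_,
      ade_hi = if (res$calculable) res$ade$ci[2] else NA_real_,
      total = if (res$calculable) res$total$point else NA_real_,
      prop_mediated = res$prop_mediated,
      calculable = res$calculable,
      significant = res$significant,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(treatment = character(), mediator = character(),
                      outcome = character(), acme = numeric(),
                      acme_lo = numeric(), acme_hi = numeric(),
                      ade = numeric(), ade_lo = numeric(), ade_hi = numeric(),
                      total = numeric(), prop_mediated = numeric(),
                      calculable = logical(), significant = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
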