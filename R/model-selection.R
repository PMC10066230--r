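#' Enumerate candidate path models over a variable pool
#'
#' Generates every acyclic path model over the pool in which the treatment
#' variable is exogenous (no incoming edges) and only variables declared
#' endogenous may receive edges. Intended for the handful-of-variables pools
#' the per-compartment analyses use; refuses pools above 6 variables unless
#' an explicit `max_edges` cap is given (combinatorial guard).
#'
#' @param pool character vector of variable names (must include `treatment`).
#' @param treatment treatment variable name (always exogenous).
#' @param endogenous variables allowed to be outcomes (default: all but the
#'   treatment).
#' @param order optional topological order: when given, only edges running
#'   forward along it are considered (the candidate set of a layered design).
#' @param forbidden optional data.frame (`source`, `target`) of banned edges.
#' @param max_edges cap on edge count per candidate.
#' @return list of `path_model` objects in a deterministic order (by edge
#'   count, then lexicographic edge sets).
#' @export
enumerate_candidates <- function(pool, treatment = "Cmp",
                                 endogenous = setdiff(pool, treatment),
                                 order = NULL, forbidden = NULL,
                                 max_edges = Inf) {
  if (!treatment %in% pool) stop("pool must include the treatment variable")
  if (length(pool) > 6 && is.infinite(max_edges))
    stop("pool has more than 6 variables; pass an explicit max_edges cap")
  src <- pool
  edges <- expand.grid(source = src, target = intersect(endogenous, pool),
                       stringsAsFactors = FALSE)
  edges <- edges[edges$source != edges$target & edges$target != treatment, ]
  if (!is.null(order)) {
    rk <- match(edges$source, order) < match(edges$target, order)
    edges <- edges[!is.na(rk) & rk, ]
  }
  if (!is.null(forbidden) && nrow(forbidden))
    edges <- edges[!paste(edges$source, edges$target) %in%
                     paste(forbidden[[1]], forbidden[[2]]), ]
  edges <- edges[order(edges$source, edges$target), ]
  k <- nrow(edges)
  if (k > 20) stop("candidate edge universe too large (", k, " edges)")
  out <- list()
  for (mask in 0:(2^k - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    if (length(sel) > max_edges) next
    reg <- edges[sel, , drop = FALSE]
    pm <- tryCatch(
      path_model(pool, regressions = if (nrow(reg))
        data.frame(outcome = reg$target, predictor = reg$source,
                   stringsAsFactors = FALSE)),
      error = function(e) NULL)     # cyclic subsets dropped
    if (!is.null(pm)) out[[length(out) + 1L]] <- pm
  }
  nedge <- vapply(out, function(m) nrow(m$regressions), 0L)
  txt <- vapply(out, serialize_model, "")
  out[order(nedge, txt)]
}

#' Fit every candidate and compute its fit battery
#' @param candidates list of `path_model`s (see [enumerate_candidates()]).
#' @param data,S,n data passed to [sem_fit()].
#' @param ... further arguments to [sem_fit()].
#' @return list of lists with elements `model`, `fit`, `indices` (indices
#'   NULL when the fit failed to converge).
#' @export
fit_candidates <- function(candidates, data = NULL, S = NULL, n = NULL, ...) {
  if (!is.null(data) && is.null(S)) {
    m <- as_variable_matrix(data, candidates[[1]]$variables)
    S <- stats::cov(m); n <- nrow(m); data <- NULL
  }
  lapply(candidates, function(cand) {
    fit <- tryCatch(sem_fit(cand, S = S, n = n, se = FALSE, ...),
                    error = function(e) NULL)
    ix <- if (!is.null(fit) && fit$converged)
      tryCatch(fit_indices(fit), error = function(e) NULL) else NULL
    list(model = cand, fit = fit, indices = ix)
  })
}

#' Rank fitted candidates by the seven-index battery
#'
#' Per-index ranks (higher better for chi-square p, CFI, TLI, GFI, AGFI;
#' lower better for RMSEA, SRMR; ties share average ranks) are computed over
#' the converged testable (df > 0) candidates on index values rounded to
#' `digits` decimals, and their mean is the reported composite.
#'
#' The default selection rule, `"parsimonious_fit"`, first screens candidates
#' against the conventional adequacy cutoffs (CFI >= 0.95, RMSEA <= 0.08,
#' SRMR <= 0.08) and orders adequate candidates by parsimony (fewer free
#' parameters), breaking ties by composite mean rank and then lexicographic
#' model text; non-adequate testable candidates follow by composite. The
#' reason parsimony leads within the adequate set: every over-parameterised
#' superset of a well-fitting model also fits "adequately", and raw
#' index-value comparison systematically prefers the superset (its SRMR/GFI
#' are closer to perfection by construction), so a pure index vote is not
#' selection-consistent. `"mean_rank"` (pure composite vote), `"rmsea"` and
#' `"cfi"` (single-index primary) are available as alternatives. Saturated
#' candidates (df = 0), whose comparative indices are undefined, are placed
#' after all testable candidates (ordered by parsimony); non-converged
#' candidates come last.
#'
#' @param fits output of [fit_candidates()].
#' @param method `"parsimonious_fit"` (default), `"mean_rank"`, `"rmsea"` or
#'   `"cfi"`.
#' @param digits index rounding used for ranking (default 3).
#' @param cutoffs named list of adequacy cutoffs for `"parsimonious_fit"`:
#'   `cfi` (minimum), `rmsea`, `srmr` (maxima).
#' @return object of class `candidate_ranking`: list with `table` (one row
#'   per candidate: indices, adequacy, composite, rank) and `winner` (index
#'   into `fits`).
#' @export
rank_models <- function(fits, method = c("parsimonious_fit", "mean_rank",
                                         "rmsea", "cfi"),
                        digits = 3,
                        cutoffs = list(cfi = 0.95, rmsea = 0.08, srmr = 0.08)) {
  method <- match.arg(method)
  ok <- vapply(fits, function(f) !is.null(f$fit) && f$fit$converged, TRUE)
  if (!any(ok)) stop("no candidate converged")
  dfs <- vapply(fits, function(f)
    if (is.null(f$fit)) NA_real_ else as.numeric(f$fit$df), 0)
  npar <- vapply(fits, function(f) n_free_parameters(f$model), 0L)
  txt <- vapply(fits, function(f) serialize_model(f$model), "")
  testable <- ok & dfs > 0 & !vapply(fits, function(f) is.null(f$indices), TRUE)

  ix <- t(vapply(fits, function(f)
    if (is.null(f$indices)) rep(NA_real_, 9) else indices_row(f$indices),
    numeric(9)))
  colnames(ix) <- c("chisq", "df", "p_value", "cfi", "tli", "rmsea", "srmr",
                    "gfi", "agfi")
  composite <- rep(NA_real_, length(fits))
  if (any(testable)) {
    sub <- round(ix[testable, , drop = FALSE], digits)
    rk_hi <- function(v) rank(-v, ties.method = "average", na.last = "keep")
    rk_lo <- function(v) rank(v, ties.method = "average", na.last = "keep")
    rmat <- switch(method,
      rmsea = cbind(rk_lo(sub[, "rmsea"])),
      cfi = cbind(rk_hi(sub[, "cfi"])),
      cbind(rk_hi(sub[, "p_value"]), rk_hi(sub[, "cfi"]),
            rk_hi(sub[, "tli"]), rk_hi(sub[, "gfi"]),
            rk_hi(sub[, "agfi"]), rk_lo(sub[, "rmsea"]),
            rk_lo(sub[, "srmr"])))
    composite[testable] <- rowMeans(rmat, na.rm = TRUE)
  }
  adequate <- testable &
    !is.na(ix[, "cfi"]) & ix[, "cfi"] >= cutoffs$cfi &
    !is.na(ix[, "rmsea"]) & ix[, "rmsea"] <= cutoffs$rmsea &
    !is.na(ix[, "srmr"]) & ix[, "srmr"] <= cutoffs$srmr
  # total order by method; saturated/df0 candidates by parsimony after all
  # testable ones; non-converged last
  grp <- ifelse(testable, 0L, ifelse(ok, 1L, 2L))
  o <- if (method == "parsimonious_fit")
    order(grp, !adequate, ifelse(adequate, npar, 0L), composite, npar, txt,
          na.last = TRUE)
  else
    order(grp, composite, npar, txt, na.last = TRUE)
  final_rank <- integer(length(fits))
  final_rank[o] <- seq_along(fits)
  tab <- data.frame(model = txt, n_parameters = npar, converged = ok,
                    ix, adequate = adequate, composite = composite,
                    rank = final_rank, stringsAsFactors = FALSE)
  structure(list(table = tab[order(tab$rank), ], winner = o[1],
                 fits = fits, method = method),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, n = 10, ...) {
  cat("Candidate ranking (", x$method, "), ", nrow(x$table), " candidates\n",
      sep = "")
  top <- utils::head(x$table, n)
  top$model <- gsub("\n", "; ", sub("^variables:[^\n]*\n?", "", top$model))
  print(top, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Winning model of a ranking
#' @param ranking a `candidate_ranking`.
#' @return list with `model` (the `path_model`), `fit`, `indices`.
#' @export
ranking_winner <- function(ranking) ranking$fits[[ranking$winner]]

#' Write a ranking table as TSV
#' @param ranking a `candidate_ranking`.
#' @param path output file.
#' @export
write_ranking_tsv <- function(ranking, path) {
  tab <- ranking$table
  tab$model <- gsub("\n", "; ", tab$model)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
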