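#' Discretize a dataset into per-sample transactions
#'
#' Turns each numeric feature into categorical items: under `median_split`,
#' a sample gets `"<feature>=high"` when its value exceeds the pooled median
#' and `"<feature>=low"` otherwise; `tertiles` uses low/mid/high thirds.
#' Treated samples additionally carry the item `"compost"`. Constant
#' features collapse to a single level (`"<feature>=low"`) with a warning.
#'
#' @param dataset an [omics_dataset()].
#' @param scheme `"median_split"` (default) or `"tertiles"`.
#' @return object of class `transactions`: list of character item sets, one
#'   per sample, with the sample ids as names.
#' @export
discretize <- function(dataset, scheme = c("median_split", "tertiles")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "omics_dataset"))
  v <- dataset$values
  items <- lapply(seq_len(nrow(v)), function(i) character(0))
  for (f in colnames(v)) {
    col <- v[, f]
    if (stats::var(col) == 0) {
      warning("constant feature '", f, "' emitted as a single level")
      lab <- rep("low", length(col))
    } else if (scheme == "median_split") {
      lab <- ifelse(col > stats::median(col), "high", "low")
    } else {
      q <- stats::quantile(col, c(1 / 3, 2 / 3), names = FALSE)
      lab <- ifelse(col <= q[1], "low", ifelse(col <= q[2], "mid", "high"))
    }
    for (i in seq_along(col))
      items[[i]] <- c(items[[i]], paste0(f, "=", lab[i]))
  }
  for (i in which(dataset$group == 1)) items[[i]] <- c("compost", items[[i]])
  names(items) <- dataset$sample_ids
  structure(items, class = "transactions")
}

#' Mine treatment-anchored association rules
#'
#' Enumerates rules `{compost} -> {item}` for every non-antecedent item with
#' exact support, confidence and lift computed from the transaction tallies:
#' support = P(antecedent and consequent), confidence = support /
#' P(antecedent), lift = confidence / P(consequent). With
#' `antecedent = NULL` all single-item antecedents are mined (full pairwise
#' mode). Output is deterministically ordered by lift (descending), then
#' consequent name.
#'
#' @param transactions a `transactions` object (or plain list of character
#'   vectors).
#' @param min_support minimum rule support in [0, 1].
#' @param min_confidence minimum confidence in [0, 1].
#' @param antecedent the anchoring item (default `"compost"`); NULL for all
#'   pairwise single-item rules.
#' @return data.frame with columns antecedent, consequent, support,
#'   confidence, lift.
#' @export
mine_rules <- function(transactions, min_support = 0.2, min_confidence = 0.5,
                       antecedent = "compost") {
  if (min_support < 0 || min_support > 1 || min_confidence < 0 || min_confidence > 1)
    stop("thresholds must lie in [0, 1]")
  tx <- unclass(transactions)
  if (!length(tx)) stop("need at least one transaction")
  n <- length(tx)
  items <- sort(unique(unlist(tx)))
  inc <- vapply(items, function(it) vapply(tx, function(t) it %in% t, TRUE),
                logical(n))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = n, dimnames = list(NULL, items))
  supp <- colMeans(inc)
  ants <- if (is.null(antecedent)) items else intersect(antecedent, items)
  out <- list()
  for (a in ants) {
    if (supp[a] == 0) next
    for (b in setdiff(items, a)) {
      s <- mean(inc[, a] & inc[, b])
      conf <- s / supp[a]
      if (s >= min_support && conf >= min_confidence)
        out[[length(out) + 1]] <- data.frame(
          antecedent = a, consequent = b, support = s, confidence = conf,
          lift = if (supp[b] > 0) conf / supp[b] else NA_real_,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(antecedent = character(), consequent = character(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric(), stringsAsFactors = FALSE))
  rules <- do.call(rbind, out)
  rules <- rules[order(-rules$lift, rules$consequent, rules$antecedent), ]
  rownames(rules) <- NULL
  rules
}

#' Select high-lift features from mined rules
#'
#' Takes the top-k rules by lift (or all rules with lift strictly above
#' `lift_threshold`, so that a threshold of 1 keeps only positively
#' associated consequents) and returns the de-duplicated base feature names
#' of their consequents (the part before `"=level"`).
#'
#' @param rules data.frame from [mine_rules()].
#' @param k number of top-lift rules to keep (ignored when `lift_threshold`
#'   given).
#' @param lift_threshold keep all rules with lift > this value.
#' @return character vector of feature names (possibly empty, with a warning
#'   when `rules` is empty).
#' @export
select_high_lift <- function(rules, k = NULL, lift_threshold = NULL) {
  if (!nrow(rules)) {
    warning("empty rule list; empty selection")
    return(character(0))
  }
  rules <- rules[order(-rules$lift, rules$consequent, rules$antecedent), ]
  keep <- if (!is.null(lift_threshold)) rules[rules$lift > lift_threshold, ]
  else utils::head(rules, if (is.null(k)) nrow(rules) else k)
  unique(sub("=.*$", "", keep$consequent))
}
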