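#' Directed path models over observed variables
#'
#' A `path_model` is a recursive (acyclic) system of linear regressions among
#' observed variables, plus an optional set of free covariances between
#' disturbances/exogenous variables. Every variable's (disturbance) variance
#' is always a free parameter. The free parameter vector is laid out as:
#' regression coefficients (in declaration order), then the p variances (in
#' variable order), then declared covariances (in declaration order).
#'
#' @param variables character vector of variable names (order fixes the
#'   variance block of the parameter vector).
#' @param regressions two-column data.frame (`outcome`, `predictor`), one row
#'   per directed edge predictor -> outcome.
#' @param covariances two-column data.frame (`a`, `b`) of unordered pairs
#'   allowed to covary; may be empty.
#' @return an object of class `path_model`.
#' @export
path_model <- function(variables, regressions = NULL, covariances = NULL) {
  variables <- as.character(variables)
  if (anyDuplicated(variables)) stop("duplicate variable names")
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (is.null(regressions)) regressions <- empty(outcome = character(), predictor = character())
  if (is.null(covariances)) covariances <- empty(a = character(), b = character())
  regressions <- empty(outcome = as.character(regressions[[1]]),
                       predictor = as.character(regressions[[2]]))
  covariances <- empty(a = as.character(covariances[[1]]),
                       b = as.character(covariances[[2]]))
  nm <- unique(c(regressions$outcome, regressions$predictor, covariances$a, covariances$b))
  unknown <- setdiff(nm, variables)
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  key <- paste(regressions$outcome, regressions$predictor)
  if (anyDuplicated(key)) stop("duplicate regression edge")
  ckey <- vapply(seq_len(nrow(covariances)), function(i)
    paste(sort(c(covariances$a[i], covariances$b[i])), collapse = "~~"), "")
  if (anyDuplicated(ckey)) stop("duplicate covariance pair")
  ord <- topological_order(variables, regressions)  # errors on cycles
  p <- length(variables)
  t_free <- nrow(regressions) + p + nrow(covariances)
  if (t_free > p * (p + 1) / 2)
    stop("model has ", t_free, " free parameters but only ", p * (p + 1) / 2,
         " observed moments (over-parameterised)")
  structure(list(variables = variables, regressions = regressions,
                 covariances = covariances, order = ord),
            class = "path_model")
}

# Kahn's algorithm; error names one cycle if present.
topological_order <- function(variables, regressions) {
  p <- length(variables)
  adj <- matrix(FALSE, p, p, dimnames = list(variables, variables))
  if (nrow(regressions)) adj[cbind(regressions$predictor, regressions$outcome)] <- TRUE
  indeg <- colSums(adj)
  ord <- character(0)
  avail <- variables[indeg == 0]
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    ord <- c(ord, v)
    ch <- variables[adj[v, ]]
    adj[v, ] <- FALSE
    indeg[ch] <- indeg[ch] - 1
    avail <- c(avail, ch[indeg[ch] == 0])
  }
  if (length(ord) < p) {
    cyc <- setdiff(variables, ord)
    stop("regression edges contain a cycle among: ", paste(cyc, collapse = ", "))
  }
  ord
}

#' Number of free parameters of a path model
#' @param model a `path_model`.
#' @return integer count (coefficients + variances + covariances).
#' @export
n_free_parameters <- function(model) {
  nrow(model$regressions) + length(model$variables) + nrow(model$covariances)
}

#' Model degrees of freedom
#' @param model a `path_model`.
#' @return `p(p+1)/2 - t`.
#' @export
model_df <- function(model) {
  p <- length(model$variables)
  as.integer(p * (p + 1) / 2 - n_free_parameters(model))
}

#' Parse path-model syntax
#'
#' One declaration per line: `outcome ~ predictor1 + predictor2` for
#' regressions, `a ~~ b` for a free covariance. An optional line
#' `variables: a b c` declares the variable set (and its order); otherwise
#' names are collected from the declarations in order of appearance.
#' Blank lines and `#` comments are ignored.
#'
#' @param text model syntax (single string with newlines, or character vector
#'   of lines).
#' @param variables optional explicit variable set; names used in `text` that
#'   are not in it are rejected.
#' @return a `path_model`.
#' @export
parse_model <- function(text, variables = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  reg <- list(); cv <- list(); seen <- character(0)
  note <- function(x) seen <<- unique(c(seen, x))
  for (ln in lines) {
    if (grepl("^variables\\s*:", ln)) {
      decl <- trimws(sub("^variables\\s*:", "", ln))
      declared <- strsplit(decl, "[,[:space:]]+")[[1]]
      declared <- declared[nzchar(declared)]
      if (is.null(variables)) variables <- declared else
        variables <- unique(c(variables, declared))
      note(declared)
      next
    }
    if (grepl("~~", ln, fixed = TRUE)) {
      pr <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      if (length(pr) != 2 || !all(nzchar(pr))) stop("malformed covariance line: ", ln)
      note(pr)
      cv[[length(cv) + 1]] <- pr
    } else if (grepl("~", ln, fixed = TRUE)) {
      pr <- trimws(strsplit(ln, "~", fixed = TRUE)[[1]])
      if (length(pr) != 2 || !all(nzchar(pr))) stop("malformed regression line: ", ln)
      preds <- trimws(strsplit(pr[2], "+", fixed = TRUE)[[1]])
      if (!all(nzchar(preds))) stop("malformed predictor list: ", ln)
      note(c(pr[1], preds))
      for (pd in preds) reg[[length(reg) + 1]] <- c(pr[1], pd)
    } else stop("unparseable line: ", ln)
  }
  if (is.null(variables)) variables <- seen
  unknown <- setdiff(seen, variables)
  if (length(unknown)) stop("undeclared variable(s): ", paste(unknown, collapse = ", "))
  regressions <- if (length(reg))
    data.frame(outcome = vapply(reg, `[`, "", 1), predictor = vapply(reg, `[`, "", 2),
               stringsAsFactors = FALSE) else NULL
  covariances <- if (length(cv))
    data.frame(a = vapply(cv, `[`, "", 1), b = vapply(cv, `[`, "", 2),
               stringsAsFactors = FALSE) else NULL
  path_model(variables, regressions, covariances)
}

#' Serialize a path model to its text syntax
#' @param model a `path_model`.
#' @return single string; `parse_model(serialize_model(m))` reproduces `m`.
#' @export
serialize_model <- function(model) {
  out <- paste("variables:", paste(model$variables, collapse = " "))
  r <- model$regressions
  if (nrow(r)) for (y in unique(r$outcome))
    out <- c(out, paste(y, "~", paste(r$predictor[r$outcome == y], collapse = " + ")))
  cvs <- model$covariances
  if (nrow(cvs)) out <- c(out, paste(cvs$a, "~~", cvs$b))
  paste(out, collapse = "\n")
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path model:", length(x$variables), "variables,",
      nrow(x$regressions), "regressions,", nrow(x$covariances), "covariances\n")
  cat(serialize_model(x), "\n")
  invisible(x)
}

#' Saturated model over a variable set
#'
#' All pairwise covariances free, no regressions; `p(p+1)/2` parameters,
#' zero degrees of freedom.
#' @param variables character vector of names.
#' @return a `path_model`.
#' @export
saturated_model <- function(variables) {
  p <- length(variables)
  pairs <- if (p > 1) t(utils::combn(variables, 2)) else matrix(character(0), 0, 2)
  path_model(variables,
             covariances = data.frame(a = pairs[, 1], b = pairs[, 2],
                                      stringsAsFactors = FALSE))
}

#' Export a fitted or unfitted path model as Graphviz DOT text
#' @param model a `path_model` or `sem_fit` object.
#' @param coefficients optional named/numeric vector of edge labels (a
#'   `sem_fit` supplies its standardized coefficients automatically).
#' @return single DOT string.
#' @export
model_to_dot <- function(model, coefficients = NULL) {
  if (inherits(model, "sem_fit")) {
    coefficients <- model$standardized
    model <- model$model
  }
  r <- model$regressions
  lab <- if (!is.null(coefficients) && nrow(r))
    sprintf(" [label=\"%.2f\"]", coefficients[seq_len(nrow(r))]) else rep("", nrow(r))
  lines <- c("digraph path_model {",
             paste0("  ", model$variables, ";"),
             if (nrow(r)) paste0("  ", r$predictor, " -> ", r$outcome, lab, ";"),
             "}")
  paste(lines, collapse = "\n")
}
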