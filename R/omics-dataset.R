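#' Sample-by-feature dataset with group labels and feature annotations
#'
#' The common currency of all pipeline stages: a numeric matrix of samples x
#' features, a binary group label per sample (0 = control, 1 = compost), and
#' a compartment/category annotation per feature.
#'
#' @param values numeric matrix, samples in rows, features in columns
#'   (column names are the feature names, must be unique).
#' @param sample_ids character vector, one per row.
#' @param group integer 0/1 per sample; both groups must be non-empty.
#' @param compartment named (or feature-ordered) character vector; one of
#'   leaf/root/soil/growth/taxa.
#' @param category named (or feature-ordered) character vector of feature
#'   categories (amino_acid, flavonoid, ...).
#' @return object of class `omics_dataset`.
#' @export
omics_dataset <- function(values, sample_ids = rownames(values), group,
                          compartment = "soil", category = "metabolite") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feats <- colnames(values)
  if (is.null(feats) || anyDuplicated(feats)) stop("feature names must exist and be unique")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(nrow(values)))
  group <- as.integer(group)
  if (length(group) != nrow(values) || anyNA(group)) stop("group labels missing")
  if (!all(group %in% 0:1) || length(unique(group)) < 2)
    stop("group must be binary 0/1 with both groups non-empty")
  expand <- function(x) {
    out <- rep_len(if (is.null(names(x))) x else NA_character_, length(feats))
    names(out) <- feats
    if (!is.null(names(x))) {
      out[] <- x[1]
      out[intersect(names(x), feats)] <- x[intersect(names(x), feats)]
    }
    out
  }
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 group = group, compartment = expand(compartment),
                 category = expand(category)),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("omics_dataset:", nrow(x$values), "samples x", ncol(x$values), "features",
      sprintf("(control %d / compost %d)\n", sum(x$group == 0), sum(x$group == 1)))
  cat("compartments:", paste(names(table(x$compartment)), table(x$compartment),
                             sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Numeric feature matrix of a dataset (plus the 0/1 treatment column)
#' @param dataset an `omics_dataset`.
#' @param treatment_column name under which the group label is appended
#'   (default `"Cmp"`; NULL to omit). Ignored when the dataset already holds
#'   a column of that name.
#' @return numeric matrix.
#' @export
dataset_values <- function(dataset, treatment_column = "Cmp") {
  v <- dataset$values
  if (!is.null(treatment_column) && !treatment_column %in% colnames(v))
    v <- cbind(v, stats::setNames(data.frame(dataset$group), treatment_column))
  as.matrix(v)
}

#' @export
as.data.frame.omics_dataset <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, group = x$group, x$values,
             check.names = FALSE)
}

#' Write an `omics_dataset` as TSV with a two-line header
#'
#' Line 1: `sample_id  group  <feature names>`; line 2: `#annot  -  ` then
#' `compartment/category` per feature; data rows follow.
#' @param dataset an `omics_dataset`.
#' @param path output file.
#' @export
write_omics_tsv <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  feats <- colnames(dataset$values)
  writeLines(paste(c("sample_id", "group", feats), collapse = "\t"), con)
  writeLines(paste(c("#annot", "-",
                     paste0(dataset$compartment[feats], "/", dataset$category[feats])),
                   collapse = "\t"), con)
  utils::write.table(as.data.frame(dataset), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an `omics_dataset` written by [write_omics_tsv()]
#' @param path TSV file path.
#' @return an `omics_dataset`.
#' @export
read_omics_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  cols <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]]
  annot <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]]
  feats <- cols[-(1:2)]
  ann <- strsplit(annot[-(1:2)], "/", fixed = TRUE)
  body <- utils::read.table(path, sep = "\t", skip = 2, header = FALSE,
                            col.names = cols, check.names = FALSE)
  omics_dataset(as.matrix(body[, feats, drop = FALSE]),
                sample_ids = body[[1]], group = body[[2]],
                compartment = stats::setNames(vapply(ann, `[`, "", 1), feats),
                category = stats::setNames(vapply(ann, `[`, "", 2), feats))
}
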