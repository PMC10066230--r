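#' Compositional taxa table
#'
#' Per-sample relative abundances at a named taxonomic rank. Rows must sum
#' to 1 (within 1e-9) and all entries be nonnegative.
#'
#' @param abundances numeric matrix, samples x taxa (taxa names as columns).
#' @param sample_ids per-row sample identifiers.
#' @param rank `"genus"` or `"phylum"`.
#' @return object of class `taxa_table` (the matrix, with `rank` and
#'   `sample_ids` attributes).
#' @export
taxa_table <- function(abundances, sample_ids = rownames(abundances),
                       rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  m <- as.matrix(abundances)
  if (is.null(colnames(m))) stop("taxa must be named")
  if (any(m < 0)) stop("abundances must be nonnegative")
  if (any(abs(rowSums(m) - 1) > 1e-9)) stop("rows must sum to 1 (within 1e-9)")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(nrow(m)))
  structure(m, rank = rank, sample_ids = as.character(sample_ids),
            class = c("taxa_table", "matrix"))
}

#' @export
print.taxa_table <- function(x, ...) {
  cat("taxa_table (", attr(x, "rank"), "): ", nrow(x), " samples x ",
      ncol(x), " taxa\n", sep = "")
  print(utils::head(round(unclass(x), 4), 4))
  invisible(x)
}

#' Aggregate a genus-level table to phylum level
#'
#' Phylum abundance is the per-sample sum of its member genera; genera
#' absent from the mapping are pooled into `"unclassified"`. Compositional
#' closure (rows sum to 1) is preserved exactly.
#'
#' @param table a genus-rank `taxa_table`.
#' @param mapping named character vector genus -> phylum.
#' @return a phylum-rank `taxa_table`.
#' @export
aggregate_rank <- function(table, mapping) {
  stopifnot(inherits(table, "taxa_table"))
  genera <- colnames(table)
  phyla <- ifelse(genera %in% names(mapping), mapping[genera], "unclassified")
  out <- vapply(unique(phyla), function(ph)
    rowSums(unclass(table)[, phyla == ph, drop = FALSE]), numeric(nrow(table)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(table),
                                       dimnames = list(NULL, unique(phyla)))
  taxa_table(out, sample_ids = attr(table, "sample_ids"), rank = "phylum")
}

#' Screen taxa for treatment response at the study's reporting thresholds
#'
#' Runs the [compare_groups()] cascade on each taxon's relative abundances
#' and retains taxa with p < `p_threshold` (default 0.1) whose maximum
#' abundance over all samples exceeds `abundance_threshold` (default 0.001,
#' i.e. the ">0.1% maximum population" filter). `filter = "mean"` switches
#' the abundance filter to the mean across samples.
#'
#' @param table a `taxa_table`.
#' @param group 0/1 group label per sample (defaults to the table's `group`
#'   attribute when generated by [generate_taxa()]).
#' @param p_threshold retain p-values strictly below this.
#' @param abundance_threshold retain max (or mean) abundance strictly above
#'   this.
#' @param filter `"max"` (default) or `"mean"` abundance filter.
#' @return data.frame sorted by p: taxon, rank, max_abundance, test_used,
#'   p_value, significance_class, direction.
#' @export
screen_taxa <- function(table, group = attr(table, "group"),
                        p_threshold = 0.1, abundance_threshold = 0.001,
                        filter = c("max", "mean")) {
  filter <- match.arg(filter)
  stopifnot(inherits(table, "taxa_table"))
  if (is.null(group) || length(group) != nrow(table))
    stop("group labels must align with samples")
  m <- unclass(table)
  rows <- lapply(colnames(m), function(tx) {
    cg <- compare_groups(m[group == 0, tx], m[group == 1, tx], feature = tx)
    data.frame(taxon = tx, rank = attr(table, "rank"),
               max_abundance = max(m[, tx]),
               mean_abundance = mean(m[, tx]),
               test_used = cg$test_used, p_value = cg$p_value,
               significance_class = cg$significance_class,
               direction = cg$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ab <- if (filter == "max") out$max_abundance else out$mean_abundance
  out <- out[out$p_value < p_threshold & ab > abundance_threshold, ]
  out[order(out$p_value), ]
}

#' Shannon alpha diversity (nats) per sample
#' @param table a `taxa_table` (rows sum to 1).
#' @return numeric vector, `H = -sum p_i log p_i` over nonzero entries.
#' @export
shannon_alpha <- function(table) {
  m <- unclass(table)
  apply(m, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

#' Observed taxa count per sample
#' @param table a `taxa_table`.
#' @param detection abundances above this count as observed (default 0).
#' @return integer vector.
#' @export
observed_taxa <- function(table, detection = 0) {
  apply(unclass(table), 1, function(p) sum(p > detection))
}

#' Write/read a taxa table as TSV (samples as rows, taxa as columns)
#' @param table a `taxa_table`.
#' @param path file path.
#' @export
write_taxa_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#rank\t", attr(table, "rank")), con)
  df <- data.frame(sample_id = attr(table, "sample_ids"), unclass(table),
                   check.names = FALSE)
  grp <- attr(table, "group")
  if (!is.null(grp)) df <- cbind(df[1], group = grp, df[-1])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxa_tsv
#' @export
read_taxa_tsv <- function(path) {
  first <- readLines(path, n = 1)
  rank <- sub("^#rank\t", "", first)
  df <- utils::read.table(path, sep = "\t", skip = 1, header = TRUE,
                          check.names = FALSE)
  has_grp <- "group" %in% names(df)
  m <- as.matrix(df[, setdiff(names(df), c("sample_id", "group")), drop = FALSE])
  tt <- taxa_table(m, sample_ids = df$sample_id, rank = rank)
  if (has_grp) attr(tt, "group") <- as.integer(df$group)
  tt
}
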