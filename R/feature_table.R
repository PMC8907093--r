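# The feature table container: integer counts of features (OTUs or ASVs)
# by samples, plus a representative sequence per feature.

#' Construct a feature table
#'
#' @param counts non-negative integer matrix, features in rows (rownames =
#'   feature ids), samples in columns (colnames = sample ids).
#' @param rep_seqs named character vector mapping every feature id to its
#'   representative sequence.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(counts, rep_seqs) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && (is.null(rownames(counts)) || anyDuplicated(rownames(counts))))
    stop("counts must have unique feature rownames", call. = FALSE)
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("counts must have sample colnames", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  miss <- setdiff(rownames(counts), names(rep_seqs))
  if (length(miss) > 0)
    stop("features without a representative sequence: ",
         paste(miss, collapse = ", "), call. = FALSE)
  rep_seqs <- toupper(rep_seqs[rownames(counts)])
  structure(list(counts = counts, rep_seqs = rep_seqs), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples, %d reads total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Number of features / samples / reads
#' @param ft a `feature_table`.
#' @return named integer vector.
#' @export
ft_dims <- function(ft) {
  c(features = nrow(ft$counts), samples = ncol(ft$counts),
    reads = sum(ft$counts))
}

#' Subset a feature table to a set of features
#'
#' Counts are unchanged; order follows the table, not `ids`.
#'
#' @param ft a `feature_table`.
#' @param ids feature ids to keep.
#' @return a `feature_table`.
#' @export
ft_subset <- function(ft, ids) {
  keep <- rownames(ft$counts) %in% ids
  feature_table(ft$counts[keep, , drop = FALSE], ft$rep_seqs[keep])
}

#' Read a feature table from TSV + FASTA
#'
#' The TSV has a `feature_id` first column and one integer column per sample.
#'
#' @param tsv path to the counts TSV.
#' @param fasta path to the representative-sequence FASTA.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(tsv, fasta) {
  df <- read.delim(tsv, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1] != "feature_id")
    stop("first column of the feature table must be 'feature_id'", call. = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$feature_id
  feature_table(counts, read_fasta(fasta))
}

#' Write a feature table as TSV + FASTA
#'
#' All-zero feature rows are refused (they indicate an accounting bug).
#'
#' @param ft a `feature_table`.
#' @param tsv,fasta output paths.
#' @return the paths, invisibly.
#' @export
write_feature_table <- function(ft, tsv, fasta) {
  if (nrow(ft$counts) > 0 && any(rowSums(ft$counts) == 0))
    stop("refusing to write all-zero feature rows", call. = FALSE)
  df <- data.frame(feature_id = rownames(ft$counts), ft$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, tsv)
  write_fasta(ft$rep_seqs, fasta)
  invisible(c(tsv = tsv, fasta = fasta))
}
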