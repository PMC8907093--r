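# Thin wrappers around Biostrings for the interchange formats. All sequence
# sets travel through the package as named character vectors.

#' Read a FASTA file as a named character vector
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x)) # id = first whitespace token
  out
}

#' Write a named character vector to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) && length(seqs) > 0)
    stop("sequences must be named", call. = FALSE)
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read a FASTQ file (phred+33)
#'
#' @param path path to an (uncompressed) FASTQ file.
#' @return a list with `seq` (named character vector) and `qual` (character
#'   vector of phred+33 quality strings, same names).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- setNames(toupper(as.character(x)), ids)
  qual <- setNames(as.character(S4Vectors::mcols(x)$qualities), ids)
  list(seq = seqs, qual = qual)
}

#' Write sequences with qualities to FASTQ (phred+33)
#'
#' @param seqs named character vector of sequences.
#' @param qual character vector of quality strings (recycled if a single
#'   constant-quality string pattern is wanted, supply full strings).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, qual, path) {
  stopifnot(length(seqs) == length(qual))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs) > 0) {
    rec <- paste0("@", names(seqs), "\n", seqs, "\n+\n", qual)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read a reference family map
#'
#' A TSV with columns `id`, `group_label`, `taxon`, `accession` (the last two
#' may be empty). `group_label` is either an AMF family name or an outgroup
#' group name.
#'
#' @param path TSV path.
#' @return data.frame with the four columns as character.
#' @export
read_family_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  need <- c("id", "group_label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("family map lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$taxon)) df$taxon <- ""
  if (is.null(df$accession)) df$accession <- ""
  df[, c("id", "group_label", "taxon", "accession")]
}

#' @keywords internal
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
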