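# Split R1/R2 alignment. The R1 and R2 fragments cover two separate stretches
# of the LSU region, so they are aligned in two independent blocks and
# concatenated afterwards; R1 content can therefore never occupy R2 columns
# of another sequence or vice versa.
#
# Alignment blocks are named character vectors of equal-width rows with an
# "is_ref" logical attribute marking reference rows. Queries are aligned
# against the frozen reference column profile, never against each other, so
# adding a query can neither perturb the reference rows nor another query.

.block <- function(rows, is_ref) {
  stopifnot(length(rows) == length(is_ref))
  if (length(rows) > 0 && length(unique(nchar(rows))) != 1)
    stop("alignment rows must have equal width", call. = FALSE)
  structure(rows, is_ref = is_ref, class = "msa_block")
}

#' @export
print.msa_block <- function(x, ...) {
  cat(sprintf("msa_block: %d rows (%d reference) x %d columns\n",
              length(x), sum(attr(x, "is_ref")),
              if (length(x) > 0) nchar(x[[1]]) else 0L))
  invisible(x)
}

#' Alignment block width (columns)
#' @param block an `msa_block`.
#' @return integer column count.
#' @export
block_width <- function(block) if (length(block) == 0) 0L else nchar(block[[1]])

# Column profile of the reference rows of a block: a 4 x W matrix of
# position-specific scores. Only A/C/G/T content is informative; N and '-'
# cells contribute nothing ("gap-neutral" N). A column with no informative
# content scores 0 for every base.
.profile_scores <- function(rows, scoring) {
  W <- nchar(rows[[1]])
  mat <- matrix(unlist(strsplit(rows, "", fixed = TRUE)),
                nrow = length(rows), ncol = W, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  freq <- matrix(0, nrow = 4, ncol = W, dimnames = list(bases, NULL))
  for (b in seq_along(bases)) freq[b, ] <- colSums(mat == bases[b])
  tot <- colSums(freq)
  informative <- tot > 0
  f <- sweep(freq, 2, pmax(tot, 1), "/")
  # expected score of base b against the column
  sc <- scoring$match * f + scoring$mismatch * (1 - f)
  sc[, !informative] <- 0
  sc
}

#' Progressively align reference fragments into a fixed-width block
#'
#' Builds the per-block reference alignment by adding fragments one at a time
#' (guide order = input order): each new fragment is aligned against the
#' column profile of the rows so far with free terminal gaps, and any
#' insertion it carries opens a new all-gap column in the existing rows.
#' Deterministic for a given input order.
#'
#' @param fragments named character vector of at least two reference
#'   fragments (one block: all-R1 or all-R2).
#' @param scoring a [scoring_scheme()].
#' @return an `msa_block` of reference rows.
#' @export
build_reference_alignment <- function(fragments, scoring = scoring_scheme()) {
  if (length(fragments) < 2)
    stop("need at least 2 reference fragments per block", call. = FALSE)
  fragments <- toupper(fragments)
  rows <- fragments[1]
  for (i in 2:length(fragments)) {
    prof <- .profile_scores(rows, scoring)
    res <- .profile_align_cpp(prof, fragments[[i]], scoring$gap_open,
                              scoring$gap_extend, TRUE)
    ops <- res$ops
    seq_chars <- strsplit(fragments[[i]], "", fixed = TRUE)[[1]]
    new_row <- character(length(ops))
    keep_col <- integer(0) # for existing rows: which op consumes a column
    si <- 0L
    old_cols <- integer(length(ops)) # 0 = new gap column
    ci <- 0L
    for (k in seq_along(ops)) {
      op <- ops[k]
      if (op == 0L) { si <- si + 1L; ci <- ci + 1L
        new_row[k] <- seq_chars[si]; old_cols[k] <- ci }
      else if (op == 1L) { ci <- ci + 1L
        new_row[k] <- "-"; old_cols[k] <- ci }
      else { si <- si + 1L
        new_row[k] <- seq_chars[si]; old_cols[k] <- 0L }
    }
    keep_col <- old_cols
    old_mat <- strsplit(rows, "", fixed = TRUE)
    rows <- vapply(old_mat, function(ch) {
      paste(ifelse(keep_col == 0L, "-", ch[pmax(keep_col, 1L)]), collapse = "")
    }, character(1), USE.NAMES = TRUE)
    names(rows) <- names(fragments)[seq_len(i - 1L)]
    rows <- c(rows, setNames(paste(new_row, collapse = ""),
                             names(fragments)[i]))
  }
  .block(rows, rep(TRUE, length(rows)))
}

#' Align a query fragment against a reference block
#'
#' The query is globally aligned (free terminal gaps) to the block's
#' position-specific profile. Reference columns are immutable: query bases
#' that would insert new columns are dropped and counted, so the output row
#' has exactly the block's width and the reference coordinate system is
#' preserved.
#'
#' @param query a single query fragment.
#' @param block an `msa_block` whose reference rows define the profile.
#' @param scoring a [scoring_scheme()].
#' @return list with `row` (aligned string of block width) and
#'   `dropped_insertions` (count of dropped query bases).
#' @export
align_query_to_block <- function(query, block, scoring = scoring_scheme()) {
  if (!nzchar(query)) stop("query must be non-empty", call. = FALSE)
  ref_rows <- block[attr(block, "is_ref")]
  if (length(ref_rows) == 0) stop("block has no reference rows", call. = FALSE)
  prof <- .profile_scores(ref_rows, scoring)
  res <- .profile_align_cpp(prof, toupper(query), scoring$gap_open,
                            scoring$gap_extend, TRUE)
  ops <- res$ops
  seq_chars <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  out <- character(0)
  si <- 0L; dropped <- 0L
  for (op in ops) {
    if (op == 0L) { si <- si + 1L; out <- c(out, seq_chars[si]) }
    else if (op == 1L) out <- c(out, "-")
    else { si <- si + 1L; dropped <- dropped + 1L }
  }
  list(row = paste(out, collapse = ""), dropped_insertions = dropped)
}

#' Add query fragments to both blocks of a split alignment
#'
#' @param split a `split_alignment` (see [split_alignment()]).
#' @param q_r1,q_r2 named character vectors of query fragments over the same
#'   query ids.
#' @param scoring a [scoring_scheme()].
#' @return the extended `split_alignment`; an `insertions` attribute records
#'   dropped insertion counts per query and block.
#' @export
add_queries <- function(split, q_r1, q_r2, scoring = scoring_scheme()) {
  stopifnot(inherits(split, "split_alignment"))
  if (!identical(sort(names(q_r1)), sort(names(q_r2))))
    stop("query ids differ between R1 and R2 fragments", call. = FALSE)
  q_r2 <- q_r2[names(q_r1)]
  ins <- data.frame(query_id = names(q_r1), r1_dropped = 0L, r2_dropped = 0L,
                    stringsAsFactors = FALSE)
  add_rows <- function(block, frags) {
    alns <- lapply(frags, align_query_to_block, block = block, scoring = scoring)
    rows <- vapply(alns, `[[`, character(1), "row")
    drops <- vapply(alns, `[[`, integer(1), "dropped_insertions")
    list(block = .block(c(unclass(block), rows),
                        c(attr(block, "is_ref"), rep(FALSE, length(rows)))),
         drops = drops)
  }
  a1 <- add_rows(split$r1, q_r1)
  a2 <- add_rows(split$r2, q_r2)
  ins$r1_dropped <- unname(a1$drops)
  ins$r2_dropped <- unname(a2$drops)
  out <- split_alignment(a1$block, a2$block)
  attr(out, "insertions") <- ins
  out
}

#' Paired R1/R2 alignment blocks over the same row set
#'
#' @param r1,r2 `msa_block`s with identical row names and reference flags.
#' @return an object of class `split_alignment`.
#' @export
split_alignment <- function(r1, r2) {
  stopifnot(inherits(r1, "msa_block"), inherits(r2, "msa_block"))
  structure(list(r1 = r1, r2 = r2), class = "split_alignment")
}

#' @export
print.split_alignment <- function(x, ...) {
  cat(sprintf("split_alignment: %d rows; R1 %d cols + R2 %d cols\n",
              length(x$r1), block_width(x$r1), block_width(x$r2)))
  invisible(x)
}

#' Concatenate the R1 and R2 blocks into one alignment
#'
#' Row-wise concatenation, R1 block first; no characters are altered. The
#' result width is the sum of the block widths.
#'
#' @param split a `split_alignment`.
#' @return named character vector of concatenated rows, with the `is_ref`
#'   attribute carried over.
#' @export
concatenate_blocks <- function(split) {
  stopifnot(inherits(split, "split_alignment"))
  n1 <- names(split$r1); n2 <- names(split$r2)
  if (!identical(sort(n1), sort(n2))) {
    miss <- c(setdiff(n1, n2), setdiff(n2, n1))
    stop("row sets differ between blocks; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  r2 <- unclass(split$r2)[n1]
  out <- paste0(unclass(split$r1), r2)
  names(out) <- n1
  attr(out, "is_ref") <- attr(split$r1, "is_ref")
  out
}
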