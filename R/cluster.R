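# Dereplication and feature construction: greedy centroid OTU clustering at
# an identity threshold, or ASV passthrough (the two coincide at identity 1).

#' Dereplicate sequences into unique features
#'
#' Aggregates identical sequences into one feature each, summing counts per
#' sample, and orders features by decreasing total abundance (ties broken by
#' lexicographic sequence). Feature ids are `ASV_0001`, `ASV_0002`, ... in
#' that order.
#'
#' @param seqs character vector of sequences (one entry per read or per
#'   pre-counted record).
#' @param samples character vector of sample ids, parallel to `seqs`.
#' @param counts integer counts, parallel to `seqs` (default 1 per entry).
#' @return a [feature_table()].
#' @export
dereplicate <- function(seqs, samples, counts = rep(1L, length(seqs))) {
  stopifnot(length(seqs) == length(samples), length(seqs) == length(counts))
  if (length(seqs) == 0) {
    return(feature_table(matrix(integer(0), 0, 0), character(0)))
  }
  seqs <- toupper(seqs)
  usam <- sort(unique(samples))
  useq <- unique(seqs)
  counts_mat <- matrix(0L, nrow = length(useq), ncol = length(usam),
                       dimnames = list(NULL, usam))
  si <- match(seqs, useq); sj <- match(samples, usam)
  for (k in seq_along(seqs)) {
    counts_mat[si[k], sj[k]] <- counts_mat[si[k], sj[k]] + as.integer(counts[k])
  }
  tot <- rowSums(counts_mat)
  ord <- order(-tot, useq)
  counts_mat <- counts_mat[ord, , drop = FALSE]
  useq <- useq[ord]
  ids <- sprintf("ASV_%04d", seq_along(useq))
  rownames(counts_mat) <- ids
  feature_table(counts_mat, setNames(useq, ids))
}

#' @keywords internal
pairwise_identity <- function(a, b, scoring = scoring_scheme()) {
  .nw_align_cpp(a, b, scoring$match, scoring$mismatch, scoring$gap_open,
                scoring$gap_extend, FALSE)$identity
}

#' Greedy centroid OTU clustering
#'
#' Features are processed in the table's (abundance-sorted) order; each
#' sequence joins the first existing centroid with which its end-to-end
#' global-alignment identity (matching columns over all alignment columns;
#' gap columns count as mismatches) reaches `identity_threshold`, otherwise
#' it founds a new cluster. Cluster counts are summed member counts; the
#' cluster keeps its centroid's feature id and representative sequence.
#'
#' @param ft a dereplicated [feature_table()].
#' @param identity_threshold fraction in `[0.5, 1]`; default 0.97, the common
#'   field convention.
#' @param scoring a [scoring_scheme()] used for the global alignments.
#' @return list with `clusters` (data.frame: centroid_id, member_id,
#'   identity) and `table` (the clustered `feature_table`).
#' @export
cluster_otus <- function(ft, identity_threshold = 0.97,
                         scoring = scoring_scheme()) {
  if (identity_threshold < 0.5 || identity_threshold > 1)
    stop("identity_threshold must be in [0.5, 1]", call. = FALSE)
  ids <- rownames(ft$counts)
  n <- length(ids)
  if (n == 0) return(list(clusters = data.frame(centroid_id = character(0),
                                                member_id = character(0),
                                                identity = numeric(0)),
                          table = ft))
  centroid_of <- character(n)
  centroid_ids <- character(0)
  member_identity <- numeric(n)
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (identity_threshold < 1 && length(centroid_ids) > 0) {
      for (cid in centroid_ids) {
        idy <- pairwise_identity(ft$rep_seqs[[ids[i]]], ft$rep_seqs[[cid]],
                                 scoring)
        if (idy >= identity_threshold) {
          centroid_of[i] <- cid; member_identity[i] <- idy
          assigned <- TRUE; break
        }
      }
    }
    if (!assigned) {
      centroid_of[i] <- ids[i]
      member_identity[i] <- 1
      centroid_ids <- c(centroid_ids, ids[i])
    }
  }
  counts <- rowsum(ft$counts, group = centroid_of, reorder = FALSE)
  # keep the original table order of the centroids
  counts <- counts[centroid_ids, , drop = FALSE]
  tab <- feature_table(counts, ft$rep_seqs[centroid_ids])
  list(clusters = data.frame(centroid_id = centroid_of, member_id = ids,
                             identity = member_identity,
                             stringsAsFactors = FALSE),
       table = tab)
}

#' ASV passthrough
#'
#' Returns the dereplicated unique sequences as the final features, i.e. OTU
#' clustering with the threshold at exactly 1. The output equals
#' `cluster_otus(ft, 1)$table`.
#'
#' @param ft a dereplicated [feature_table()].
#' @return the same `feature_table`.
#' @export
asv_passthrough <- function(ft) ft

#' Truncate, filter, and merge paired reads into feature sequences
#'
#' A deliberately simple stand-in for a full denoising step: truncates R1 and
#' R2 to fixed lengths, drops pairs containing N or shorter than the
#' truncation length, and merges by concatenating the truncated R1 with the
#' reverse complement of the truncated R2 (the two read fragments cover
#' disjoint ends of the amplified region, so no overlap assembly is
#' attempted). Use externally denoised ASVs when error correction matters.
#'
#' @param r1,r2 primer-clipped read pairs (named character vectors).
#' @param r1_len,r2_len truncation lengths in bp.
#' @return list with `seq` (named merged sequences) and `log` counts.
#' @export
merge_read_pairs <- function(r1, r2, r1_len, r2_len) {
  stopifnot(length(r1) == length(r2))
  long_enough <- nchar(r1) >= r1_len & nchar(r2) >= r2_len
  t1 <- substr(r1, 1L, r1_len)
  t2 <- substr(r2, 1L, r2_len)
  clean <- !grepl("N", t1, fixed = TRUE) & !grepl("N", t2, fixed = TRUE)
  keep <- long_enough & clean
  merged <- paste0(t1[keep], revcomp(t2[keep]))
  names(merged) <- names(r1)[keep]
  list(seq = merged,
       log = c(n_pairs = length(r1), n_short = sum(!long_enough),
               n_with_N = sum(long_enough & !clean), n_merged = sum(keep)))
}
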