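# Homology pre-screen: a permissive local-alignment filter that keeps only
# study sequences showing some similarity to the curated reference database,
# removing non-homologous reads before any tree building. Non-homologous
# sequences otherwise attract each other during placement and produce
# spurious long-branch clusters.

#' Alignment scoring scheme
#'
#' Parameterises the local and global aligners. A gap of length L costs
#' `|gap_open| + L * |gap_extend|`. `N` scores 0 against everything.
#'
#' The defaults (+1 / -2 / -5 / -2, word size 7) are deliberately permissive:
#' together with the default screening `min_score` of 40 they retain anything
#' sharing roughly a 40 bp perfect match (or an equivalent slightly longer,
#' imperfect stretch) with any reference.
#'
#' @param match positive match reward.
#' @param mismatch mismatch penalty (<= 0).
#' @param gap_open gap opening penalty (<= 0).
#' @param gap_extend gap extension penalty (<= 0).
#' @param word_size exact-seed length (>= 4) used by the optional
#'   seed-and-extend accelerator in [screen_queries()].
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -2, word_size = 7) {
  if (match <= 0) stop("match reward must be positive", call. = FALSE)
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0)
    stop("penalties must be <= 0", call. = FALSE)
  if (word_size < 4) stop("word_size must be >= 4", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = as.integer(word_size)),
            class = "scoring_scheme")
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gaps under a
#' [scoring_scheme()]. Both strands of the query are tried and the better
#' one reported.
#'
#' @param query,subject single uppercase DNA strings (N allowed).
#' @param scoring a [scoring_scheme()].
#' @return list with `score`, `identity` (matches over aligned columns,
#'   gap columns included), `aligned_length`, `strand` (`"+"`/`"-"`),
#'   `q_start`, `q_end`, `s_start`, `s_end` (1-based inclusive, on the
#'   reported strand of the query).
#' @export
local_align <- function(query, subject, scoring = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(subject))
    stop("query and subject must be non-empty", call. = FALSE)
  run <- function(q, strand) {
    r <- .sw_align_cpp(q, subject, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
    r$strand <- strand
    r
  }
  fw <- run(toupper(query), "+")
  rv <- run(revcomp(toupper(query)), "-")
  best <- if (rv$score > fw$score) rv else fw
  list(score = best$score,
       identity = if (best$columns > 0) best$matches / best$columns else 0,
       aligned_length = best$columns,
       strand = best$strand,
       q_start = best$q_start, q_end = best$q_end,
       s_start = best$s_start, s_end = best$s_end)
}

#' @keywords internal
seq_words <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, seq_len(n - k + 1L), k:n)
  unique(w[!grepl("[^ACGT]", w)])
}

#' Screen study sequences for homology to the reference database
#'
#' A query is retained iff its best local-alignment score against any
#' curated reference region reaches `min_score`. Both query strands are
#' screened; references are assumed forward-oriented after curation.
#'
#' With `accelerate = TRUE`, subjects sharing exact words of
#' `scoring$word_size` with the query are aligned first and scanning stops at
#' the first subject reaching `min_score`. This never changes which queries
#' are retained (every pair is still aligned if no early hit is found), but
#' the reported best subject for a retained query may then be the first
#' sufficient hit rather than the global best.
#'
#' @param queries named character vector of study sequences (typically merged
#'   R1+R2 feature sequences).
#' @param db a `reference_db` from [build_reference_db()], or a named
#'   character vector of reference sequences.
#' @param scoring a [scoring_scheme()].
#' @param min_score positive retention threshold.
#' @param accelerate use the seed-and-extend early-exit strategy.
#' @return list with `retained` (character vector of retained query ids) and
#'   `results` (data.frame: query_id, best_subject_id, best_score, identity,
#'   aligned_length, retained).
#' @export
screen_queries <- function(queries, db, scoring = scoring_scheme(),
                           min_score = 40, accelerate = FALSE) {
  if (min_score <= 0) stop("min_score must be positive", call. = FALSE)
  subjects <- if (inherits(db, "reference_db")) db$region_seqs else db
  if (length(subjects) == 0) stop("reference database is empty", call. = FALSE)
  if (length(queries) == 0) {
    return(list(retained = character(0),
                results = data.frame(query_id = character(0),
                                     best_subject_id = character(0),
                                     best_score = numeric(0),
                                     identity = numeric(0),
                                     aligned_length = integer(0),
                                     retained = logical(0))))
  }
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    stop("queries must have unique names", call. = FALSE)

  word_index <- NULL
  if (accelerate) {
    word_index <- lapply(subjects, seq_words, k = scoring$word_size)
  }
  n <- length(queries)
  best_score <- numeric(n); best_subject <- character(n)
  identity <- numeric(n); alen <- integer(n)
  for (i in seq_len(n)) {
    q <- queries[[i]]
    qrc <- revcomp(q)
    ord <- seq_along(subjects)
    if (accelerate) {
      qwords <- union(seq_words(q, scoring$word_size),
                      seq_words(qrc, scoring$word_size))
      hits <- vapply(word_index, function(w) sum(w %in% qwords), numeric(1))
      ord <- order(-hits, seq_along(subjects))
    }
    bs <- -Inf; bj <- NA_integer_
    for (j in ord) {
      s <- max(.sw_score_cpp(q, subjects[[j]], scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_extend),
               .sw_score_cpp(qrc, subjects[[j]], scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_extend))
      if (s > bs) { bs <- s; bj <- j }
      if (accelerate && bs >= min_score) break
    }
    aln <- local_align(q, subjects[[bj]], scoring)
    best_score[i] <- bs
    best_subject[i] <- names(subjects)[bj]
    identity[i] <- aln$identity
    alen[i] <- aln$aligned_length
  }
  retained <- best_score >= min_score
  results <- data.frame(query_id = names(queries),
                        best_subject_id = best_subject,
                        best_score = best_score,
                        identity = identity,
                        aligned_length = alen,
                        retained = retained,
                        stringsAsFactors = FALSE)
  list(retained = names(queries)[retained], results = results)
}
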