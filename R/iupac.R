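# IUPAC nucleotide handling shared by primer matching and the reference
# curation code. Bases are represented as 4-bit masks over {A, C, G, T};
# two characters are compatible iff their masks intersect.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

#' @keywords internal
iupac_bits <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bits <- .IUPAC_BITS[chars]
  if (anyNA(bits)) {
    bad <- unique(chars[is.na(bits)])
    stop(sprintf("invalid character(s) in %s: %s", what,
                 paste(dQuote(bad, FALSE), collapse = ", ")), call. = FALSE)
  }
  unname(bits)
}

#' @keywords internal
is_valid_iupac <- function(seq) {
  nzchar(seq) &&
    !anyNA(.IUPAC_BITS[strsplit(toupper(seq), "", fixed = TRUE)[[1]]])
}

#' Reverse complement of nucleotide sequences
#'
#' Vectorised over a character vector; IUPAC ambiguity codes and gaps are
#' complemented correctly (e.g. `R` -> `Y`, `N` -> `N`, `-` -> `-`).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length, names preserved.
#' @examples
#' revcomp(c("ACGT", "AANR"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", x)
  out <- vapply(strsplit(out, "", fixed = TRUE),
                function(ch) paste(rev(ch), collapse = ""), character(1))
  names(out) <- names(x)
  out
}

#' Locate the best match of a degenerate primer in a sequence
#'
#' Scans every window of length `nchar(primer)` and returns the
#' minimal-mismatch window whose mismatch count does not exceed
#' `floor(max_error_rate * nchar(primer))`. IUPAC codes in either the primer
#' or the sequence match any base they denote; `N` on either side matches
#' everything (0 mismatches). Ties are broken by the leftmost position.
#' Indels are not considered.
#'
#' @param seq a single nucleotide string.
#' @param primer a single IUPAC primer string.
#' @param max_error_rate allowed mismatch fraction in `[0, 0.5)`.
#' @return a list with elements `start`, `end` (0-based, half-open) and
#'   `mismatches`, or `NULL` if no window qualifies.
#' @examples
#' find_primer_site("GGAAACC", "AAA", 0)     # exact hit at (2, 5)
#' find_primer_site("GGAGACC", "ARA", 0)     # R matches A or G
#' @export
find_primer_site <- function(seq, primer, max_error_rate = 0.1) {
  stopifnot(length(seq) == 1, length(primer) == 1)
  if (!nzchar(seq)) stop("sequence must be non-empty", call. = FALSE)
  if (!nzchar(primer)) stop("primer must be non-empty", call. = FALSE)
  if (!is.numeric(max_error_rate) || max_error_rate < 0 || max_error_rate >= 0.5)
    stop("max_error_rate must be in [0, 0.5)", call. = FALSE)
  sb <- iupac_bits(seq, "sequence")
  pb <- iupac_bits(primer, "primer")
  k <- length(pb)
  n <- length(sb)
  if (k > n) return(NULL)
  nwin <- n - k + 1L
  mm <- integer(nwin)
  for (j in seq_len(k)) {
    mm <- mm + as.integer(bitwAnd(sb[j:(j + nwin - 1L)], pb[j]) == 0L)
  }
  allowed <- floor(max_error_rate * k)
  best <- which.min(mm) # leftmost minimum
  if (mm[best] > allowed) return(NULL)
  list(start = best - 1L, end = best - 1L + k, mismatches = mm[best])
}
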