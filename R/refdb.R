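# Reference-database curation: trim references to the primer-bounded LSU
# region, pad short entries with N to a common target length, annotate family
# labels, and cut the curated regions to study read lengths.

#' Define an amplification primer pair
#'
#' @param forward_name,forward_seq name and IUPAC sequence of the forward
#'   primer (5' end of R1 reads).
#' @param reverse_name,reverse_seq name and IUPAC sequence of the reverse
#'   primer (5' end of R2 reads).
#' @param max_error_rate allowed mismatch fraction per primer match,
#'   in `[0, 0.5)`. Mismatch counting only; indels are not modelled.
#' @return an object of class `primer_pair`.
#' @seealso [default_primer_pair()] for the shipped LROR/FLR2 defaults.
#' @export
primer_pair <- function(forward_name, forward_seq, reverse_name, reverse_seq,
                        max_error_rate = 0.1) {
  for (s in c(forward_seq, reverse_seq)) {
    if (!is_valid_iupac(s))
      stop("primer sequences must be non-empty IUPAC nucleotide strings",
           call. = FALSE)
  }
  if (!is.numeric(max_error_rate) || max_error_rate < 0 || max_error_rate >= 0.5)
    stop("max_error_rate must be in [0, 0.5)", call. = FALSE)
  structure(
    list(forward_name = forward_name, forward_seq = toupper(forward_seq),
         reverse_name = reverse_name, reverse_seq = toupper(reverse_seq),
         max_error_rate = max_error_rate),
    class = "primer_pair"
  )
}

#' Default LROR/FLR2 primer pair
#'
#' The widely used LSU primers LROR (forward) and FLR2 (reverse) delimiting
#' the amplified 28S region. The sequences are the published primer strings
#' from the primary literature (Vilgalys lab LROR; Trouvelot et al. FLR2) and
#' are shipped as editable defaults, not hard-coded constants: pass your own
#' [primer_pair()] anywhere a primer pair is accepted.
#'
#' @param max_error_rate allowed mismatch fraction (default 0.1).
#' @return a `primer_pair`.
#' @export
default_primer_pair <- function(max_error_rate = 0.1) {
  primer_pair("LROR", "ACCCGCTGAACTTAAGC",
              "FLR2", "GTCGTTTAAAGCCATTACGTC",
              max_error_rate = max_error_rate)
}

#' Trim a reference sequence to the primer-bounded region
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer in the sequence (trying both strand orientations) and returns the
#' inner region between (and excluding) the two sites, in forward
#' orientation. If only one or neither site is found the full sequence is
#' returned flagged `trimmed = FALSE` so that it can be padded instead.
#'
#' @param seq a single nucleotide string.
#' @param primers a [primer_pair()].
#' @param max_error_rate overrides the pair's error rate if given.
#' @return list with `region`, `trimmed` (logical), `orientation`
#'   (`"forward"`, `"reverse"` or `NA`), and 0-based half-open `fwd_site` /
#'   `rev_site` coordinates on the searched strand (or `NULL`).
#' @export
trim_reference <- function(seq, primers, max_error_rate = NULL) {
  stopifnot(inherits(primers, "primer_pair"))
  if (!nzchar(seq)) stop("reference sequence must be non-empty", call. = FALSE)
  rate <- if (is.null(max_error_rate)) primers$max_error_rate else max_error_rate
  rc_rev <- revcomp(primers$reverse_seq)
  misordered <- FALSE
  for (orient in c("forward", "reverse")) {
    s <- if (orient == "forward") seq else revcomp(seq)
    f <- find_primer_site(s, primers$forward_seq, rate)
    r <- find_primer_site(s, rc_rev, rate)
    if (!is.null(f) && !is.null(r)) {
      if (r$start < f$end) { misordered <- TRUE; next }
      region <- substr(s, f$end + 1L, r$start)
      return(list(region = region, trimmed = TRUE, orientation = orient,
                  fwd_site = f, rev_site = r))
    }
  }
  if (misordered)
    stop("malformed reference: reverse primer site upstream of forward site",
         call. = FALSE)
  list(region = toupper(seq), trimmed = FALSE, orientation = NA_character_,
       fwd_site = NULL, rev_site = NULL)
}

#' Pad a sequence with N to a target region length
#'
#' @param seq a single nucleotide string with `nchar(seq) <=
#'   target_region_length`.
#' @param target_region_length target length in bp.
#' @param anchor `"start"` keeps the sequence 5'-anchored and appends N;
#'   `"end"` prepends N.
#' @return list with `seq` (padded), `pad_left`, `pad_right`.
#' @export
pad_to_region <- function(seq, target_region_length, anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  n <- nchar(seq)
  if (n > target_region_length)
    stop(sprintf("sequence (%d bp) longer than target region (%d bp); trim first",
                 n, target_region_length), call. = FALSE)
  pad <- target_region_length - n
  if (anchor == "start") {
    list(seq = paste0(seq, strrep("N", pad)), pad_left = 0L, pad_right = pad)
  } else {
    list(seq = paste0(strrep("N", pad), seq), pad_left = pad, pad_right = 0L)
  }
}

#' Build a curated reference database
#'
#' Trims every reference to the primer-bounded region ([trim_reference()]),
#' pads all records with N to a common target length ([pad_to_region()]), and
#' attaches family / group labels from the family map. References in which no
#' primer pair is found are retained untrimmed and padded (the database may
#' legitimately include shorter-amplicon references), unless `strict = TRUE`.
#'
#' @param fasta path to a reference FASTA file, or a named character vector.
#' @param family_map path to a family-map TSV ([read_family_map()]) or an
#'   equivalent data.frame with columns `id`, `group_label`, `taxon`,
#'   `accession`.
#' @param primers a [primer_pair()]; default [default_primer_pair()].
#' @param target_region_length common curated length; default is the maximum
#'   trimmed length across records.
#' @param anchor padding anchor, see [pad_to_region()]; default `"start"`.
#' @param outgroup_labels group labels to treat as non-AMF outgroups. The
#'   default treats any label starting with `"outgroup"` (case-insensitive)
#'   as an outgroup; all remaining labels are AMF family names.
#' @param strict drop untrimmed (primer-less) references instead of padding
#'   them.
#' @return an object of class `reference_db`: list with `records`
#'   (data.frame: id, accession, taxon, group_label, is_outgroup, trimmed,
#'   pad_left, pad_right), `region_seqs` (named character vector over
#'   `{A,C,G,T,N}` and IUPAC codes, all of the target length),
#'   `target_region_length`, `primer_pair`, `family_names`.
#' @export
build_reference_db <- function(fasta, family_map,
                               primers = default_primer_pair(),
                               target_region_length = NULL,
                               anchor = c("start", "end"),
                               outgroup_labels = NULL,
                               strict = FALSE) {
  anchor <- match.arg(anchor)
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    read_fasta(fasta) else toupper(fasta)
  if (length(seqs) == 0) stop("reference FASTA is empty", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("reference sequences must be named", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate reference ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  fmap <- if (is.data.frame(family_map)) family_map else read_family_map(family_map)
  missing_ids <- setdiff(names(seqs), fmap$id)
  if (length(missing_ids) > 0)
    stop("reference id(s) missing from family map: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  fmap <- fmap[match(names(seqs), fmap$id), , drop = FALSE]

  trims <- lapply(seqs, trim_reference, primers = primers)
  trimmed <- vapply(trims, `[[`, logical(1), "trimmed")
  if (strict) {
    keep <- trimmed
    if (!any(keep)) stop("strict mode dropped every reference", call. = FALSE)
    seqs <- seqs[keep]; trims <- trims[keep]; trimmed <- trimmed[keep]
    fmap <- fmap[keep, , drop = FALSE]
  }
  regions <- vapply(trims, `[[`, character(1), "region")
  lens <- nchar(regions)
  if (is.null(target_region_length)) target_region_length <- max(lens)
  too_long <- lens > target_region_length
  if (any(too_long))
    stop("region(s) longer than target_region_length: ",
         paste(names(regions)[too_long], collapse = ", "), call. = FALSE)
  padded <- lapply(regions, pad_to_region,
                   target_region_length = target_region_length, anchor = anchor)
  region_seqs <- vapply(padded, `[[`, character(1), "seq")
  names(region_seqs) <- names(seqs)

  is_out <- if (is.null(outgroup_labels)) {
    grepl("^outgroup", fmap$group_label, ignore.case = TRUE)
  } else {
    fmap$group_label %in% outgroup_labels
  }
  records <- data.frame(
    id = names(seqs),
    accession = fmap$accession,
    taxon = fmap$taxon,
    group_label = fmap$group_label,
    is_outgroup = is_out,
    trimmed = trimmed,
    pad_left = vapply(padded, `[[`, integer(1), "pad_left"),
    pad_right = vapply(padded, `[[`, integer(1), "pad_right"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  db <- structure(
    list(records = records, region_seqs = region_seqs,
         target_region_length = as.integer(target_region_length),
         primer_pair = primers,
         family_names = sort(unique(records$group_label[!records$is_outgroup]))),
    class = "reference_db"
  )
  db
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d records (%d trimmed, %d padded), region %d bp\n",
              nrow(x$records), sum(x$records$trimmed),
              sum(x$records$pad_left + x$records$pad_right > 0),
              x$target_region_length))
  cat(sprintf("  families (%d): %s\n", length(x$family_names),
              paste(x$family_names, collapse = ", ")))
  cat(sprintf("  outgroup records: %d\n", sum(x$records$is_outgroup)))
  invisible(x)
}

#' Write a curated database to FASTA plus a JSON manifest
#'
#' @param db a `reference_db`.
#' @param dir output directory (created if missing).
#' @return paths, invisibly.
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "reference_regions.fasta")
  write_fasta(db$region_seqs, fa)
  manifest <- list(
    target_region_length = db$target_region_length,
    primer_pair = unclass(db$primer_pair),
    n_records = nrow(db$records),
    n_trimmed = sum(db$records$trimmed),
    n_padded = sum(db$records$pad_left + db$records$pad_right > 0),
    family_names = db$family_names,
    records = db$records
  )
  mf <- file.path(dir, "reference_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  tsv <- file.path(dir, "family_map.tsv")
  write_tsv(db$records[, c("id", "group_label", "taxon", "accession")], tsv)
  invisible(c(fasta = fa, manifest = mf, family_map = tsv))
}

#' Cut curated references to study read lengths
#'
#' Mimics the study reads on the reference side: each curated region yields an
#' R1 fragment (its first `r1_len` bases) and an R2 fragment (its last
#' `r2_len` bases, reverse-complemented into read orientation).
#'
#' @param db a `reference_db`.
#' @param r1_len,r2_len positive fragment lengths with
#'   `r1_len + r2_len <= target_region_length`.
#' @return list with named character vectors `r1` and `r2` plus the lengths.
#' @export
cut_reference_to_read_lengths <- function(db, r1_len, r2_len) {
  stopifnot(inherits(db, "reference_db"))
  r1_len <- as.integer(r1_len); r2_len <- as.integer(r2_len)
  if (r1_len < 1 || r2_len < 1)
    stop("read lengths must be positive", call. = FALSE)
  if (r1_len + r2_len > db$target_region_length)
    stop(sprintf("r1_len + r2_len (%d) exceeds target region length (%d)",
                 r1_len + r2_len, db$target_region_length), call. = FALSE)
  reg <- db$region_seqs
  L <- db$target_region_length
  r1 <- substr(reg, 1L, r1_len)
  r2 <- revcomp(substr(reg, L - r2_len + 1L, L))
  names(r1) <- names(reg); names(r2) <- names(reg)
  list(r1 = r1, r2 = r2, r1_len = r1_len, r2_len = r2_len)
}

#' Clip primers from paired study reads
#'
#' Removes the forward primer from the 5' end of R1 and the reverse primer
#' from the 5' end of R2 where found (anchored at the read start, within the
#' pair's `max_error_rate`). Pairs lacking a detectable primer on either side
#' are flagged and, under `policy = "drop"`, excluded.
#'
#' @param r1,r2 named character vectors of equal length (read pairs).
#' @param primers a [primer_pair()].
#' @param policy `"keep"` retains primer-less pairs unclipped; `"drop"`
#'   removes them.
#' @param q1,q2 optional quality strings clipped alongside.
#' @return list with `r1`, `r2`, (`q1`, `q2` if given), `flags` (data.frame:
#'   id, primer_r1, primer_r2, kept) and a `log` vector of counts.
#' @export
trim_read_pair <- function(r1, r2, primers = default_primer_pair(),
                           policy = c("keep", "drop"), q1 = NULL, q2 = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(primers, "primer_pair"), length(r1) == length(r2))
  clip_one <- function(reads, primer) {
    k <- nchar(primer)
    found <- logical(length(reads))
    out <- reads
    for (i in seq_along(reads)) {
      site <- find_primer_site(substr(reads[i], 1L, k), primer,
                               primers$max_error_rate)
      if (!is.null(site) && site$start == 0L) {
        found[i] <- TRUE
        out[i] <- substr(reads[i], k + 1L, nchar(reads[i]))
      }
    }
    list(reads = out, found = found, clipped = ifelse(found, k, 0L))
  }
  c1 <- clip_one(toupper(r1), primers$forward_seq)
  c2 <- clip_one(toupper(r2), primers$reverse_seq)
  kept <- if (policy == "drop") c1$found & c2$found else rep(TRUE, length(r1))
  flags <- data.frame(id = if (is.null(names(r1))) as.character(seq_along(r1)) else names(r1),
                      primer_r1 = c1$found, primer_r2 = c2$found, kept = kept,
                      stringsAsFactors = FALSE)
  out <- list(
    r1 = c1$reads[kept], r2 = c2$reads[kept], flags = flags,
    log = c(n_pairs = length(r1),
            n_primer_r1 = sum(c1$found), n_primer_r2 = sum(c2$found),
            n_dropped = sum(!kept))
  )
  if (!is.null(q1)) out$q1 <- substr(q1, c1$clipped + 1L, nchar(q1))[kept]
  if (!is.null(q2)) out$q2 <- substr(q2, c2$clipped + 1L, nchar(q2))[kept]
  out
}
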