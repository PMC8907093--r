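# End-to-end orchestration: primer clipping -> truncate/filter/merge ->
# homology screen -> OTU/ASV features -> split alignment -> parsimony
# placement -> clade extraction, with a machine-readable run manifest.

#' Per-position read quality profile
#'
#' Summarises phred quality by cycle position, the basis for choosing the
#' R1/R2 truncation lengths.
#'
#' @param fastq path to a FASTQ file (phred+33).
#' @param side label recorded in the output (e.g. `"R1"`).
#' @return data.frame: side, position, n, mean, q25, median, q75.
#' @export
quality_profile <- function(fastq, side = "R1") {
  fq <- read_fastq(fastq)
  if (length(fq$qual) == 0) {
    return(data.frame(side = character(0), position = integer(0),
                      n = integer(0), mean = numeric(0), q25 = numeric(0),
                      median = numeric(0), q75 = numeric(0)))
  }
  scores <- lapply(fq$qual, function(q) utf8ToInt(q) - 33L)
  maxlen <- max(lengths(scores))
  do.call(rbind, lapply(seq_len(maxlen), function(pos) {
    v <- unlist(lapply(scores, function(s) if (length(s) >= pos) s[pos] else NULL))
    data.frame(side = side, position = pos, n = length(v), mean = mean(v),
               q25 = unname(quantile(v, 0.25)), median = median(v),
               q75 = unname(quantile(v, 0.75)), stringsAsFactors = FALSE)
  }))
}

#' Pipeline configuration
#'
#' Collects every knob of a full run. Either `reads_r1`/`reads_r2` (FASTQ
#' paths or named character vectors) or a pre-denoised `features`
#' ([feature_table()]) must be supplied.
#'
#' @param reference_fasta,family_map,tree_newick reference inputs (paths or
#'   in-memory equivalents: named character vector, data.frame, `phylo`).
#' @param reads_r1,reads_r2 paired study reads.
#' @param features pre-denoised ASV [feature_table()] (alternative to reads).
#' @param primers a [primer_pair()].
#' @param r1_len,r2_len read truncation / reference cut lengths.
#' @param scoring a [scoring_scheme()].
#' @param min_score homology-screen retention threshold.
#' @param mode `"otu"` or `"asv"`.
#' @param otu_identity OTU clustering identity threshold.
#' @param batch_size placement batch size.
#' @param include_stem count stem-edge attachments as inside clades.
#' @param outgroup_tip tip used to root the backbone; defaults to the first
#'   outgroup-labelled reference in the family map.
#' @param outgroup_labels see [build_reference_db()].
#' @param trim_policy `"keep"` or `"drop"` for primer-less read pairs.
#' @param out_dir optional output directory for artifact files.
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_fasta, family_map, tree_newick,
                            reads_r1 = NULL, reads_r2 = NULL, features = NULL,
                            primers = default_primer_pair(),
                            r1_len = 150, r2_len = 150,
                            scoring = scoring_scheme(), min_score = 40,
                            mode = c("asv", "otu"), otu_identity = 0.97,
                            batch_size = 500, include_stem = FALSE,
                            outgroup_tip = NULL, outgroup_labels = NULL,
                            trim_policy = c("drop", "keep"),
                            out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  trim_policy <- match.arg(trim_policy)
  if (is.null(features) && (is.null(reads_r1) || is.null(reads_r2)))
    stop("supply either reads_r1/reads_r2 or features", call. = FALSE)
  structure(list(reference_fasta = reference_fasta, family_map = family_map,
                 tree_newick = tree_newick, reads_r1 = reads_r1,
                 reads_r2 = reads_r2, features = features, primers = primers,
                 r1_len = as.integer(r1_len), r2_len = as.integer(r2_len),
                 scoring = scoring, min_score = min_score, mode = mode,
                 otu_identity = otu_identity, batch_size = batch_size,
                 include_stem = include_stem, outgroup_tip = outgroup_tip,
                 outgroup_labels = outgroup_labels, trim_policy = trim_policy,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `primers`
#' and `scoring` may be given as nested mappings.
#'
#' @param path YAML path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  primers <- if (is.null(y$primers)) default_primer_pair() else
    do.call(primer_pair, y$primers)
  scoring <- if (is.null(y$scoring)) scoring_scheme() else
    do.call(scoring_scheme, y$scoring)
  args <- y[setdiff(names(y), c("primers", "scoring"))]
  do.call(pipeline_config, c(args, list(primers = primers, scoring = scoring)))
}

#' Run the full placement pipeline
#'
#' Stages run in fixed order: primer clipping, truncate/filter/merge,
#' dereplication, homology screen, OTU clustering or ASV passthrough, split
#' R1/R2 alignment, parsimony placement, clade classification and extraction.
#' Each feature ends up in exactly one terminal bucket (a family,
#' unclassified-AMF, non-AMF, screened-out, or unplaceable) and the manifest
#' records the feature count surviving each stage.
#'
#' @param config a [pipeline_config()].
#' @return list with `db`, `table` (final [feature_table()]), `screen`,
#'   `placements`, `assignments`, `extracts`, `summary`
#'   ([summarize_fractions()]), `manifest` (list), `model`
#'   ([clade_model()]). When `config$out_dir` is set, artifacts and
#'   `manifest.json` are written there.
#' @export
pipeline_run <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(parameters = list(
    r1_len = config$r1_len, r2_len = config$r2_len,
    min_score = config$min_score, mode = config$mode,
    otu_identity = config$otu_identity, batch_size = config$batch_size,
    include_stem = config$include_stem, trim_policy = config$trim_policy,
    seed = config$seed,
    primers = unclass(config$primers), scoring = unclass(config$scoring)))
  counts <- list()

  db <- build_reference_db(config$reference_fasta, config$family_map,
                           primers = config$primers,
                           outgroup_labels = config$outgroup_labels)
  counts$references <- nrow(db$records)

  if (!is.null(config$features)) {
    ft <- config$features
  } else {
    r1 <- config$reads_r1; r2 <- config$reads_r2
    if (is.character(r1) && length(r1) == 1 && file.exists(r1)) {
      fq1 <- read_fastq(r1); fq2 <- read_fastq(config$reads_r2)
      r1 <- fq1$seq; r2 <- fq2$seq
    }
    trimmed <- trim_read_pair(r1, r2, config$primers,
                              policy = config$trim_policy)
    counts$read_pairs_in <- length(r1)
    counts$read_pairs_primer_trimmed <- length(trimmed$r1)
    merged <- merge_read_pairs(trimmed$r1, trimmed$r2,
                               config$r1_len, config$r2_len)
    counts$read_pairs_merged <- unname(merged$log["n_merged"])
    # single-sample unless read ids encode a sample as "<sample>:<read>"
    samples <- sub("^([^:]+):.+$", "\\1", names(merged$seq))
    samples[samples == names(merged$seq)] <- "sample1"
    ft <- dereplicate(merged$seq, samples)
  }
  counts$features_in <- nrow(ft$counts)
  counts$reads_in <- sum(ft$counts)

  scr <- screen_queries(ft$rep_seqs, db, config$scoring, config$min_score)
  ft_scr <- ft_subset(ft, scr$retained)
  counts$features_screened <- nrow(ft_scr$counts)

  if (config$mode == "otu") {
    cl <- cluster_otus(ft_scr, config$otu_identity, config$scoring)
    ft_final <- cl$table
  } else {
    cl <- NULL
    ft_final <- asv_passthrough(ft_scr)
  }
  counts$features_final <- nrow(ft_final$counts)

  tree <- if (inherits(config$tree_newick, "phylo")) config$tree_newick
          else ape::read.tree(config$tree_newick)
  outgroup <- config$outgroup_tip
  if (is.null(outgroup)) {
    og <- db$records$id[db$records$is_outgroup]
    if (length(og) == 0) stop("no outgroup reference to root on", call. = FALSE)
    outgroup <- og[1]
  }
  tree <- root_tree(tree, outgroup)

  cuts <- cut_reference_to_read_lengths(db, config$r1_len, config$r2_len)
  ref_r1 <- build_reference_alignment(cuts$r1, config$scoring)
  ref_r2 <- build_reference_alignment(cuts$r2, config$scoring)
  split <- split_alignment(ref_r1, ref_r2)
  q_seq <- ft_final$rep_seqs
  q_r1 <- substr(q_seq, 1L, config$r1_len)
  q_r2 <- revcomp(substr(q_seq, nchar(q_seq) - config$r2_len + 1L,
                         nchar(q_seq)))
  names(q_r1) <- names(q_r2) <- names(q_seq)
  split <- add_queries(split, q_r1, q_r2, config$scoring)
  concat <- concatenate_blocks(split)
  ref_rows <- concat[attr(concat, "is_ref")]
  query_rows <- concat[!attr(concat, "is_ref")]

  placements <- place_batch(query_rows, tree, ref_rows,
                            batch_size = config$batch_size)
  counts$features_placed <- sum(!placements$unplaceable)

  model <- clade_model(tree, db$records[, c("id", "group_label")],
                       outgroup_labels = config$outgroup_labels)
  assignments <- classify_placement(placements[!placements$unplaceable, ,
                                               drop = FALSE],
                                    model, include_stem = config$include_stem)
  extracts <- extract_tables(ft_final, assignments,
                             family_names = model$family_names)
  counts$features_amf <- nrow(extracts$amf$counts)
  summary <- summarize_fractions(assignments, ft_final)
  manifest$feature_counts <- counts

  res <- list(db = db, table = ft_final, screen = scr$results,
              placements = placements, assignments = assignments,
              extracts = extracts, summary = summary, model = model,
              manifest = manifest, tree = model$tree, clusters = cl)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reference_db(db, file.path(config$out_dir, "refdb"))
    write_tsv(scr$results, file.path(config$out_dir, "screen_report.tsv"))
    if (nrow(ft_final$counts) > 0)
      write_feature_table(ft_final, file.path(config$out_dir, "features.tsv"),
                          file.path(config$out_dir, "features.fasta"))
    write_fasta(concat, file.path(config$out_dir, "aligned_concat.fasta"))
    write_jplace(placements, tree,
                 file.path(config$out_dir, "placements.jplace"))
    write_extracts(extracts, assignments,
                   file.path(config$out_dir, "extracts"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
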