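# Synthetic fixtures: a clade-structured reference tree with labelled family
# clades and outgroups, reference sequences evolved along it, amplicon read
# pairs derived from chosen tips, and non-homologous junk reads. Everything
# is deterministic under the configured seed.

.GLOM_FAMILIES <- c(
  "Acaulosporaceae", "Ambisporaceae", "Archaeosporaceae",
  "Claroideoglomeraceae", "Diversisporaceae", "Gigasporaceae",
  "Glomeraceae", "Pacisporaceae", "Paraglomeraceae",
  "Pervetustaceae", "Sacculosporaceae"
)

#' Simulation configuration
#'
#' Defaults describe the standard study design exercised by the package's
#' own validation: 60 AMF reference tips spread over the 11 described
#' Glomeromycota families, 20 outgroup tips, a 600 bp primer-bounded region,
#' 150 bp forward and reverse reads, 100 queries at 2% divergence from their
#' origin tips, and 15 uniform-random junk reads.
#'
#' @param n_amf_tips AMF reference tips (>= 2 per family).
#' @param n_families number of family clades; 11 uses the described
#'   Glomeromycota family names.
#' @param n_outgroup_tips non-AMF reference tips.
#' @param region_length curated region length in bp.
#' @param substitution_rate substitutions per site per unit branch length,
#'   in `[0, 0.75)`.
#' @param r1_len,r2_len read lengths in bp.
#' @param query_divergence per-site substitution probability applied to a
#'   tip sequence to derive a query, in `[0, 0.75)`.
#' @param n_queries number of query read pairs.
#' @param n_junk_reads number of uniform-random non-homologous read pairs.
#' @param seed mandatory integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_amf_tips = 60, n_families = 11, n_outgroup_tips = 20,
                       region_length = 600, substitution_rate = 0.5,
                       r1_len = 150, r2_len = 150, query_divergence = 0.02,
                       n_queries = 100, n_junk_reads = 15, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(n_amf_tips = n_amf_tips, n_families = n_families,
              n_outgroup_tips = n_outgroup_tips,
              region_length = region_length,
              substitution_rate = substitution_rate,
              r1_len = r1_len, r2_len = r2_len,
              query_divergence = query_divergence,
              n_queries = n_queries, n_junk_reads = n_junk_reads,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_amf_tips", "n_families", "n_outgroup_tips",
                         "region_length", "r1_len", "r2_len", "n_queries",
                         "n_junk_reads")])
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  for (r in c(substitution_rate, query_divergence)) {
    if (r < 0 || r >= 0.75)
      stop("rates must be in [0, 0.75)", call. = FALSE)
  }
  if (n_families < 1 || n_outgroup_tips < 2)
    stop("need at least 1 family and 2 outgroup tips", call. = FALSE)
  if (n_families > floor(n_amf_tips / 2))
    stop("n_families exceeds the available disjoint clades (need >= 2 AMF tips per family)",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a random rooted binary tree
#'
#' Topology from `ape::rtree`; branch lengths are exponential with the given
#' mean. Reproducible under the seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param mean_branch mean branch length.
#' @return a rooted binary `phylo`.
#' @export
simulate_tree <- function(n_tips, seed, mean_branch = 0.1) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  set.seed(seed)
  ape::rtree(n_tips, rooted = TRUE,
             br = function(n) rexp(n, rate = 1 / mean_branch))
}

#' @keywords internal
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each site independently with probability p (to a uniformly
# chosen different base)
.mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < p
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

#' Evolve sequences along a tree by per-branch substitution
#'
#' Each branch substitutes every site independently with probability
#' `min(rate * branch_length, 0.75)`; a substituted site changes to a
#' uniformly chosen different base (Jukes-Cantor-style symmetric model, no
#' indels).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param root_seq the ancestral sequence over `{A,C,G,T}`.
#' @param rate substitutions per site per unit branch length.
#' @param seed integer seed.
#' @return named character vector of tip sequences.
#' @export
evolve_sequences <- function(tree, root_seq, rate, seed) {
  if (grepl("[^ACGT]", root_seq))
    stop("root_seq must be over {A,C,G,T}", call. = FALSE)
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  seqs <- vector("character", max(tree$edge))
  seqs[n_tip + 1L] <- root_seq
  for (k in seq_len(nrow(tree$edge))) {
    p <- min(rate * tree$edge.length[k], 0.75)
    seqs[tree$edge[k, 2]] <- .mutate_seq(seqs[tree$edge[k, 1]], p)
  }
  setNames(seqs[seq_len(n_tip)], tree$tip.label)
}

# Compose the backbone: an outgroup subtree and an AMF subtree whose family
# clades are grafted onto a family backbone, guaranteeing that every family
# is a clean clade inside the AMF clade. Grafting is done on Newick text (a
# stub tip is textually replaced by its family subtree), which keeps the
# composition correct for any subtree size.
.compose_tree <- function(cfg) {
  fam_sizes <- rep(2L, cfg$n_families)
  extra <- cfg$n_amf_tips - sum(fam_sizes)
  if (extra > 0) {
    add <- table(sample(seq_len(cfg$n_families), extra, replace = TRUE))
    fam_sizes[as.integer(names(add))] <- fam_sizes[as.integer(names(add))] +
      as.integer(add)
  }
  fam_names <- if (cfg$n_families == 11) .GLOM_FAMILIES
               else sprintf("Family_%02d", seq_len(cfg$n_families))
  strip <- function(tr) sub(";$", "", ape::write.tree(tr))
  rand_subtree <- function(n, br) {
    if (n == 1) return(NULL) # caller handles single-tip case
    ape::rtree(n, rooted = TRUE, br = br)
  }
  # family subtrees: short internal branches with a minimum length so that
  # sibling references stay distinguishable on the cut region
  fam_core <- character(cfg$n_families)
  tip_family <- character(0)
  for (i in seq_len(cfg$n_families)) {
    labels <- sprintf("AMF_%s%02d_%02d", substr(fam_names[i], 1, 4), i,
                      seq_len(fam_sizes[i]))
    sub <- rand_subtree(fam_sizes[i],
                        br = function(n) 0.02 + rexp(n, rate = 1 / 0.06))
    sub$tip.label <- labels
    fam_core[i] <- strip(sub)
    tip_family <- c(tip_family, setNames(rep(fam_names[i], fam_sizes[i]),
                                         labels))
  }
  # family backbone: internal branches clearly longer than within-family ones
  # so families are well separated without saturating the alignable signal
  if (cfg$n_families >= 2) {
    backbone <- ape::rtree(cfg$n_families, rooted = TRUE,
                           br = function(n) 0.08 + rexp(n, rate = 1 / 0.05))
    backbone$tip.label <- paste0("STUB_", seq_len(cfg$n_families))
    amf_core <- strip(backbone)
    for (i in seq_len(cfg$n_families)) {
      # stub branch length becomes the family stem; the colon anchors the
      # pattern so STUB_1 cannot match STUB_10
      amf_core <- sub(paste0("STUB_", i, ":"),
                      paste0(fam_core[i], ":"), amf_core, fixed = TRUE)
    }
  } else {
    amf_core <- fam_core[1]
  }
  og <- ape::rtree(cfg$n_outgroup_tips, rooted = TRUE,
                   br = function(n) 0.04 + rexp(n, rate = 1 / 0.08))
  og$tip.label <- sprintf("OUT_%02d", seq_len(cfg$n_outgroup_tips))
  nwk <- paste0("(", amf_core, ":0.25,", strip(og), ":0.25);")
  full <- ape::reorder.phylo(ape::read.tree(text = nwk), "cladewise")
  list(tree = full, tip_family = tip_family, fam_names = fam_names)
}

#' Generate a complete synthetic fixture
#'
#' Produces a reference set (raw sequences carrying the primer pair around an
#' evolved region), its family map and backbone tree, query read pairs
#' derived from randomly chosen tips by further substitution, junk read pairs
#' of i.i.d. uniform bases, and a truth table.
#'
#' @param cfg a [sim_config()].
#' @param primers a [primer_pair()] embedded around the reference regions and
#'   at the 5' ends of reads.
#' @param dir optional output directory; when given, writes
#'   `references.fasta`, `family_map.tsv`, `backbone.nwk`, `reads_R1.fastq`,
#'   `reads_R2.fastq`, `truth.tsv`.
#' @return list with `tree` (rooted `phylo`), `ref_raw`, `ref_regions`
#'   (named character vectors), `family_map` (data.frame), `reads` (list
#'   `r1`, `r2`, `q1`, `q2`), `truth` (data.frame: query_id, origin_tip,
#'   group_label, is_amf), `outgroup_tip` (designated rooting tip), `config`.
#' @export
make_fixture <- function(cfg, primers = default_primer_pair(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  comp <- .compose_tree(cfg)
  tree <- comp$tree
  root_seq <- random_seq(cfg$region_length)
  regions <- evolve_sequences(tree, root_seq, cfg$substitution_rate,
                              seed = cfg$seed + 1L)
  set.seed(cfg$seed + 2L)
  ref_raw <- setNames(paste0(primers$forward_seq, regions,
                             revcomp(primers$reverse_seq)), names(regions))
  fam_of <- comp$tip_family
  family_map <- data.frame(
    id = names(regions),
    group_label = ifelse(names(regions) %in% names(fam_of),
                         fam_of[names(regions)], "outgroup"),
    taxon = ifelse(names(regions) %in% names(fam_of),
                   paste0(fam_of[names(regions)], " sp."), "non-AMF fungus"),
    accession = sprintf("SYN%05d", seq_along(regions)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  # queries: evolve a randomly chosen tip further, cut read fragments
  tips <- names(regions)
  origin <- if (cfg$n_queries > 0) sample(tips, cfg$n_queries, replace = TRUE)
            else character(0)
  q_ids <- sprintf("Q_%04d", seq_len(cfg$n_queries))
  r1 <- r2 <- character(cfg$n_queries)
  for (i in seq_len(cfg$n_queries)) {
    mut <- .mutate_seq(regions[[origin[i]]], cfg$query_divergence)
    L <- nchar(mut)
    r1[i] <- paste0(primers$forward_seq, substr(mut, 1L, cfg$r1_len))
    r2[i] <- paste0(primers$reverse_seq,
                    revcomp(substr(mut, L - cfg$r2_len + 1L, L)))
  }
  names(r1) <- names(r2) <- q_ids
  junk_ids <- if (cfg$n_junk_reads > 0)
    sprintf("JUNK_%04d", seq_len(cfg$n_junk_reads)) else character(0)
  j1 <- setNames(vapply(seq_len(cfg$n_junk_reads), function(i)
    random_seq(cfg$r1_len + nchar(primers$forward_seq)), character(1)), junk_ids)
  j2 <- setNames(vapply(seq_len(cfg$n_junk_reads), function(i)
    random_seq(cfg$r2_len + nchar(primers$reverse_seq)), character(1)), junk_ids)
  all_r1 <- c(r1, j1); all_r2 <- c(r2, j2)
  q1 <- setNames(strrep("F", nchar(all_r1)), names(all_r1)) # constant Q37
  q2 <- setNames(strrep("F", nchar(all_r2)), names(all_r2))

  truth <- data.frame(
    query_id = c(q_ids, junk_ids),
    origin_tip = c(origin, rep(NA_character_, cfg$n_junk_reads)),
    group_label = c(ifelse(origin %in% names(fam_of), fam_of[origin],
                           "outgroup"),
                    rep("junk", cfg$n_junk_reads)),
    is_amf = c(origin %in% names(fam_of), rep(FALSE, cfg$n_junk_reads)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- list(tree = tree, ref_raw = ref_raw, ref_regions = regions,
              family_map = family_map,
              reads = list(r1 = all_r1, r2 = all_r2, q1 = q1, q2 = q2),
              truth = truth, outgroup_tip = "OUT_01", config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(ref_raw, file.path(dir, "references.fasta"))
    write_tsv(family_map, file.path(dir, "family_map.tsv"))
    ape::write.tree(tree, file.path(dir, "backbone.nwk"))
    write_fastq(all_r1, q1, file.path(dir, "reads_R1.fastq"))
    write_fastq(all_r2, q2, file.path(dir, "reads_R2.fastq"))
    write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  out
}
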