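# Independent oracles used across the suite. These deliberately share no code
# with the package internals: the parsimony oracle is a plain recursive Fitch
# on explicitly augmented ape trees, the alignment oracle is a naive
# full-matrix DP in R, and the clade oracle tests tip-subset containment edge
# by edge.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- parsimony -------------------------------------------------------------

# Fitch/Hartigan small-parsimony total, recursive, one column at a time.
r_fitch_score <- function(tree, rows) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  enc <- function(s) {
    b <- bits[strsplit(s, "", fixed = TRUE)[[1]]]
    b[is.na(b)] <- 15L
    unname(b)
  }
  st <- lapply(rows[tree$tip.label], enc)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  total <- 0L
  down <- function(node, col) {
    if (node <= n_tip) return(st[[node]][col])
    sets <- vapply(kids[[as.character(node)]], down, integer(1), col = col)
    cnt <- vapply(0:3, function(b) sum(bitwAnd(sets, bitwShiftL(1L, b)) > 0L),
                  integer(1))
    k <- max(cnt)
    total <<- total + length(sets) - k
    Reduce(bitwOr, bitwShiftL(1L, which(cnt == k) - 1L))
  }
  for (col in seq_along(st[[1]])) down(n_tip + 1L, col)
  total
}

# Attachment score for every candidate edge by explicitly grafting a new tip
# with ape::bind.tree and rescoring the whole augmented tree. Index 1 is the
# root attachment, index e+1 is edge e in tree_edges() numbering.
oracle_attachment_scores <- function(tree, rows, qrow, qid = "ORACLE_Q") {
  tree <- tree_edges(tree)$tree
  tip1 <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = qid,
                         Nnode = 1L, edge.length = 0), class = "phylo")
  all_rows <- c(rows, setNames(qrow, qid))
  scores <- integer(nrow(tree$edge) + 1L)
  tr0 <- ape::bind.tree(tree, tip1, where = length(tree$tip.label) + 1L,
                        position = 0)
  scores[1] <- r_fitch_score(tr0, all_rows)
  for (e in seq_len(nrow(tree$edge))) {
    pos <- if (is.null(tree$edge.length)) 0 else tree$edge.length[e] / 2
    tr <- ape::bind.tree(tree, tip1, where = tree$edge[e, 2], position = pos)
    scores[e + 1] <- r_fitch_score(tr, all_rows)
  }
  scores
}

# --- alignment -------------------------------------------------------------

# Naive full-matrix affine Smith-Waterman in R; N scores 0 against anything.
# Gap of length L costs |open| + L * |extend|.
r_sw_score <- function(a, b, match = 1, mismatch = -2, gap_open = -5,
                       gap_extend = -2) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(x); n <- length(y)
  go <- gap_open + gap_extend; ge <- gap_extend
  sub <- function(p, q) {
    if (p == "N" || q == "N") 0 else if (p == q) match else mismatch
  }
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + ge)
      F[i, j] <- max(H[i - 1, j] + go, F[i - 1, j] + ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub(x[i - 1], y[j - 1]),
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# --- clades ----------------------------------------------------------------

# Member edges of the clade defined by `tips`, by brute force: an edge
# belongs to the clade iff the tip set below it is contained in the MRCA's
# tip set and the edge is not the stem (child == MRCA).
brute_clade_edges <- function(tree, tips) {
  te <- tree_edges(tree)
  tree <- te$tree
  n_tip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_below))
  }
  mrca <- ape::getMRCA(tree, tips)
  clade_tips <- tips_below(mrca)
  keep <- vapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    all(tips_below(child) %in% clade_tips) && child != mrca
  }, logical(1))
  te$edges$edge_id[keep]
}

# --- fixtures --------------------------------------------------------------

small_fixture <- function(seed = 42, ...) {
  cfg <- sim_config(n_amf_tips = 16, n_families = 4, n_outgroup_tips = 6,
                    region_length = 300, r1_len = 80, r2_len = 80,
                    n_queries = 24, n_junk_reads = 4, seed = seed, ...)
  make_fixture(cfg)
}

# strip the primers off fixture reads (fragment payloads)
fixture_fragments <- function(fx, primers = default_primer_pair()) {
  p1 <- nchar(primers$forward_seq); p2 <- nchar(primers$reverse_seq)
  r1 <- substr(fx$reads$r1, p1 + 1L, nchar(fx$reads$r1))
  r2 <- substr(fx$reads$r2, p2 + 1L, nchar(fx$reads$r2))
  names(r1) <- names(r2) <- names(fx$reads$r1)
  list(r1 = r1, r2 = r2)
}
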