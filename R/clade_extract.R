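# Clade extraction: the Glomeromycota (AMF) clade and the family clades are
# delimited by the MRCA of their defining reference tips; a placement is
# inside a clade iff its attachment edge lies strictly within the MRCA's
# subtree. Attachments on a clade's stem edge count as outside by default
# (conservative: a sequence sister to the phylum is not claimed as AMF).

#' Root a tree on an outgroup tip
#'
#' Places the root on the outgroup's pendant edge; the topology is otherwise
#' unchanged. Re-rooting an already correctly rooted tree is a no-op.
#'
#' @param tree a `phylo`.
#' @param outgroup_tip tip label of the outgroup.
#' @return a rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup_tip) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup_tip %in% tree$tip.label)
    stop("outgroup tip not in tree: ", outgroup_tip, call. = FALSE)
  if (ape::is.rooted(tree)) {
    root <- length(tree$tip.label) + 1L
    kids <- tree$edge[tree$edge[, 1] == root, 2]
    og <- match(outgroup_tip, tree$tip.label)
    if (og %in% kids) return(ape::reorder.phylo(tree, "cladewise"))
  }
  tr <- ape::root(tree, outgroup = outgroup_tip, resolve.root = TRUE)
  ape::reorder.phylo(tr, "cladewise")
}

#' Delimit a named clade from defining reference tips
#'
#' The clade is the subtree of the MRCA of the defining tips; its member
#' edges are all edges strictly within that subtree (the stem edge subtending
#' the MRCA is excluded).
#'
#' @param tree a rooted `phylo`.
#' @param defining_tips at least two tip labels present in the tree.
#' @param name clade name.
#' @return list with `name`, `mrca` (node id in the canonical tree),
#'   `defining_tips`, `tips` (all tips of the subtree), `edges` (member edge
#'   ids per [tree_edges()]), `stem_edge` (edge id or `NA` for the root).
#' @export
define_clade <- function(tree, defining_tips, name) {
  te <- tree_edges(tree)
  tree <- te$tree
  if (length(defining_tips) < 2)
    stop("a clade needs at least 2 defining tips", call. = FALSE)
  unknown <- setdiff(defining_tips, tree$tip.label)
  if (length(unknown) > 0)
    stop("defining tip(s) not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  mrca <- ape::getMRCA(tree, defining_tips)
  sub_nodes <- .subtree_nodes(tree, mrca)
  member <- te$edges$edge_id[te$edges$parent %in% sub_nodes]
  stem <- te$edges$edge_id[te$edges$child == mrca]
  tips <- .clade_tips(tree, mrca)
  list(name = name, mrca = mrca, defining_tips = defining_tips,
       tips = tips, edges = member,
       stem_edge = if (length(stem) == 1) stem else NA_integer_)
}

# all nodes (internal and tips) in the subtree rooted at `node`
.subtree_nodes <- function(tree, node) {
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, u)
    ch <- kids[[as.character(u)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  out
}

#' Build the clade model: AMF clade plus family clades
#'
#' The AMF (Glomeromycota) clade is delimited by all reference tips carrying
#' a family label; each family clade is delimited by its own tips. Families
#' with a single reference tip are represented by that tip's pendant edge.
#'
#' @param tree the rooted backbone `phylo` (root it with [root_tree()]
#'   first).
#' @param family_map data.frame with `id` and `group_label` columns (see
#'   [read_family_map()]); ids must be tree tips.
#' @param outgroup_labels as in [build_reference_db()]: `NULL` treats labels
#'   starting with "outgroup" (case-insensitive) as outgroups.
#' @param amf_clade_name name for the phylum-level clade.
#' @return an object of class `clade_model`: list with `tree` (canonical),
#'   `edges`, `amf` (clade entry), `families` (named list of clade entries),
#'   `family_names`.
#' @export
clade_model <- function(tree, family_map, outgroup_labels = NULL,
                        amf_clade_name = "Glomeromycota") {
  fmap <- if (is.data.frame(family_map)) family_map else read_family_map(family_map)
  te <- tree_edges(tree)
  tree <- te$tree
  fmap <- fmap[fmap$id %in% tree$tip.label, , drop = FALSE]
  is_out <- if (is.null(outgroup_labels)) {
    grepl("^outgroup", fmap$group_label, ignore.case = TRUE)
  } else {
    fmap$group_label %in% outgroup_labels
  }
  amf_tips <- fmap$id[!is_out]
  if (length(amf_tips) < 2)
    stop("need at least 2 AMF reference tips", call. = FALSE)
  amf <- define_clade(tree, amf_tips, amf_clade_name)
  fam_names <- sort(unique(fmap$group_label[!is_out]))
  families <- lapply(fam_names, function(fn) {
    tips <- fmap$id[fmap$group_label == fn]
    if (length(tips) >= 2) {
      cl <- define_clade(tree, tips, fn)
    } else {
      eid <- te$edges$edge_id[!is.na(te$edges$tip_label) &
                                te$edges$tip_label == tips]
      cl <- list(name = fn, mrca = match(tips, tree$tip.label),
                 defining_tips = tips, tips = tips, edges = eid,
                 stem_edge = NA_integer_)
    }
    outside <- setdiff(cl$tips, amf$tips)
    if (length(outside) > 0)
      stop(sprintf("family %s spans tips outside the AMF clade: %s", fn,
                   paste(outside, collapse = ", ")), call. = FALSE)
    cl
  })
  names(families) <- fam_names
  structure(list(tree = tree, edges = te$edges, amf = amf,
                 families = families, family_names = fam_names),
            class = "clade_model")
}

#' @export
print.clade_model <- function(x, ...) {
  cat(sprintf("clade_model: %s with %d tips; %d family clades\n",
              x$amf$name, length(x$amf$tips), length(x$families)))
  invisible(x)
}

#' Classify placements into AMF / family clades
#'
#' A placement is AMF iff its attachment edge is a member edge of the AMF
#' clade; within AMF, the family is the smallest named family clade whose
#' member edges contain the attachment edge, or `"Glomeromycota_unclassified"`
#' when no family clade contains it. Unplaceable queries are non-AMF.
#'
#' @param placements data.frame from [place_batch()].
#' @param model a [clade_model()].
#' @param include_stem also count attachments on a clade's stem edge as
#'   inside it (sensitivity analysis; default `FALSE`).
#' @return data.frame with query_id, is_amf, family (`NA` outside AMF).
#' @export
classify_placement <- function(placements, model, include_stem = FALSE) {
  stopifnot(inherits(model, "clade_model"))
  edge_set <- function(cl) {
    if (include_stem && !is.na(cl$stem_edge)) c(cl$edges, cl$stem_edge)
    else cl$edges
  }
  amf_edges <- edge_set(model$amf)
  valid <- c(0L, model$edges$edge_id)
  fam_sizes <- vapply(model$families, function(cl) length(cl$edges), integer(1))
  fam_order <- names(sort(fam_sizes)) # smallest enclosing clade wins
  out <- data.frame(query_id = placements$query_id,
                    is_amf = FALSE, family = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(placements))) {
    if (isTRUE(placements$unplaceable[i])) next
    e <- placements$best_edge[i]
    if (!e %in% valid) stop("unknown edge id: ", e, call. = FALSE)
    if (!e %in% amf_edges) next
    out$is_amf[i] <- TRUE
    fam <- NA_character_
    for (fn in fam_order) {
      if (e %in% edge_set(model$families[[fn]])) { fam <- fn; break }
    }
    out$family[i] <- if (is.na(fam)) "Glomeromycota_unclassified" else fam
  }
  out
}

#' Split a feature table by clade assignment
#'
#' @param ft a [feature_table()] covering the classified features.
#' @param assignments data.frame from [classify_placement()]; features of
#'   `ft` absent from it (e.g. screened out or unplaceable) land in the
#'   `discarded` bucket.
#' @param family_names family names that must appear in the output even when
#'   empty (e.g. `model$family_names`); defaults to the families observed in
#'   `assignments`.
#' @return list with `amf` (feature_table), `families` (named list of
#'   feature_tables, one per family plus `Glomeromycota_unclassified` if
#'   any), `non_amf`, `discarded`.
#' @export
extract_tables <- function(ft, assignments, family_names = NULL) {
  ids <- rownames(ft$counts)
  amf_ids <- assignments$query_id[assignments$is_amf]
  non_amf_ids <- assignments$query_id[!assignments$is_amf]
  discarded_ids <- setdiff(ids, assignments$query_id)
  fams <- unique(c(family_names,
                   assignments$family[assignments$is_amf]))
  fams <- fams[!is.na(fams)]
  fam_tables <- lapply(fams, function(fn) {
    ft_subset(ft, assignments$query_id[!is.na(assignments$family) &
                                         assignments$family == fn])
  })
  names(fam_tables) <- fams
  list(amf = ft_subset(ft, amf_ids),
       families = fam_tables,
       non_amf = ft_subset(ft, intersect(non_amf_ids, ids)),
       discarded = ft_subset(ft, discarded_ids))
}

#' Write extracted tables to a directory
#'
#' Emits `amf.{tsv,fasta}`, `family_<name>.{tsv,fasta}`,
#' `unclassified_amf.*`, `non_amf.*`, `discarded.*` and a `clade_summary.tsv`
#' ([summarize_fractions()]). Empty tables produce valid header-only files.
#'
#' @param extracts output of [extract_tables()].
#' @param assignments the assignments used.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_extracts <- function(extracts, assignments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(ft, stem) {
    tsv <- file.path(dir, paste0(stem, ".tsv"))
    fa <- file.path(dir, paste0(stem, ".fasta"))
    df <- data.frame(feature_id = rownames(ft$counts), ft$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, tsv)
    write_fasta(ft$rep_seqs, fa)
  }
  emit(extracts$amf, "amf")
  for (fn in names(extracts$families)) {
    stem <- if (fn == "Glomeromycota_unclassified") "unclassified_amf"
            else paste0("family_", gsub("[^A-Za-z0-9_]+", "_", fn))
    emit(extracts$families[[fn]], stem)
  }
  emit(extracts$non_amf, "non_amf")
  emit(extracts$discarded, "discarded")
  write_tsv(summarize_fractions(assignments, .recombine(extracts)),
            file.path(dir, "clade_summary.tsv"))
  invisible(dir)
}

.recombine <- function(extracts) {
  counts <- rbind(extracts$amf$counts, extracts$non_amf$counts,
                  extracts$discarded$counts)
  feature_table(counts, c(extracts$amf$rep_seqs, extracts$non_amf$rep_seqs,
                          extracts$discarded$rep_seqs))
}

#' Per-clade fractions of AMF features and reads
#'
#' For every family (plus the unclassified bucket) reports the percentage of
#' AMF-assigned features and of AMF-assigned reads (summed counts) placed in
#' it.
#'
#' @param assignments data.frame from [classify_placement()].
#' @param ft the [feature_table()] the assignments refer to.
#' @return data.frame: clade, n_features, pct_features, n_reads, pct_reads.
#' @export
summarize_fractions <- function(assignments, ft) {
  amf <- assignments[assignments$is_amf & assignments$query_id %in%
                       rownames(ft$counts), , drop = FALSE]
  if (nrow(amf) == 0) {
    return(data.frame(clade = character(0), n_features = integer(0),
                      pct_features = numeric(0), n_reads = numeric(0),
                      pct_reads = numeric(0)))
  }
  reads <- rowSums(ft$counts)[amf$query_id]
  tot_feat <- nrow(amf); tot_reads <- sum(reads)
  by_fam <- split(seq_len(nrow(amf)), amf$family)
  df <- do.call(rbind, lapply(names(by_fam), function(fn) {
    ii <- by_fam[[fn]]
    data.frame(clade = fn, n_features = length(ii),
               pct_features = 100 * length(ii) / tot_feat,
               n_reads = sum(reads[ii]),
               pct_reads = 100 * sum(reads[ii]) / tot_reads,
               stringsAsFactors = FALSE)
  }))
  df[order(df$clade), , drop = FALSE]
}
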