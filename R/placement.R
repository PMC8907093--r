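# Parsimony placement of aligned queries into a fixed backbone tree. Each
# query is attached, one at a time, to every candidate edge (including the
# root) and the attachment minimising the Fitch parsimony score of the
# augmented tree wins. Queries are placed independently, so results cannot
# depend on which other queries are in the batch -- non-homologous queries
# can never attract each other into spurious clusters.

# Bitmask encoding of alignment rows for the parsimony kernel: A/C/G/T get
# their own bit, any IUPAC ambiguity keeps its base set, and N or '-' is the
# full wildcard (missing data).
.row_states <- function(rows) {
  if (length(rows) == 0) return(matrix(integer(0), 0, 0))
  W <- nchar(rows[[1]])
  mat <- matrix(0L, nrow = length(rows), ncol = W)
  for (i in seq_along(rows)) {
    ch <- strsplit(rows[[i]], "", fixed = TRUE)[[1]]
    bits <- .IUPAC_BITS[toupper(ch)]
    bits[is.na(bits) | bits == 0L] <- 15L  # '-' and unknowns -> wildcard
    mat[i, ] <- unname(bits)
  }
  rownames(mat) <- names(rows)
  mat
}

#' Canonical edge table of a rooted tree
#'
#' Fixes the edge numbering used by placement, clade extraction and the
#' jplace output: the tree is reordered cladewise and edges are numbered by
#' row, 1-based. Edge 0 denotes attachment at the root (outside every
#' clade). `depth` is the number of edges from the root to the edge's parent
#' node.
#'
#' @param tree a rooted `phylo` tree.
#' @return list with `tree` (the canonical `phylo`) and `edges` (data.frame:
#'   edge_id, parent, child, depth, is_pendant, tip_label).
#' @export
tree_edges <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  depth <- integer(max(tree$edge))
  depth[root] <- 0L
  for (k in seq_len(nrow(tree$edge))) depth[child[k]] <- depth[parent[k]] + 1L
  edges <- data.frame(
    edge_id = seq_len(nrow(tree$edge)),
    parent = parent, child = child,
    depth = depth[parent],
    is_pendant = child <= n_tip,
    tip_label = ifelse(child <= n_tip, tree$tip.label[pmin(child, n_tip)],
                       NA_character_),
    stringsAsFactors = FALSE
  )
  list(tree = tree, edges = edges)
}

#' Fitch parsimony score of an alignment on a tree
#'
#' Sum over columns of the small-parsimony change counts (Fitch for binary
#' nodes, the Hartigan counting generalisation at multifurcations). `N` and
#' `-` are wildcards (missing data) and never force a change.
#'
#' @param tree a rooted `phylo`.
#' @param rows named character vector of aligned rows covering every tip.
#' @return integer total number of changes.
#' @export
fitch_parsimony_score <- function(tree, rows) {
  te <- tree_edges(tree)
  tree <- te$tree
  miss <- setdiff(tree$tip.label, names(rows))
  if (length(miss) > 0)
    stop("alignment rows missing for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  states <- .row_states(rows[tree$tip.label])
  .fitch_total_cpp(tree$edge, length(tree$tip.label), states)
}

#' Parsimony score of every candidate attachment of a query
#'
#' Returns the Fitch score of the augmented tree for the query attached at
#' the root (name `"0"`) and on every edge, in [tree_edges()] numbering.
#'
#' @param tree a rooted `phylo`.
#' @param ref_rows named character vector of aligned reference rows.
#' @param query_row a single aligned query row of the same width.
#' @return named integer vector of length `nrow(edges) + 1`.
#' @export
attachment_scores <- function(tree, ref_rows, query_row) {
  te <- tree_edges(tree)
  tree <- te$tree
  ref_states <- .row_states(ref_rows[tree$tip.label])
  q_states <- .row_states(setNames(query_row, "q"))
  sc <- .attachment_scores_cpp(tree$edge, length(tree$tip.label), ref_states,
                               q_states)[1, ]
  setNames(as.integer(sc), as.character(0:(length(sc) - 1L)))
}

#' Place one aligned query into the backbone tree
#'
#' @param tree a rooted `phylo` backbone.
#' @param ref_rows named character vector of aligned reference rows (all tips
#'   covered), as produced by [concatenate_blocks()].
#' @param query_row a single aligned query row of the same width.
#' @param query_id id used in the output.
#' @return one-row data.frame as in [place_batch()].
#' @export
place_query <- function(tree, ref_rows, query_row, query_id = "query") {
  place_batch(setNames(query_row, query_id), tree, ref_rows)
}

#' Place aligned queries into the backbone tree
#'
#' Every query is placed independently by evaluating its attachment on every
#' edge of the tree plus the root; ties are broken by the edge closest to the
#' root, then the smallest edge id. Queries whose row is all missing data
#' (N/gap only) are flagged unplaceable.
#'
#' `batch_size` splits the work for audit-tree emission only; placements are
#' identical for any batch size.
#'
#' @param query_rows named character vector of aligned query rows.
#' @param tree a rooted `phylo` backbone.
#' @param ref_rows named character vector of aligned reference rows.
#' @param batch_size positive integer (default 500).
#' @param audit_trees if `TRUE`, attach an `audit_trees` attribute: one
#'   `phylo` per batch with that batch's queries grafted on their placement
#'   edges.
#' @return data.frame with columns query_id, best_edge (0 = root),
#'   parsimony_score, score_margin (second best minus best, >= 0), tie_count,
#'   unplaceable.
#' @export
place_batch <- function(query_rows, tree, ref_rows, batch_size = 500,
                        audit_trees = FALSE) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  te <- tree_edges(tree)
  tree <- te$tree
  miss <- setdiff(tree$tip.label, names(ref_rows))
  if (length(miss) > 0)
    stop("reference rows missing for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(query_id = character(0), best_edge = integer(0),
                    parsimony_score = integer(0), score_margin = integer(0),
                    tie_count = integer(0), unplaceable = logical(0))
  if (length(query_rows) == 0) {
    if (audit_trees) attr(out, "audit_trees") <- list()
    return(out)
  }
  W <- nchar(ref_rows[[1]])
  if (any(nchar(query_rows) != W))
    stop("query row width must equal reference row width", call. = FALSE)
  ref_states <- .row_states(ref_rows[tree$tip.label])
  q_states <- .row_states(query_rows)
  unplaceable <- apply(q_states, 1, function(r) all(r == 15L))
  res <- .place_queries_cpp(tree$edge, length(tree$tip.label), ref_states,
                            q_states, te$edges$depth)
  out <- data.frame(
    query_id = names(query_rows),
    best_edge = ifelse(unplaceable, NA_integer_, res$best_edge),
    parsimony_score = ifelse(unplaceable, NA_integer_, res$score),
    score_margin = ifelse(unplaceable, NA_integer_, res$second - res$score),
    tie_count = ifelse(unplaceable, NA_integer_, res$tie_count),
    unplaceable = unname(unplaceable),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (audit_trees) {
    idx <- split(seq_len(nrow(out)),
                 ceiling(seq_len(nrow(out)) / batch_size))
    attr(out, "audit_trees") <- lapply(idx, function(ii) {
      audit_tree(tree, out[ii, , drop = FALSE])
    })
  }
  out
}

#' Graft placed queries onto the backbone (audit tree)
#'
#' @param tree canonical backbone `phylo`.
#' @param placements rows from [place_batch()].
#' @return a `phylo` with one new tip per placeable query.
#' @export
audit_tree <- function(tree, placements) {
  te <- tree_edges(tree)
  tr <- te$tree
  for (i in seq_len(nrow(placements))) {
    if (isTRUE(placements$unplaceable[i])) next
    e <- placements$best_edge[i]
    tip <- placements$query_id[i]
    # node numbering shifts as tips are grafted, so the attachment point is
    # re-identified by its clade tip set each round
    if (e == 0) {
      where <- length(tr$tip.label) + 1L
      pos <- 0
    } else {
      orig_child <- te$edges$child[e]
      tips0 <- .clade_tips(te$tree, orig_child)
      where <- .node_by_tips(tr, tips0)
      # attach along the edge (position > 0), never replacing a tip
      blen <- tr$edge.length[which(tr$edge[, 2] == where)]
      pos <- if (length(blen) == 1 && !is.null(blen) && !is.na(blen))
        blen / 2 else 0
    }
    tr <- ape::bind.tree(tr, structure(list(edge = matrix(c(2L, 1L), 1, 2),
                                            tip.label = tip, Nnode = 1L,
                                            edge.length = 0),
                                       class = "phylo"),
                         where = where, position = pos)
  }
  tree_edges(tr)$tree
}

# tips descending from a node (node may be a tip)
.clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .clade_tips, tree = tree))
}

# node (tip index or internal node) whose clade is exactly `tips`
.node_by_tips <- function(tree, tips) {
  if (length(tips) == 1) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' Write placements as a jplace file
#'
#' Standard jplace (version 3) JSON: the canonical backbone Newick with
#' `{edge_id}` edge numbering and one placement record per query. Fields are
#' `edge_num`, `parsimony_score`, `score_margin`, `tie_count`.
#'
#' @param placements data.frame from [place_batch()].
#' @param tree the backbone `phylo` used for placement.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(placements, tree, path) {
  te <- tree_edges(tree)
  tr <- te$tree
  nwk <- ape::write.tree(tr)
  # annotate each edge with {edge_id}: rebuild newick with edge tags by
  # writing branch lengths then appending tags via a labelled traversal.
  tagged <- .newick_with_edge_tags(tr, te$edges)
  placed <- placements[!placements$unplaceable, , drop = FALSE]
  jp <- list(
    version = 3,
    tree = tagged,
    placements = lapply(seq_len(nrow(placed)), function(i) {
      list(p = list(list(placed$best_edge[i], placed$parsimony_score[i],
                         placed$score_margin[i], placed$tie_count[i])),
           n = list(placed$query_id[i]))
    }),
    fields = list("edge_num", "parsimony_score", "score_margin", "tie_count"),
    metadata = list(software = "amfplacer", original_tree = nwk)
  )
  jsonlite::write_json(jp, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Newick string with {edge_id} after each branch, matching tree_edges()
# numbering.
.newick_with_edge_tags <- function(tree, edges) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  bl <- tree$edge.length
  rec <- function(node, in_edge) {
    rows <- kids[[as.character(node)]]
    lab <- if (node <= n_tip) tree$tip.label[node] else ""
    body <- if (is.null(rows)) lab else {
      paste0("(", paste(vapply(rows, function(k)
        rec(tree$edge[k, 2], k), character(1)), collapse = ","), ")", lab)
    }
    if (is.na(in_edge) || is.null(in_edge)) return(body)
    len <- if (is.null(bl)) "" else paste0(":", format(bl[in_edge], digits = 10))
    paste0(body, len, "{", edges$edge_id[in_edge], "}")
  }
  paste0(rec(root, NA), ";")
}
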