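# Parsimony scoring and edge placement, checked against the independent
# recursive oracle on explicitly augmented trees.

test_that("fitch_parsimony_score matches textbook cases and the oracle", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  rows4 <- c(A = "AAAA", B = "AAAA", C = "AAAA", D = "AAAA")
  expect_equal(fitch_parsimony_score(tr, rows4), 0L)
  # one column splitting the two cherries costs exactly 1 change
  rows <- c(A = "A", B = "A", C = "T", D = "T")
  expect_equal(fitch_parsimony_score(tr, rows), 1L)
  # missing data never forces a change
  rowsN <- c(A = "A", B = "N", C = "-", D = "T")
  expect_equal(fitch_parsimony_score(tr, rowsN), 1L)
  expect_error(fitch_parsimony_score(tr, rows[1:3]), "missing for tip")
  # random instances vs the independent recursive scorer
  set.seed(41)
  for (rep in 1:15) {
    nt <- sample(4:8, 1); W <- sample(5:20, 1)
    tri <- ape::rtree(nt)
    rws <- setNames(vapply(1:nt, function(i)
      rand_dna(W, c("A", "C", "G", "T", "N", "-")), character(1)),
      tri$tip.label)
    expect_equal(fitch_parsimony_score(tri, rws), r_fitch_score(tri, rws))
  }
})

test_that("a query identical to a tip places on that tip's pendant edge region", {
  set.seed(42)
  nt <- 10
  tr <- ape::rtree(nt)
  rows <- setNames(vapply(1:nt, function(i) rand_dna(60), character(1)),
                   tr$tip.label)
  te <- tree_edges(tr)
  for (tip in tr$tip.label[1:4]) {
    pl <- place_query(tr, rows, rows[[tip]], "q")
    best_sc <- pl$parsimony_score
    # attaching on the pendant edge must achieve the optimum
    pend <- te$edges$edge_id[!is.na(te$edges$tip_label) &
                               te$edges$tip_label == tip]
    sc <- attachment_scores(tr, rows, rows[[tip]])
    expect_equal(unname(sc[as.character(pend)]), best_sc)
    expect_gte(pl$score_margin, 0)
  }
})

test_that("symmetric ties are counted and resolved root-most", {
  # ((A,B),(C,D)) with A=B and C=D, query midway between the two cherries:
  # several attachments tie; the reported edge must be the root-most tie
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rows <- c(A = "AAAATT", B = "AAAATT", C = "TTTTTT", D = "TTTTTT")
  q <- "AAATTT"
  pl <- place_query(tr, rows, q)
  expect_gte(pl$tie_count, 2)
  sc <- attachment_scores(tr, rows, q)
  ties <- names(sc)[sc == min(sc)]
  te <- tree_edges(tr)
  depths <- c(`0` = -1L, setNames(te$edges$depth, as.character(te$edges$edge_id)))
  best_depth <- min(depths[ties])
  want <- min(as.integer(ties[depths[ties] == best_depth]))
  expect_equal(pl$best_edge, want)
})

test_that("placement equals the exhaustive bind-and-rescore oracle", {
  set.seed(43)
  for (rep in 1:12) {
    nt <- sample(4:9, 1); W <- sample(8:25, 1)
    tr <- ape::rtree(nt)
    rows <- setNames(vapply(1:nt, function(i)
      rand_dna(W, c("A", "C", "G", "T", "N", "-")), character(1)),
      tr$tip.label)
    q <- rand_dna(W, c("A", "C", "G", "T", "N"))
    mine <- attachment_scores(tr, rows, q)
    oracle <- oracle_attachment_scores(tr, rows, q)
    expect_equal(unname(mine), oracle)
  }
})

test_that("simulated queries place near their origin tip and degrade monotonely", {
  fx <- small_fixture(seed = 44, query_divergence = 0.02)
  db <- build_reference_db(fx$ref_raw, fx$family_map)
  tree <- root_tree(fx$tree, fx$outgroup_tip)
  cuts <- cut_reference_to_read_lengths(db, 80, 80)
  sp <- split_alignment(build_reference_alignment(cuts$r1),
                        build_reference_alignment(cuts$r2))
  fr <- fixture_fragments(fx)
  sp <- add_queries(sp, substr(fr$r1, 1, 80), substr(fr$r2, 1, 80))
  cc <- concatenate_blocks(sp)
  pl <- place_batch(cc[!attr(cc, "is_ref")], tree, cc[attr(cc, "is_ref")])
  te <- tree_edges(tree)
  pend <- setNames(te$edges$edge_id[te$edges$is_pendant],
                   te$edges$tip_label[te$edges$is_pendant])
  amf <- fx$truth$is_amf[match(pl$query_id, fx$truth$query_id)]
  origin <- fx$truth$origin_tip[match(pl$query_id, fx$truth$query_id)]
  # most AMF-origin queries hit their origin pendant edge exactly
  hit <- (pl$best_edge == pend[origin])[amf & !is.na(origin)]
  expect_gte(mean(hit), 0.7)
})

test_that("batching and query order never change placements", {
  fx <- small_fixture(seed = 45)
  db <- build_reference_db(fx$ref_raw, fx$family_map)
  tree <- root_tree(fx$tree, fx$outgroup_tip)
  cuts <- cut_reference_to_read_lengths(db, 80, 80)
  sp <- split_alignment(build_reference_alignment(cuts$r1),
                        build_reference_alignment(cuts$r2))
  fr <- fixture_fragments(fx)
  sp <- add_queries(sp, substr(fr$r1, 1, 80), substr(fr$r2, 1, 80))
  cc <- concatenate_blocks(sp)
  qrows <- cc[!attr(cc, "is_ref")]
  rrows <- cc[attr(cc, "is_ref")]
  a <- place_batch(qrows, tree, rrows, batch_size = 1)
  b <- place_batch(qrows, tree, rrows, batch_size = 500)
  expect_identical(a, b)
  perm <- sample(length(qrows))
  c2 <- place_batch(qrows[perm], tree, rrows)
  expect_identical(a[match(c2$query_id, a$query_id), ]$best_edge, c2$best_edge)
  # empty query set
  expect_equal(nrow(place_batch(character(0), tree, rrows)), 0)
  # all-missing row is unplaceable
  allN <- setNames(strrep("N", nchar(rrows[[1]])), "degenerate")
  un <- place_batch(allN, tree, rrows)
  expect_true(un$unplaceable)
  expect_true(is.na(un$best_edge))
})

test_that("audit trees contain the batch queries plus all reference tips", {
  fx <- small_fixture(seed = 46)
  db <- build_reference_db(fx$ref_raw, fx$family_map)
  tree <- root_tree(fx$tree, fx$outgroup_tip)
  cuts <- cut_reference_to_read_lengths(db, 80, 80)
  sp <- split_alignment(build_reference_alignment(cuts$r1),
                        build_reference_alignment(cuts$r2))
  fr <- fixture_fragments(fx)
  ids <- names(fr$r1)[1:6]
  sp <- add_queries(sp, substr(fr$r1[ids], 1, 80), substr(fr$r2[ids], 1, 80))
  cc <- concatenate_blocks(sp)
  pl <- place_batch(cc[!attr(cc, "is_ref")], tree, cc[attr(cc, "is_ref")],
                    batch_size = 4, audit_trees = TRUE)
  audits <- attr(pl, "audit_trees")
  expect_length(audits, 2)
  expect_setequal(audits[[1]]$tip.label, c(tree$tip.label, pl$query_id[1:4]))
})

test_that("jplace output round-trips tree, fields, and placements", {
  fx <- small_fixture(seed = 47)
  db <- build_reference_db(fx$ref_raw, fx$family_map)
  tree <- root_tree(fx$tree, fx$outgroup_tip)
  cuts <- cut_reference_to_read_lengths(db, 60, 60)
  sp <- split_alignment(build_reference_alignment(cuts$r1),
                        build_reference_alignment(cuts$r2))
  fr <- fixture_fragments(fx)
  ids <- names(fr$r1)[1:3]
  sp <- add_queries(sp, substr(fr$r1[ids], 1, 60), substr(fr$r2[ids], 1, 60))
  cc <- concatenate_blocks(sp)
  pl <- place_batch(cc[!attr(cc, "is_ref")], tree, cc[attr(cc, "is_ref")])
  path <- tempfile(fileext = ".jplace")
  write_jplace(pl, tree, path)
  jp <- jsonlite::read_json(path)
  expect_equal(jp$version, 3)
  expect_equal(unlist(jp$fields)[1], "edge_num")
  expect_length(jp$placements, sum(!pl$unplaceable))
  # every edge id appears exactly once as a {tag} in the tree string
  te <- tree_edges(tree)
  tags <- as.integer(gsub("[{}]", "",
                          regmatches(jp$tree, gregexpr("\\{\\d+\\}", jp$tree))[[1]]))
  expect_setequal(tags, te$edges$edge_id)
})
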