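# Clade delimitation by MRCA, placement classification, table extraction,
# and per-clade summaries.

test_that("root_tree is idempotent and errors on unknown tips", {
  tr <- ape::read.tree(text = "((A,B),(C,O));")
  r1 <- root_tree(tr, "O")
  expect_true(ape::is.rooted(r1))
  r2 <- root_tree(r1, "O")
  expect_equal(ape::write.tree(r1), ape::write.tree(r2))
  # outgroup sits directly under the root
  root <- length(r1$tip.label) + 1L
  kids <- r1$edge[r1$edge[, 1] == root, 2]
  expect_true(match("O", r1$tip.label) %in% kids)
  # unrooted tree gets rooted
  un <- ape::unroot(ape::rtree(5))
  un$tip.label[1] <- "OG"
  ru <- root_tree(un, "OG")
  expect_true(ape::is.rooted(ru))
  expect_error(root_tree(tr, "ZZZ"), "not in tree")
})

test_that("define_clade finds MRCA and member edges on small cases", {
  tr <- ape::read.tree(text = "((A,B),C);")
  cl <- define_clade(tr, c("A", "B"), "AB")
  te <- tree_edges(tr)
  pend <- te$edges$edge_id[!is.na(te$edges$tip_label) &
                             te$edges$tip_label %in% c("A", "B")]
  expect_setequal(cl$edges, pend)
  expect_false(cl$stem_edge %in% cl$edges)
  # defining tips spanning the root: all non-stem edges belong
  cl2 <- define_clade(tr, c("A", "C"), "all")
  expect_setequal(cl2$edges, te$edges$edge_id)
  expect_error(define_clade(tr, "A", "single"), "at least 2")
  expect_error(define_clade(tr, c("A", "Z"), "bad"), "not in tree")
})

test_that("define_clade equals the brute-force containment oracle", {
  set.seed(51)
  for (rep in 1:25) {
    nt <- sample(6:14, 1)
    tr <- ape::rtree(nt)
    tips <- sample(tr$tip.label, sample(2:(nt - 1), 1))
    cl <- define_clade(tr, tips, "X")
    expect_setequal(cl$edges, brute_clade_edges(tr, tips))
  }
})

test_that("clade membership is invariant to tip-order rotations", {
  fx <- small_fixture(seed = 52)
  tr <- root_tree(fx$tree, fx$outgroup_tip)
  fam <- fx$family_map$id[fx$family_map$group_label == "Family_01"]
  cl <- define_clade(tr, fam, "Family_01")
  rot <- ape::rotate(tr, node = cl$mrca)
  cl2 <- define_clade(rot, fam, "Family_01")
  expect_setequal(cl$tips, cl2$tips)
  # edge ids differ after rotation, but the tip content of the clade is fixed
  te2 <- tree_edges(rot)
  tips2 <- te2$edges$tip_label[te2$edges$edge_id %in% cl2$edges &
                                 te2$edges$is_pendant]
  expect_setequal(tips2, setdiff(cl$tips, NA))
})

test_that("the default fixture model yields exactly 11 family clades", {
  fx <- make_fixture(sim_config(n_amf_tips = 26, n_families = 11,
                                n_outgroup_tips = 6, region_length = 120,
                                r1_len = 40, r2_len = 40, n_queries = 0,
                                n_junk_reads = 0, seed = 53))
  tr <- root_tree(fx$tree, fx$outgroup_tip)
  mod <- clade_model(tr, fx$family_map)
  expect_length(mod$families, 11)
  expect_true(all(vapply(mod$families, function(f)
    all(f$tips %in% mod$amf$tips), logical(1))))
})

test_that("classify_placement applies the stem rule and smallest-clade rule", {
  fx <- small_fixture(seed = 54)
  tr <- root_tree(fx$tree, fx$outgroup_tip)
  mod <- clade_model(tr, fx$family_map)
  fam1 <- mod$families[[1]]
  mk <- function(edge) data.frame(query_id = "q", best_edge = edge,
                                  parsimony_score = 0L, score_margin = 0L,
                                  tie_count = 1L, unplaceable = FALSE)
  # edge inside a family clade
  a <- classify_placement(mk(fam1$edges[1]), mod)
  expect_true(a$is_amf)
  expect_equal(a$family, fam1$name)
  # AMF stem edge counts as outside by default, inside with include_stem
  st <- classify_placement(mk(mod$amf$stem_edge), mod)
  expect_false(st$is_amf)
  st2 <- classify_placement(mk(mod$amf$stem_edge), mod, include_stem = TRUE)
  expect_true(st2$is_amf)
  # inside AMF but between families -> unclassified
  fam_edges <- unlist(lapply(mod$families, `[[`, "edges"))
  between <- setdiff(mod$amf$edges,
                     c(fam_edges, vapply(mod$families, `[[`, integer(1),
                                         "stem_edge")))
  b <- classify_placement(mk(between[1]), mod)
  expect_true(b$is_amf)
  expect_equal(b$family, "Glomeromycota_unclassified")
  # root attachment is outside everything; unknown edges error
  r <- classify_placement(mk(0L), mod)
  expect_false(r$is_amf)
  expect_error(classify_placement(mk(9999L), mod), "unknown edge")
})

test_that("extract_tables partitions features and conserves counts", {
  fx <- small_fixture(seed = 55)
  tr <- root_tree(fx$tree, fx$outgroup_tip)
  mod <- clade_model(tr, fx$family_map)
  set.seed(56)
  n <- 12
  ft <- dereplicate(vapply(1:n, function(i) rand_dna(30), character(1)),
                    rep(c("s1", "s2"), length.out = n),
                    sample(1:20, n, replace = TRUE))
  ids <- rownames(ft$counts)
  asn <- data.frame(
    query_id = ids[1:10],
    is_amf = c(rep(TRUE, 6), rep(FALSE, 4)),
    family = c(mod$family_names[c(1, 1, 2, 3)], "Glomeromycota_unclassified",
               "Glomeromycota_unclassified", rep(NA, 4)),
    stringsAsFactors = FALSE
  ) # ids 11:12 unassigned -> discarded
  ex <- extract_tables(ft, asn, family_names = mod$family_names)
  # every family of the model appears, even empty ones
  expect_setequal(setdiff(names(ex$families), "Glomeromycota_unclassified"),
                  mod$family_names)
  # family tables partition the AMF table
  fam_ids <- unlist(lapply(ex$families, function(t) rownames(t$counts)))
  expect_equal(sort(unname(fam_ids)), sort(rownames(ex$amf$counts)))
  expect_equal(anyDuplicated(fam_ids), 0L)
  # all buckets together account for every feature exactly once
  all_ids <- c(rownames(ex$amf$counts), rownames(ex$non_amf$counts),
               rownames(ex$discarded$counts))
  expect_setequal(all_ids, ids)
  expect_equal(sum(ex$amf$counts) + sum(ex$non_amf$counts) +
                 sum(ex$discarded$counts), sum(ft$counts))
  # counts per feature unchanged
  expect_equal(ex$amf$counts, ft$counts[rownames(ex$amf$counts), , drop = FALSE])
})

test_that("summarize_fractions reports feature and read percentages", {
  ft <- feature_table(matrix(c(70L, 10L, 10L, 10L), ncol = 1,
                             dimnames = list(paste0("F", 1:4), "s1")),
                      setNames(rep("ACGT", 4), paste0("F", 1:4)))
  asn <- data.frame(query_id = paste0("F", 1:4), is_amf = TRUE,
                    family = c("X", "Y", "Y", "Y"))
  sf <- summarize_fractions(asn, ft)
  x <- sf[sf$clade == "X", ]
  expect_equal(x$pct_features, 25)
  expect_equal(x$pct_reads, 70)
  expect_equal(sum(sf$pct_features), 100)
  expect_equal(sum(sf$pct_reads), 100)
  # all in one family
  asn2 <- data.frame(query_id = paste0("F", 1:4), is_amf = TRUE, family = "X")
  sf2 <- summarize_fractions(asn2, ft)
  expect_equal(sf2$pct_features, 100)
  # zero AMF features: empty report, not an error
  asn3 <- data.frame(query_id = paste0("F", 1:4), is_amf = FALSE,
                     family = NA_character_)
  expect_equal(nrow(summarize_fractions(asn3, ft)), 0)
})
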