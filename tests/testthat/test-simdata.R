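# Synthetic fixture generator: determinism, tree shape, sequence evolution,
# and truth-label consistency.

test_that("simulate_tree is reproducible with the right shape", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  a <- simulate_tree(20, seed = 5)
  b <- simulate_tree(20, seed = 5)
  expect_equal(ape::write.tree(a), ape::write.tree(b))
  t50 <- simulate_tree(50, seed = 6)
  # rooted binary: 2n - 2 edges
  expect_equal(nrow(t50$edge), 98)
  expect_true(ape::is.rooted(t50))
  expect_error(simulate_tree(1, seed = 1), ">= 2")
})

test_that("evolve_sequences follows the per-branch substitution model", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  root <- paste(rep(c("A", "C", "G", "T"), 2500), collapse = "")
  # rate 0: all tips identical to the root
  tips0 <- evolve_sequences(tr, root, 0, seed = 1)
  expect_equal(unname(tips0["A"]), root)
  # rate 0.05 on a unit branch: observed differences within 3 SD of binomial
  tips <- evolve_sequences(tr, root, 0.05, seed = 2)
  d <- sum(strsplit(tips[["A"]], "")[[1]] != strsplit(root, "")[[1]])
  n <- nchar(root); p <- 0.05
  expect_lt(abs(d - n * p), 3 * sqrt(n * p * (1 - p)))
  # determinism
  tips2 <- evolve_sequences(tr, root, 0.05, seed = 2)
  expect_identical(tips, tips2)
  expect_error(evolve_sequences(tr, "ACGN", 0.1, seed = 1), "root_seq")
})

test_that("fixtures are byte-identical under a fixed seed", {
  cfg <- sim_config(n_amf_tips = 10, n_families = 3, n_outgroup_tips = 4,
                    region_length = 100, r1_len = 30, r2_len = 30,
                    n_queries = 5, n_junk_reads = 2, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  make_fixture(cfg, dir = d1)
  make_fixture(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("truth labels are consistent with the emitted tree and map", {
  fx <- small_fixture(seed = 61)
  # every AMF-origin query's tip carries exactly one family label
  amf_truth <- fx$truth[fx$truth$is_amf, ]
  labels <- fx$family_map$group_label[match(amf_truth$origin_tip,
                                            fx$family_map$id)]
  expect_false(any(is.na(labels)))
  expect_identical(labels, amf_truth$group_label)
  # family tips form clades: defining tips' MRCA subtree contains no
  # other family's tips
  tr <- root_tree(fx$tree, fx$outgroup_tip)
  for (fam in unique(labels)) {
    tips <- fx$family_map$id[fx$family_map$group_label == fam]
    cl <- define_clade(tr, tips, fam)
    expect_setequal(cl$tips, tips)
  }
  # query fragments at divergence 0 equal the reference fragments
  cfg0 <- sim_config(n_amf_tips = 8, n_families = 2, n_outgroup_tips = 3,
                     region_length = 100, r1_len = 30, r2_len = 30,
                     query_divergence = 0, n_queries = 6, n_junk_reads = 0,
                     seed = 62)
  fx0 <- make_fixture(cfg0)
  fr <- fixture_fragments(fx0)
  for (i in seq_len(6)) {
    org <- fx0$truth$origin_tip[i]
    expect_equal(unname(fr$r1[i]), substr(fx0$ref_regions[[org]], 1, 30))
  }
})

test_that("junk reads have near-uniform base composition", {
  cfg <- sim_config(n_amf_tips = 6, n_families = 2, n_outgroup_tips = 3,
                    region_length = 100, r1_len = 100, r2_len = 100,
                    n_queries = 0, n_junk_reads = 40, seed = 63)
  fx <- make_fixture(cfg)
  junk <- fx$reads$r1[grepl("^JUNK", names(fx$reads$r1))]
  tab <- table(strsplit(paste(junk, collapse = ""), "")[[1]])
  chi <- chisq.test(tab[c("A", "C", "G", "T")])
  expect_gt(chi$p.value, 1e-4)
})

test_that("sim_config validates counts, rates, and family feasibility", {
  expect_error(sim_config(seed = 1, substitution_rate = 0.8), "rates")
  expect_error(sim_config(seed = 1, n_amf_tips = 10, n_families = 6),
               "disjoint clades")
  expect_error(sim_config(), "seed is mandatory")
})
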