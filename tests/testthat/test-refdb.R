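# Reference curation: primer location, region trimming, padding, database
# assembly, read-length cutting, and read primer clipping.

test_that("find_primer_site locates minimal-mismatch windows", {
  # exact substring
  expect_equal(find_primer_site("GGAAACC", "AAA", 0),
               list(start = 2L, end = 5L, mismatches = 0L))
  # IUPAC degeneracy: R matches A or G
  expect_equal(find_primer_site("GGAGACC", "ARA", 0)[c("start", "end")],
               list(start = 2L, end = 5L))
  # brute-force oracle over all windows of length 4 in TTTTAAAT at rate 0.25:
  # best window is AAAT at offset 3 with 1 mismatch
  site <- find_primer_site("TTTTAAAT", "AAAA", 0.25)
  expect_equal(site, list(start = 3L, end = 7L, mismatches = 1L))
  # no window within budget
  expect_null(find_primer_site("CCCCCCC", "AAAA", 0.25))
  # N matches anything on either side
  expect_equal(find_primer_site("GGNAACC", "AAA", 0)$mismatches, 0L)
  expect_error(find_primer_site("ACGX", "AAA", 0), "invalid character")
})

test_that("find_primer_site matches a brute-force window scan on random input", {
  set.seed(7)
  brute <- function(seq, primer, rate) {
    s <- strsplit(seq, "")[[1]]; p <- strsplit(primer, "")[[1]]
    k <- length(p); best <- NULL
    for (i in seq_len(length(s) - k + 1)) {
      mm <- sum(s[i:(i + k - 1)] != p)
      if (is.null(best) || mm < best$mm) best <- list(i = i, mm = mm)
    }
    if (best$mm > floor(rate * k)) NULL else best
  }
  for (rep in 1:25) {
    seq <- rand_dna(60); primer <- rand_dna(8)
    got <- find_primer_site(seq, primer, 0.25)
    want <- brute(seq, primer, 0.25)
    if (is.null(want)) expect_null(got) else {
      expect_equal(got$start, want$i - 1L)
      expect_equal(got$mismatches, want$mm)
    }
  }
})

test_that("trim_reference recovers the inner region in either orientation", {
  pp <- default_primer_pair()
  set.seed(1)
  for (rep in 1:10) {
    x <- rand_dna(30)
    raw <- paste0(pp$forward_seq, x, revcomp(pp$reverse_seq))
    tr <- trim_reference(raw, pp)
    expect_true(tr$trimmed)
    expect_equal(tr$region, x)
    expect_equal(tr$orientation, "forward")
    # whole construct reverse-complemented: orientation corrected
    tr2 <- trim_reference(revcomp(raw), pp)
    expect_true(tr2$trimmed)
    expect_equal(tr2$region, x)
    expect_equal(tr2$orientation, "reverse")
  }
  # neither primer present: full sequence back, flagged untrimmed
  plain <- rand_dna(200)
  tr3 <- trim_reference(plain, pp)
  expect_false(tr3$trimmed)
  expect_equal(tr3$region, plain)
  # reverse site upstream of forward site is malformed
  bad <- paste0(revcomp(pp$reverse_seq), rand_dna(20), pp$forward_seq)
  expect_error(trim_reference(bad, pp), "malformed")
})

test_that("pad_to_region pads on the side opposite the anchor", {
  p <- pad_to_region("ACGTACG", 10, anchor = "start")
  expect_equal(p, list(seq = "ACGTACGNNN", pad_left = 0L, pad_right = 3L))
  expect_equal(pad_to_region("ACGTACGTAC", 10),
               list(seq = "ACGTACGTAC", pad_left = 0L, pad_right = 0L))
  expect_equal(pad_to_region("ACGTAC", 10, anchor = "end"),
               list(seq = "NNNNACGTAC", pad_left = 4L, pad_right = 0L))
  expect_error(pad_to_region("ACGTACGTACG", 10), "longer than target")
  # stripping the padded side recovers the input
  set.seed(2)
  for (rep in 1:10) {
    x <- rand_dna(sample(3:10, 1))
    out <- pad_to_region(x, 12, anchor = sample(c("start", "end"), 1))
    expect_equal(nchar(out$seq), 12)
    expect_equal(gsub("^N+|N+$", "", out$seq), x)
  }
})

test_that("build_reference_db trims, pads, and annotates", {
  pp <- default_primer_pair()
  set.seed(3)
  regions <- c(R1 = rand_dna(50), R2 = rand_dna(44), R3 = rand_dna(38))
  raw <- setNames(paste0(pp$forward_seq, regions, revcomp(pp$reverse_seq)),
                  names(regions))
  fmap <- data.frame(id = names(raw), group_label = c("FamA", "FamB", "outgroup"),
                     taxon = "", accession = "")
  db <- build_reference_db(raw, fmap, pp)
  expect_s3_class(db, "reference_db")
  expect_equal(db$target_region_length, 50L)
  expect_equal(unname(db$records$pad_right), c(0L, 6L, 12L))
  expect_equal(db$family_names, c("FamA", "FamB"))
  expect_equal(substr(db$region_seqs[["R2"]], 1, 44), unname(regions["R2"]))
  # an 11-family map yields 11 family names
  fx <- make_fixture(sim_config(n_amf_tips = 22, n_families = 11,
                                n_outgroup_tips = 4, region_length = 120,
                                r1_len = 40, r2_len = 40, n_queries = 0,
                                n_junk_reads = 0, seed = 5))
  db11 <- build_reference_db(fx$ref_raw, fx$family_map)
  expect_length(db11$family_names, 11)
  # errors
  expect_error(build_reference_db(character(0), fmap), "empty")
  expect_error(build_reference_db(raw, fmap[-2, ]), "missing from family map")
  expect_error(build_reference_db(setNames(raw, c("A", "A", "B")),
                                  data.frame(id = c("A", "B"),
                                             group_label = "F",
                                             taxon = "", accession = "")),
               "duplicate")
})

test_that("cut_reference_to_read_lengths partitions the region", {
  pp <- default_primer_pair()
  raw <- c(X = paste0(pp$forward_seq, "AAACCCGGGTTT", revcomp(pp$reverse_seq)))
  fmap <- data.frame(id = "X", group_label = "FamA", taxon = "", accession = "")
  db <- build_reference_db(raw, fmap, pp)
  cut <- cut_reference_to_read_lengths(db, 3, 3)
  expect_equal(unname(cut$r1["X"]), "AAA")
  expect_equal(unname(cut$r2["X"]), revcomp("TTT"))
  # fragments + middle reconstruct the region
  mid <- substr(db$region_seqs[["X"]], 4, 9)
  expect_equal(paste0(cut$r1[["X"]], mid, revcomp(cut$r2[["X"]])),
               db$region_seqs[["X"]])
  # boundary: r1 + r2 = region length partitions it
  cut2 <- cut_reference_to_read_lengths(db, 6, 6)
  expect_equal(paste0(cut2$r1[["X"]], revcomp(cut2$r2[["X"]])),
               db$region_seqs[["X"]])
  expect_error(cut_reference_to_read_lengths(db, 7, 6), "exceeds")
})

test_that("trim_read_pair clips anchored primers and applies the drop policy", {
  pp <- default_primer_pair()
  set.seed(4)
  payload1 <- rand_dna(40); payload2 <- rand_dna(40)
  r1 <- c(a = paste0(pp$forward_seq, payload1), b = payload1)
  r2 <- c(a = paste0(pp$reverse_seq, payload2),
          b = paste0(pp$reverse_seq, payload2))
  kept <- trim_read_pair(r1, r2, pp, policy = "keep")
  expect_equal(unname(kept$r1["a"]), payload1)
  expect_equal(unname(kept$r1["b"]), payload1) # no primer found, unclipped
  expect_equal(unname(kept$log["n_dropped"]), 0L)
  dropped <- trim_read_pair(r1, r2, pp, policy = "drop")
  expect_equal(names(dropped$r1), "a")
  expect_equal(unname(dropped$log["n_dropped"]), 1L)
  # one mismatch within rate 0.1 of a 17-mer primer (floor(1.7) = 1 allowed)
  mut <- pp$forward_seq
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mut, 5, 5))[1]
  r1m <- c(m = paste0(mut, payload1))
  r2m <- c(m = paste0(pp$reverse_seq, payload2))
  out <- trim_read_pair(r1m, r2m, pp, policy = "drop")
  expect_equal(unname(out$r1["m"]), payload1)
})

test_that("database build is order-independent up to record order", {
  fx <- small_fixture(seed = 9)
  db1 <- build_reference_db(fx$ref_raw, fx$family_map)
  perm <- sample(length(fx$ref_raw))
  db2 <- build_reference_db(fx$ref_raw[perm], fx$family_map)
  expect_equal(db1$region_seqs[sort(names(db1$region_seqs))],
               db2$region_seqs[sort(names(db2$region_seqs))])
  expect_equal(db1$target_region_length, db2$target_region_length)
  expect_equal(db1$family_names, db2$family_names)
})
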