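# Homologue screening: threshold operators, deduplication, presence units,
# and the local-alignment identity oracle.

test_that("e-value threshold is strict and identity threshold inclusive", {
  hits <- dplyr::bind_rows(
    make_hits(evalue = 1e-31, pident = 35),   # kept
    make_hits(evalue = 1e-30, pident = 35),   # rejected: evalue boundary
    make_hits(evalue = 1e-31, pident = 30.0), # kept: identity boundary
    make_hits(evalue = 1e-31, pident = 29.99) # rejected
  )
  kept <- filter_hits(hits, screen_config())
  expect_equal(nrow(kept), 2)
  expect_equal(kept$pident, c(35, 30.0))
  expect_equal(nrow(filter_hits(hits[0, ])), 0)
})

test_that("filtering is idempotent and monotone in the thresholds", {
  set.seed(42)
  hits <- make_hits(scaffold_id = sprintf("s%d", 1:200),
                    evalue = 10^-runif(200, 20, 60),
                    pident = runif(200, 10, 90))
  once <- filter_hits(hits)
  expect_identical(filter_hits(once), once)
  for (i in 1:10) {
    loose <- screen_config(evalue_max = 10^-runif(1, 25, 35),
                           pident_min = runif(1, 20, 40))
    tight <- screen_config(evalue_max = loose$evalue_max / 10,
                           pident_min = loose$pident_min + 10)
    expect_true(all(filter_hits(hits, tight)$subject %in%
                      filter_hits(hits, loose)$subject))
  }
})

test_that("deduplication keeps min e-value, then max bitscore, then first", {
  h <- dplyr::bind_rows(
    make_hits(evalue = 1e-35, bitscore = 100),
    make_hits(evalue = 1e-40, bitscore = 90)
  )
  expect_equal(dedupe_hits(h)$evalue, 1e-40)
  tie <- dplyr::bind_rows(
    make_hits(evalue = 1e-40, bitscore = 200),
    make_hits(evalue = 1e-40, bitscore = 180)
  )
  expect_equal(dedupe_hits(tie)$bitscore, 200)
  two_prot <- dplyr::bind_rows(
    make_hits(protein_index = 1L), make_hits(protein_index = 2L)
  )
  expect_equal(nrow(dedupe_hits(two_prot)), 2)
})

test_that("presence is per MAG when binned, per scaffold when not", {
  hits <- dplyr::bind_rows(
    make_hits(scaffold_id = "s1", protein_index = 1L),
    make_hits(scaffold_id = "s1", protein_index = 2L),
    make_hits(scaffold_id = "s2", protein_index = 1L),
    make_hits(scaffold_id = "scf7", protein_index = 1L)
  )
  bins <- tibble::tibble(scaffold_id = c("s1", "s2"), bin_id = "b1")
  pres <- presence_by_unit(hits, bins)
  expect_equal(nrow(pres), 2)
  mag <- pres[pres$unit_type == "mag", ]
  expect_equal(mag$unit, "b1")
  expect_equal(mag$n_hit_scaffolds, 2L)
  expect_equal(pres$unit[pres$unit_type == "unbinned"], "unbinned:scf7")
  expect_equal(nrow(presence_by_unit(hits[0, ], bins)), 0)
  bad_bins <- tibble::tibble(scaffold_id = c("s1", "s1"), bin_id = c("b1", "b2"))
  expect_error(presence_by_unit(hits, bad_bins), "more than one bin")
})

test_that("sw_identity scores agree with an independent aligner on random peptides", {
  skip_if_not_installed("Biostrings")
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- matrix(-1, 20, 20, dimnames = list(aa, aa))
  diag(mat) <- 2
  for (i in 1:25) {
    a <- paste(sample(aa, sample(3:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(3:12, 1), replace = TRUE), collapse = "")
    mine <- sw_identity(a, b, match = 2, mismatch = -1, gap = -2)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2)
    expect_equal(mine$score, max(0, Biostrings::score(ref)),
                 info = paste(a, b))
  }
})

test_that("sw_identity handles known alignments and degenerate input", {
  s <- sw_identity("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(s$identity, 100)
  expect_equal(s$columns, 10L)
  # full-length local alignment with one mismatch beats the exact prefix
  s2 <- sw_identity("ACDEFG", "ACXEFG", match = 1, mismatch = -1, gap = -2)
  expect_equal(s2$score, 4)
  expect_equal(s2$identity, 100 * 5 / 6)
  # disjoint alphabets: empty optimal alignment, identity undefined
  s3 <- sw_identity("AAAA", "GGGG", match = 1, mismatch = -1, gap = -2)
  expect_equal(s3$score, 0)
  expect_true(is.na(s3$identity))
  expect_error(sw_identity("", "AAA"), "non-empty")
})

test_that("planted synthetic proteins align well to their family query", {
  bundle <- generate_community(small_config(seed = 5))
  prot <- bundle$tables$proteins
  q <- bundle$tables$queries
  hit <- bundle$tables$hits[1, ]
  s <- sw_identity(prot[[hit$subject]], q[[hit$family]])
  expect_gt(s$identity, 30)
})
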