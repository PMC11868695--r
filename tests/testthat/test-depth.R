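# Depth normalization and the own-sample aggregation rule.

test_that("normalization is avg_depth * scale / total_reads", {
  d <- make_depth("s1", "50", "50", avg_depth = c(2, 0, 3),
                  mapping_total_reads = c(1e8, 1e8, 5e7))
  nd <- normalize_depth(d, scale = 1e8)
  expect_equal(nd$norm_depth, c(2, 0, 6))
  expect_error(normalize_depth(make_depth("s1", "a", "a", 1, 0)),
               "mapping_total_reads")
})

test_that("normalization is invariant under joint rescaling of depth and totals", {
  set.seed(2)
  d <- make_depth(sprintf("s%d", 1:50), "50", "70",
                  avg_depth = runif(50, 0, 5),
                  mapping_total_reads = runif(50, 1e6, 1e9))
  k <- 3.7
  d2 <- dplyr::mutate(d, avg_depth = avg_depth * k,
                      mapping_total_reads = mapping_total_reads * k)
  expect_equal(normalize_depth(d)$norm_depth, normalize_depth(d2)$norm_depth)
})

test_that("own-sample vs naive aggregation on the two-scaffold worked example", {
  # scaffold A assembled in s1, B in s2; both strains present in both samples
  d <- dplyr::bind_rows(
    make_depth("A", "s1", "s1", 5), make_depth("A", "s1", "s2", 4),
    make_depth("B", "s2", "s1", 3), make_depth("B", "s2", "s2", 6)
  )
  nd <- normalize_depth(d)
  own <- aggregate_own_sample(nd, samples = c("s1", "s2"))
  expect_equal(own$value, c(5, 6))
  naive <- aggregate_naive(nd, samples = c("s1", "s2"))
  expect_equal(naive$value, c(8, 10))
  # samples with no qualifying scaffolds are zero-filled, not dropped
  own3 <- aggregate_own_sample(nd, samples = c("s1", "s2", "s3"))
  expect_equal(own3$value, c(5, 6, 0))
  empty <- aggregate_own_sample(nd[0, ], samples = c("s1", "s2"))
  expect_equal(empty$value, c(0, 0))
})

test_that("own-sample never exceeds naive, and equals it without strain sharing", {
  for (seed in 1:10) {
    bundle <- generate_community(small_config(seed = seed))
    nd <- normalize_depth(bundle$tables$depth)
    own <- aggregate_own_sample(nd, bundle$config$sample_labels)
    naive <- aggregate_naive(nd, bundle$config$sample_labels)
    expect_true(all(own$value <= naive$value + 1e-12))
  }
  shared0 <- generate_community(small_config(seed = 21, sharing_prob = 0))
  expect_true(all(shared0$tables$depth$assembly_sample ==
                    shared0$tables$depth$mapping_sample))
  nd <- normalize_depth(shared0$tables$depth)
  expect_equal(aggregate_own_sample(nd, shared0$config$sample_labels)$value,
               aggregate_naive(nd, shared0$config$sample_labels)$value)
})

test_that("profiles count each hit scaffold once and pool unclassified taxa", {
  hits <- dplyr::bind_rows(
    make_hits(scaffold_id = "s1", protein_index = 1L),
    make_hits(scaffold_id = "s1", protein_index = 2L),
    make_hits(scaffold_id = "s1", protein_index = 3L),
    make_hits(scaffold_id = "s9", protein_index = 1L)
  )
  bins <- tibble::tibble(scaffold_id = "s1", bin_id = "b1")
  scaf <- tibble::tibble(id = c("s1", "s9"), classification = c("d__B;p__X", ""))
  binl <- tibble::tibble(id = "b1", classification = "d__B;p__X")
  depth <- dplyr::bind_rows(
    make_depth("s1", "50", "50", 2.0),
    make_depth("s9", "50", "50", 1.5)
  )
  prof <- profile_by_taxon_gene(dedupe_hits(hits), bins, scaf, binl, depth,
                                samples = c("50", "70"))
  x <- prof[prof$taxon == "X" & prof$sample == "50", ]
  expect_equal(x$value, 2.0)  # three proteins on s1 contribute its depth once
  uncl <- prof[prof$taxon == "unclassified" & prof$sample == "50", ]
  expect_equal(uncl$value, 1.5)  # not dropped
  expect_equal(prof$value[prof$sample == "70"], c(0, 0))
})

test_that("a hit scaffold without an own-sample depth record is an error", {
  hits <- make_hits(scaffold_id = "s1")
  bins <- tibble::tibble(scaffold_id = character(), bin_id = character())
  scaf <- tibble::tibble(id = "s1", classification = "d__B")
  binl <- tibble::tibble(id = character(), classification = character())
  depth <- make_depth("s1", "50", "70", 1)  # cross-mapping only
  expect_error(
    profile_by_taxon_gene(hits, bins, scaf, binl, depth, samples = c("50", "70")),
    "own-sample depth record: s1")
})

test_that("profiles conserve: taxa sum to the pooled profile", {
  bundle <- generate_community(small_config(seed = 13))
  prof <- bundle_profiles(bundle)
  per_taxon <- prof %>%
    dplyr::group_by(family, sample) %>%
    dplyr::summarise(value = sum(value), .groups = "drop")
  # pooled: same computation at domain rank collapses most taxa; instead
  # recompute with all scaffolds under one label by classifying at a rank
  # where everything shares the domain only if bacterial+archaeal mix --
  # so compare against a direct own-sample sum over all hit scaffolds
  t <- bundle$tables
  hits <- dedupe_hits(filter_hits(t$hits))
  nd <- normalize_depth(t$depth)
  direct <- hits %>%
    dplyr::distinct(family, scaffold_id) %>%
    dplyr::inner_join(nd, by = "scaffold_id", relationship = "many-to-many") %>%
    dplyr::filter(assembly_sample == mapping_sample) %>%
    dplyr::group_by(family, sample = mapping_sample) %>%
    dplyr::summarise(value = sum(norm_depth), .groups = "drop")
  m <- dplyr::left_join(per_taxon, direct, by = c("family", "sample"))
  m$value.y[is.na(m$value.y)] <- 0
  expect_equal(m$value.x, m$value.y)
})
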