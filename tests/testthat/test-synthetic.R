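# The synthetic community generator: determinism, conservation, planted
# truth, and configuration validation.

test_that("a fixed seed reproduces the bundle and peak table exactly", {
  cfg <- small_config(seed = 1)
  b1 <- generate_community(cfg)
  b2 <- generate_community(cfg)
  expect_identical(b1, b2)
  expect_identical(generate_lipid_peaks(b1), generate_lipid_peaks(b2))
  # and written bundles are byte-identical
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_bundle(b1, d1); write_bundle(b2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
  b3 <- generate_community(small_config(seed = 2))
  expect_false(identical(b1$tables$depth, b3$tables$depth))
})

test_that("without strain sharing every mapping is an own-sample mapping", {
  b <- generate_community(small_config(seed = 4, sharing_prob = 0))
  expect_true(all(b$tables$depth$assembly_sample ==
                    b$tables$depth$mapping_sample))
})

test_that("depth times length sums to the mapping's total reads (conservation)", {
  b <- generate_community(small_config(seed = 6))
  cfg <- b$config
  check <- b$tables$depth %>%
    dplyr::group_by(assembly_sample, mapping_sample) %>%
    dplyr::summarise(
      summed = sum(avg_depth * cfg$scaffold_len_bp),
      total = dplyr::first(mapping_total_reads), .groups = "drop")
  expect_equal(check$summed, check$total)
})

test_that("planted families land only in their phyla when bins are clean", {
  cfg <- small_config(seed = 9, bin_contamination = 0)
  b <- generate_community(cfg)
  t <- b$tables
  hits <- dedupe_hits(filter_hits(t$hits))
  presence <- presence_by_unit(hits, t$bins)
  binl <- t$bin_lineages
  names(binl) <- c("id", "classification")
  mag_phyla <- setNames(lineage_at_rank(binl$classification, "phylum"), binl$id)
  mss_mags <- presence$unit[presence$family == "mss" &
                              presence$unit_type == "mag"]
  expect_true(all(mag_phyla[mss_mags] == "Desulfobacterota"))
  # exhaustive: no MAG outside the planted phylum carries any mss hit
  other_mags <- names(mag_phyla)[mag_phyla != "Desulfobacterota"]
  expect_length(intersect(mss_mags, other_mags), 0)
})

test_that("decoy hits sit exactly on the thresholds and are all rejected", {
  b <- generate_community(small_config(seed = 10))
  hits <- b$tables$hits
  decoy_ev <- hits[hits$evalue == 1e-30, ]
  decoy_id <- hits[hits$pident == 29.99, ]
  expect_gt(nrow(decoy_ev), 0)
  expect_gt(nrow(decoy_id), 0)
  kept <- filter_hits(hits)
  expect_equal(nrow(kept) + nrow(decoy_ev) + nrow(decoy_id), nrow(hits))
  expect_true(all(kept$evalue < 1e-30 & kept$pident >= 30))
  # surviving hits are exactly the planted ones (protein index 7 by design)
  expect_true(all(kept$protein_index == 7L))
})

test_that("contaminant scaffolds come from a different phylum than their bin", {
  b <- generate_community(small_config(seed = 12, bin_contamination = 0.3))
  prov <- b$truth$bin_provenance
  contam <- prov[prov$role == "contaminant", ]
  expect_gt(nrow(contam), 0)
  genome_of <- setNames(b$truth$scaffolds$genome, b$truth$scaffolds$scaffold_id)
  phylum_of <- setNames(b$truth$genomes$phylum, b$truth$genomes$genome)
  bin_genome <- setNames(prov$source_genome[prov$role == "own"],
                         prov$bin_id[prov$role == "own"])
  expect_true(all(phylum_of[genome_of[contam$scaffold_id]] !=
                    phylum_of[bin_genome[contam$bin_id]]))
  # and every scaffold is in at most one bin
  expect_false(anyDuplicated(prov$scaffold_id) > 0)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(community_config(sharing_prob = 1.5), "sharing_prob")
  expect_error(community_config(n_genomes = 0), "n_genomes")
  expect_error(community_config(bin_completeness = -0.1), "bin_completeness")
  expect_error(community_config(planted_families = list(mss = "NotAPhylum")),
               "planted_families")
  expect_error(generate_community(list()), "community_config")
  b <- generate_community(small_config(seed = 1))
  expect_error(generate_lipid_peaks(b, producer_map = c(nope = "brGDGT-1a")),
               "planted families")
})

test_that("matrix effects scale analyte and standard equally, cancelling on normalization", {
  b <- generate_community(small_config(seed = 14))
  peaks <- generate_lipid_peaks(b, producer_map = c(mss = "brGDGT-1a"))
  q1 <- quantify_lipids(peaks)
  # doubling the matrix factor at one depth: scale all areas there by 2
  s0 <- peaks$sample[1]
  peaks2 <- dplyr::mutate(peaks,
    area = ifelse(sample == s0, area * 2, area),
    is_area = ifelse(sample == s0, is_area * 2, is_area))
  q2 <- quantify_lipids(peaks2)
  expect_equal(q1$response, q2$response)
})
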