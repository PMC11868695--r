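# MAG fractions, co-occurrence, profile comparison, candidate ranking.

make_mag_world <- function() {
  mags <- tibble::tibble(bin_id = c("m1", "m2", "m3", "m4"),
                         sample = c("50", "50", "50", "100"))
  binl <- tibble::tibble(
    id = c("m1", "m2", "m3", "m4"),
    classification = c("d__B;p__X", "d__B;p__X", "d__B;p__Y", "d__B;p__X"))
  list(mags = mags, binl = binl)
}

test_that("MAG fractions count hit-bearing MAGs per taxon and sample", {
  w <- make_mag_world()
  presence <- tibble::tibble(family = "mss", unit = c("m1", "m3"),
                             unit_type = "mag", n_hit_scaffolds = 1L)
  cells <- mag_fraction_matrix(presence, w$mags, w$binl)
  x50 <- cells[cells$taxon == "X" & cells$sample == "50", ]
  expect_equal(x50$n_mags, 2L)
  expect_equal(x50$n_with_family, 1L)
  expect_equal(x50$fraction, 0.5)
  y50 <- cells[cells$taxon == "Y" & cells$sample == "50", ]
  expect_equal(y50$fraction, 1)
  x100 <- cells[cells$taxon == "X" & cells$sample == "100", ]
  expect_equal(x100$fraction, 0)
  expect_true(all(cells$fraction >= 0 & cells$fraction <= 1))
  expect_true(all(cells$n_with_family <= cells$n_mags))
  # the arithmetic matches reported fractions like 19 of 28 MAGs
  expect_equal(19 / 28, 0.6785714, tolerance = 1e-6)
})

test_that("co-occurrence counts intersections per taxon", {
  w <- make_mag_world()
  presence <- dplyr::bind_rows(
    tibble::tibble(family = "mss", unit = c("m1", "m2"), unit_type = "mag",
                   n_hit_scaffolds = 1L),
    tibble::tibble(family = "ger", unit = c("m2", "m3"), unit_type = "mag",
                   n_hit_scaffolds = 1L))
  rep <- gene_cooccurrence(presence, w$mags, w$binl, pair = c("mss", "ger"))
  x <- rep[rep$taxon == "X", ]
  expect_equal(x$n_both, 1L)       # m2
  expect_equal(x$n_a_only, 1L)     # m1
  expect_equal(x$n_b_only, 0L)
  y <- rep[rep$taxon == "Y", ]
  expect_equal(y$n_both, 0L)       # disjoint in Y
  expect_true(all(rep$n_both <= pmin(rep$n_a, rep$n_b)))
})

test_that("Spearman comparison matches hand-computed rho and enforces n >= 3", {
  lp <- tibble::tibble(sample = as.character(1:4), value = c(1, 2, 3, 4))
  same <- compare_profiles(lp, lp)
  expect_equal(same$rho, 1)
  rev <- tibble::tibble(sample = as.character(1:4), value = c(4, 3, 2, 1))
  expect_equal(compare_profiles(lp, rev)$rho, -1)
  gp <- tibble::tibble(sample = as.character(1:4), value = c(1, 3, 2, 4))
  cmp <- compare_profiles(lp, gp)
  # hand Spearman, no ties: 1 - 6*sum(d^2)/(n(n^2-1)) = 1 - 6*2/60 = 0.8
  expect_equal(cmp$rho, 0.8)
  expect_equal(cmp$n, 4)
  short <- tibble::tibble(sample = c("1", "2"), value = c(1, 2))
  expect_error(compare_profiles(short, short), "at least 3")
})

test_that("candidate ranking sorts by rho, breaks ties alphabetically, drops zero profiles", {
  lp <- tibble::tibble(sample = as.character(1:5), value = c(1, 2, 3, 4, 5))
  gp <- dplyr::bind_rows(
    tibble::tibble(taxon = "Zeta", family = "mss", sample = as.character(1:5),
                   value = c(1, 2, 3, 4, 5)),
    tibble::tibble(taxon = "Alpha", family = "mss", sample = as.character(1:5),
                   value = c(1, 2, 3, 4, 5)),
    tibble::tibble(taxon = "Noise", family = "mss", sample = as.character(1:5),
                   value = c(5, 1, 4, 2, 3)),
    tibble::tibble(taxon = "Silent", family = "mss", sample = as.character(1:5),
                   value = rep(0, 5)))
  ranked <- rank_candidate_producers(lp, gp, "mss")
  expect_equal(ranked$taxon, c("Alpha", "Zeta", "Noise"))
  expect_false("Silent" %in% ranked$taxon)
  none <- rank_candidate_producers(
    lp, tibble::tibble(taxon = "A", family = "mss",
                       sample = as.character(1:5), value = 0), "mss")
  expect_equal(nrow(none), 0)
})

test_that("planted producers are recovered from contamination-free bundles", {
  for (seed in c(2, 5, 8)) {
    cfg <- small_config(seed = seed, bin_contamination = 0)
    bundle <- generate_community(cfg)
    peaks <- generate_lipid_peaks(bundle,
                                  producer_map = c(mss = "brGDGT-1a",
                                                   gms = "brGMGT-1a"))
    prof <- bundle_profiles(bundle)
    lq <- quantify_lipids(peaks)
    for (fm in c("mss", "gms")) {
      lipid <- c(mss = "brGDGT-1a", gms = "brGMGT-1a")[[fm]]
      lp <- lq %>% dplyr::filter(lipid == !!lipid) %>%
        dplyr::select(sample, value = response)
      ranked <- rank_candidate_producers(lp, prof, fm)
      planted <- bundle$config$planted_families[[fm]]
      expect_equal(ranked$taxon[1], planted)
    }
  }
})

test_that("joint planting yields exact co-occurrence counts from ground truth", {
  cfg <- community_config(
    n_genomes = 12, scaffolds_per_genome = 6, scaffold_len_bp = 10000,
    reads_per_sample = 5e5,
    phylum_pool = c("Desulfobacterota", "Planctomycetota"),
    planted_families = list(mss = "Desulfobacterota",
                            ger = "Desulfobacterota"),
    bin_contamination = 0, bin_completeness = 1, unbinned_frac = 0,
    seed = 17)
  bundle <- generate_community(cfg)
  t <- bundle$tables
  hits <- dedupe_hits(filter_hits(t$hits))
  presence <- presence_by_unit(hits, t$bins)
  binl <- t$bin_lineages
  names(binl) <- c("id", "classification")
  rep <- gene_cooccurrence(presence, t$mags, binl, pair = c("mss", "ger"))
  des <- rep[rep$taxon == "Desulfobacterota", ]
  # every Desulfobacterota MAG carries both planted genes
  n_mags <- sum(lineage_at_rank(binl$classification, "phylum") ==
                  "Desulfobacterota")
  expect_equal(des$n_both, n_mags)
  expect_equal(des$n_a_only, 0L)
  expect_false("Planctomycetota" %in% rep$taxon)
})
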