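# The two complementary attribution analyses, plus co-occurrence and
# quantitative profile comparison. (1) MAG-fraction matrices: for each
# taxon and sample, the fraction of that taxon's MAGs binned in the sample
# that encode a key biosynthetic gene -- a diversity/robustness view, since
# a high fraction over many MAGs is unlikely to be spurious binning noise.
# (2) Normalized-depth profiles of all hit scaffolds, binned or not (built
# in profile_by_taxon_gene()). Co-occurrence of two gene families within
# one MAG flags genomes with the full pathway. Profile comparison uses
# Spearman rank correlation, an ordinal convention chosen because depth
# profiles are non-Gaussian and the scientific claims are ordinal
# ("maximum at 1000 m").

#' MAG-fraction matrix
#'
#' For each gene family, taxon at `rank` and binning sample: the number of
#' MAGs (`n_mags`), the number carrying at least one hit of the family
#' (`n_with_family`), and their ratio. MAGs are grouped by the sample they
#' were binned from. MAGs unclassified at `rank` form their own row.
#'
#' @param presence Presence tibble from [presence_by_unit()] (only
#'   `unit_type == "mag"` rows are used).
#' @param mags MAG tibble (`bin_id`, `sample`).
#' @param bin_lineages Lineage tibble (`id`, `classification`).
#' @param rank Reporting rank (default `"phylum"`).
#' @param families Families to report; defaults to those present.
#' @return A tibble (`family`, `taxon`, `sample`, `n_mags`,
#'   `n_with_family`, `fraction`) with a cell for every (taxon, sample)
#'   that has at least one MAG.
#' @export
mag_fraction_matrix <- function(presence, mags, bin_lineages, rank = "phylum",
                                families = NULL) {
  check_columns(mags, c("bin_id", "sample"), "MAG table")
  check_columns(presence, c("family", "unit", "unit_type"), "presence table")
  families <- families %||% sort(unique(presence$family))
  lookup <- setNames(bin_lineages$classification, bin_lineages$id)
  mag_tax <- mags %>%
    mutate(classification = dplyr::coalesce(unname(lookup[.data$bin_id]), ""),
           taxon = lineage_at_rank(.data$classification, rank))
  cells <- mag_tax %>% count(.data$taxon, .data$sample, name = "n_mags")
  flagged <- presence %>%
    filter(.data$unit_type == "mag", .data$family %in% families) %>%
    distinct(.data$family, bin_id = .data$unit) %>%
    inner_join(mag_tax, by = "bin_id") %>%
    count(.data$family, .data$taxon, .data$sample, name = "n_with_family")
  tidyr::crossing(family = families, cells) %>%
    left_join(flagged, by = c("family", "taxon", "sample")) %>%
    mutate(n_with_family = dplyr::coalesce(.data$n_with_family, 0L),
           fraction = .data$n_with_family / .data$n_mags) %>%
    arrange(.data$family, .data$taxon, .data$sample)
}

#' Within-MAG co-occurrence of two gene families
#'
#' Counts, per taxon at `rank`, the MAGs carrying both families of a pair
#' and the MAGs carrying each family alone.
#'
#' @inheritParams mag_fraction_matrix
#' @param pair Character vector of two family names.
#' @return A tibble (`taxon`, `family_a`, `family_b`, `n_both`,
#'   `n_a_only`, `n_b_only`, `n_a`, `n_b`).
#' @export
gene_cooccurrence <- function(presence, mags, bin_lineages, pair,
                              rank = "phylum") {
  if (length(pair) != 2L) tl_abort("pair must name exactly two families")
  check_columns(presence, c("family", "unit", "unit_type"), "presence table")
  lookup <- setNames(bin_lineages$classification, bin_lineages$id)
  mag_tax <- mags %>%
    mutate(classification = dplyr::coalesce(unname(lookup[.data$bin_id]), ""),
           taxon = lineage_at_rank(.data$classification, rank))
  flag <- presence %>%
    filter(.data$unit_type == "mag", .data$family %in% pair) %>%
    distinct(.data$family, bin_id = .data$unit) %>%
    inner_join(mag_tax, by = "bin_id")
  sets <- split(flag$bin_id, flag$family)
  a_set <- unique(sets[[pair[1]]]) %||% character()
  b_set <- unique(sets[[pair[2]]]) %||% character()
  taxa <- sort(unique(mag_tax$taxon))
  purrr::map_dfr(taxa, function(tx) {
    ids <- mag_tax$bin_id[mag_tax$taxon == tx]
    a <- intersect(a_set, ids); b <- intersect(b_set, ids)
    tibble(taxon = tx, family_a = pair[1], family_b = pair[2],
           n_both = length(intersect(a, b)),
           n_a_only = length(setdiff(a, b)),
           n_b_only = length(setdiff(b, a)),
           n_a = length(a), n_b = length(b))
  }) %>%
    filter(.data$n_a > 0 | .data$n_b > 0)
}

#' Spearman comparison of a lipid profile with a gene profile
#'
#' Rank correlation over the shared samples, average ranks for ties. At
#' least three shared samples are required.
#'
#' @param lipid_profile Tibble (`sample`, `value`) of per-sample lipid
#'   responses.
#' @param gene_profile Tibble (`sample`, `value`) of per-sample summed
#'   normalized depth for one (taxon, family).
#' @return A list with `rho` and `n` (shared samples).
#' @export
compare_profiles <- function(lipid_profile, gene_profile) {
  check_columns(lipid_profile, c("sample", "value"), "lipid profile")
  check_columns(gene_profile, c("sample", "value"), "gene profile")
  shared <- inner_join(
    lipid_profile %>% select("sample", lipid = "value"),
    gene_profile %>% select("sample", gene = "value"),
    by = "sample")
  if (nrow(shared) < 3) {
    tl_abort(sprintf("only %d shared sample(s); need at least 3 for a rank correlation",
                     nrow(shared)),
             class = "tetralink_insufficient_data_error")
  }
  list(rho = suppressWarnings(cor(shared$lipid, shared$gene, method = "spearman")),
       n = nrow(shared))
}

#' Rank candidate producer taxa for a lipid
#'
#' Correlates the lipid's per-sample profile with every taxon's gene
#' profile for one family and sorts taxa by Spearman rho, descending, ties
#' broken alphabetically. Taxa whose gene profile is all zero are excluded.
#'
#' @param lipid_profile Tibble (`sample`, `value`).
#' @param gene_profiles Tibble (`taxon`, `family`, `sample`, `value`) from
#'   [profile_by_taxon_gene()].
#' @param family The gene family to rank on.
#' @return A tibble (`taxon`, `rho`, `n`) in rank order.
#' @export
rank_candidate_producers <- function(lipid_profile, gene_profiles, family) {
  check_columns(gene_profiles, c("taxon", "family", "sample", "value"),
                "gene profiles")
  fam <- gene_profiles %>% filter(.data$family == !!family)
  nz <- fam %>%
    group_by(.data$taxon) %>%
    summarise(any_nonzero = any(.data$value > 0), .groups = "drop") %>%
    filter(.data$any_nonzero) %>%
    pull("taxon")
  if (length(nz) == 0) return(tibble(taxon = character(), rho = numeric(),
                                     n = integer()))
  purrr::map_dfr(nz, function(tx) {
    cmp <- compare_profiles(lipid_profile,
                            fam %>% filter(.data$taxon == tx) %>%
                              select("sample", "value"))
    tibble(taxon = tx, rho = cmp$rho, n = cmp$n)
  }) %>%
    arrange(desc(.data$rho), .data$taxon)
}
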