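# Depth normalization and taxon-by-gene abundance profiles.
#
# Each scaffold has an average depth (mapped reads per base pair) under each
# sample's read mapping, and each mapping has a total mapped read count.
# Depth is normalized per a fixed number of mapped reads (1e8 by default) so
# samples of different sequencing effort are comparable. When profiles are
# aggregated over the scaffolds of a taxon, only the mapping of the sample
# from which each scaffold was assembled is summed (the "own-sample" rule):
# reads from one sample can map to similar strains assembled in several
# samples, and summing all mappings would count those reads multiple times.
# The naive all-mappings sum is retained for comparison.

#' Normalize scaffold depth per a fixed number of mapped reads
#'
#' Adds a `norm_depth` column: `avg_depth * scale / mapping_total_reads`,
#' i.e. reads per base pair per `scale` mapped reads of the mapping sample.
#'
#' @param depth A depth tibble ([read_depth_table()]).
#' @param scale Mapped-read scale (default `1e8`).
#' @return The depth tibble with `norm_depth` added.
#' @export
normalize_depth <- function(depth, scale = 1e8) {
  check_scalar(scale, "scale", min = 0, strict_min = TRUE)
  check_columns(depth, c("avg_depth", "mapping_total_reads"), "depth table")
  if (any(depth$mapping_total_reads <= 0)) {
    tl_abort("mapping_total_reads must be > 0",
             class = "tetralink_validation_error")
  }
  if (any(depth$avg_depth < 0)) {
    tl_abort("avg_depth must be >= 0", class = "tetralink_validation_error")
  }
  depth %>% mutate(norm_depth = .data$avg_depth * scale / .data$mapping_total_reads)
}

# shared zero-filled per-sample summation
sum_by_sample <- function(depth, samples) {
  prof <- depth %>%
    group_by(sample = .data$mapping_sample) %>%
    summarise(value = sum(.data$norm_depth), .groups = "drop")
  tibble(sample = samples) %>%
    left_join(prof, by = "sample") %>%
    mutate(value = dplyr::coalesce(.data$value, 0))
}

#' Own-sample aggregation of normalized depth
#'
#' For each sample, sums normalized depth only over records whose assembly
#' sample equals the mapping sample, so reads mapping onto similar strains
#' assembled from other samples are never counted. Samples with no
#' qualifying scaffolds are reported as 0, not dropped.
#'
#' @param depth A normalized depth tibble (see [normalize_depth()])
#'   restricted to the scaffolds of interest.
#' @param samples Character vector giving the full, ordered sample set for
#'   zero-filling; defaults to the samples seen in `depth`.
#' @return A tibble (`sample`, `value`).
#' @export
aggregate_own_sample <- function(depth, samples = NULL) {
  check_columns(depth, c("assembly_sample", "mapping_sample", "norm_depth"),
                "normalized depth table")
  samples <- samples %||% sample_order(c(depth$mapping_sample, depth$assembly_sample))
  depth %>%
    filter(.data$assembly_sample == .data$mapping_sample) %>%
    sum_by_sample(samples)
}

#' Naive all-mappings aggregation of normalized depth
#'
#' The sum the own-sample rule corrects: for each sample, sums normalized
#' depth over all records mapped by that sample regardless of where the
#' scaffold was assembled. Overestimates taxa whose strains recur across
#' samples; equals [aggregate_own_sample()] when strains are sample-private.
#'
#' @inheritParams aggregate_own_sample
#' @return A tibble (`sample`, `value`).
#' @export
aggregate_naive <- function(depth, samples = NULL) {
  check_columns(depth, c("mapping_sample", "norm_depth"),
                "normalized depth table")
  samples <- samples %||% sample_order(c(depth$mapping_sample, depth$assembly_sample))
  sum_by_sample(depth, samples)
}

#' Taxon-by-gene normalized depth profiles
#'
#' Builds one per-sample profile per (taxon at `rank`, gene family) from the
#' hit-bearing scaffolds: hits are reduced to scaffold presence (a scaffold
#' with several hits of one family contributes its depth once), each
#' scaffold's unit (MAG or itself) is resolved to a lineage, and normalized
#' depth is aggregated per taxon with the own-sample rule (or the naive
#' all-mappings sum). Scaffolds unclassified at `rank` are pooled under
#' `"unclassified"`, never dropped.
#'
#' @param hits Deduplicated hit tibble.
#' @param bins Bin membership tibble.
#' @param scaffold_lineages,bin_lineages Lineage tibbles (`id`,
#'   `classification`).
#' @param depth Depth tibble ([read_depth_table()]).
#' @param rank Reporting rank (default `"phylum"`).
#' @param scale Mapped-read scale (default `1e8`).
#' @param samples Ordered sample set; defaults to all samples in `depth`.
#' @param mode `"own"` (own-sample rule, default) or `"naive"`.
#' @return A tibble (`taxon`, `family`, `sample`, `value`), zero-filled over
#'   the full sample set.
#' @export
profile_by_taxon_gene <- function(hits, bins, scaffold_lineages, bin_lineages,
                                  depth, rank = "phylum", scale = 1e8,
                                  samples = NULL, mode = c("own", "naive")) {
  mode <- match.arg(mode)
  samples <- samples %||% sample_order(c(depth$mapping_sample, depth$assembly_sample))
  sc <- hit_scaffold_units(hits, bins) %>%
    resolve_hit_taxonomy(scaffold_lineages, bin_lineages) %>%
    mutate(taxon = lineage_at_rank(.data$classification, rank))
  if (nrow(sc) == 0) {
    return(tibble(taxon = character(), family = character(),
                  sample = character(), value = numeric()))
  }
  ndepth <- normalize_depth(depth, scale = scale)
  # every hit scaffold must have a depth record for its own assembly sample
  own_scaffolds <- unique(ndepth$scaffold_id[
    ndepth$assembly_sample == ndepth$mapping_sample])
  missing <- setdiff(unique(sc$scaffold_id), own_scaffolds)
  if (length(missing) > 0) {
    tl_abort(sprintf("hit scaffold(s) lacking an own-sample depth record: %s",
                     paste(missing, collapse = ", ")),
             class = "tetralink_consistency_error")
  }
  recs <- sc %>%
    select("family", "taxon", "scaffold_id") %>%
    inner_join(ndepth, by = "scaffold_id", relationship = "many-to-many")
  if (mode == "own") {
    recs <- recs %>% filter(.data$assembly_sample == .data$mapping_sample)
  }
  prof <- recs %>%
    group_by(.data$taxon, .data$family, sample = .data$mapping_sample) %>%
    summarise(value = sum(.data$norm_depth), .groups = "drop")
  tidyr::crossing(distinct(sc, .data$taxon, .data$family),
                  sample = samples) %>%
    left_join(prof, by = c("taxon", "family", "sample")) %>%
    mutate(value = dplyr::coalesce(.data$value, 0),
           sample = factor(.data$sample, levels = samples)) %>%
    arrange(.data$family, .data$taxon, .data$sample) %>%
    mutate(sample = as.character(.data$sample))
}
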