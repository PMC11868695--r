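# Taxonomic resolution of hit-bearing units. Binned scaffolds inherit their
# bin's classification; unbinned scaffolds keep their own. Bin classification
# follows a majority vote over member-scaffold lineages: support is counted
# hierarchically (a scaffold classified p__X also supports d__Bacteria), and
# the bin is classified to the deepest node whose support strictly exceeds
# f of the total weight, degrading gracefully to shallower ranks on mixed
# bins. Real bin annotators vote with ORF bit scores, which lineage tables
# alone do not carry; weights here default to one per scaffold, with
# scaffold length as the natural alternative.

#' Majority classification of a bin from member-scaffold lineages
#'
#' Returns the deepest lineage whose weighted support, summed over scaffolds
#' whose lineage equals or descends from it, strictly exceeds
#' `f * total weight`. Ranks below that point are unclassified. At
#' `f >= 0.5` the winning taxon at any rank is unique. The result is
#' invariant under uniform rescaling of the weights.
#'
#' @param classification Character vector of member-scaffold lineage strings
#'   (canonical rank-prefixed form; `""` = unclassified).
#' @param weights Positive scaffold weights (scaffold counts by default,
#'   i.e. all 1; pass lengths for length-weighted votes).
#' @param f Support fraction in (0, 1\]; strictly-greater-than semantics.
#'   Default 0.5.
#' @return A single canonical lineage string (possibly `""`).
#' @examples
#' majority_classify_bin(
#'   c("d__Bacteria;p__X", "d__Bacteria;p__Y", "d__Bacteria;p__Z"),
#'   weights = c(0.4, 0.4, 0.2)
#' ) # "d__Bacteria": no phylum exceeds 0.5, the domain does
#' @export
majority_classify_bin <- function(classification, weights = NULL, f = 0.5) {
  if (length(classification) == 0) {
    tl_abort("majority_classify_bin needs at least one scaffold lineage")
  }
  check_scalar(f, "f", min = 0, max = 1, strict_min = TRUE)
  weights <- weights %||% rep(1, length(classification))
  if (length(weights) != length(classification) || any(weights <= 0)) {
    tl_abort("weights must be positive and match the number of lineages")
  }
  classification <- vapply(classification, canonical_lineage, character(1),
                           USE.NAMES = FALSE)
  total <- sum(weights)
  depths <- ifelse(nzchar(classification),
                   lengths(strsplit(classification, ";", fixed = TRUE)), 0L)
  for (d in 7:1) {
    at_depth <- depths >= d
    if (!any(at_depth)) next
    prefixes <- vapply(classification[at_depth], truncate_lineage, character(1),
                       depth = d, USE.NAMES = FALSE)
    support <- tapply(weights[at_depth], prefixes, sum)
    winners <- support[support > f * total]
    if (length(winners) > 0) {
      # at f >= 0.5 there can be only one; below that, take the best
      # supported, ties broken alphabetically for determinism
      best <- names(winners)[order(-winners, names(winners))][1]
      return(best)
    }
  }
  ""
}

#' Resolve the lineage of every hit-bearing unit
#'
#' Binned scaffolds take their bin's classification; unbinned scaffolds take
#' their own scaffold classification; units missing from both tables are
#' reported fully unclassified, never dropped.
#'
#' @param units A tibble from [presence_by_unit()] or
#'   `hit_scaffold_units()`, with columns `unit`, `unit_type` and (for
#'   unbinned units) `scaffold_id`.
#' @param scaffold_lineages Tibble (`id`, `classification`) of per-scaffold
#'   classifications.
#' @param bin_lineages Tibble (`id`, `classification`) of per-bin
#'   classifications.
#' @return The input with a `classification` column added.
#' @export
resolve_hit_taxonomy <- function(units, scaffold_lineages, bin_lineages) {
  check_columns(units, c("unit", "unit_type"), "unit table")
  check_columns(scaffold_lineages, c("id", "classification"), "scaffold lineage table")
  check_columns(bin_lineages, c("id", "classification"), "bin lineage table")
  scaf_lookup <- setNames(scaffold_lineages$classification, scaffold_lineages$id)
  bin_lookup <- setNames(bin_lineages$classification, bin_lineages$id)
  scaffold_id <- if ("scaffold_id" %in% names(units)) units$scaffold_id
                 else sub("^unbinned:", "", units$unit)
  cls <- ifelse(units$unit_type == "mag",
                unname(bin_lookup[units$unit]),
                unname(scaf_lookup[scaffold_id]))
  cls[is.na(cls)] <- ""
  units$classification <- vapply(cls, canonical_lineage, character(1),
                                 USE.NAMES = FALSE)
  units
}

#' Classify all bins by scaffold-lineage majority vote
#'
#' Convenience wrapper applying [majority_classify_bin()] to every bin in a
#' membership table.
#'
#' @param bins Bin membership tibble (`scaffold_id`, `bin_id`).
#' @param scaffold_lineages Tibble (`id`, `classification`).
#' @param weights Optional named vector of per-scaffold weights (e.g.
#'   lengths); default one per scaffold.
#' @param f Support fraction, see [majority_classify_bin()].
#' @return A tibble (`id`, `classification`), one row per bin.
#' @export
classify_bins <- function(bins, scaffold_lineages, weights = NULL, f = 0.5) {
  check_columns(bins, c("scaffold_id", "bin_id"), "bin table")
  lookup <- setNames(scaffold_lineages$classification, scaffold_lineages$id)
  bins %>%
    mutate(classification = dplyr::coalesce(unname(lookup[.data$scaffold_id]), ""),
           w = if (is.null(weights)) 1 else unname(weights[.data$scaffold_id])) %>%
    group_by(id = .data$bin_id) %>%
    summarise(classification = majority_classify_bin(.data$classification,
                                                     .data$w, f = f),
              .groups = "drop")
}
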