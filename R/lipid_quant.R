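# GDGT quantification from peak tables: adduct combination, internal-
# standard normalization, response units per litre, and relative
# abundances. Peak areas of the [M+H]+, [M+NH4]+ and [M+Na]+ ions of one
# species are combined where present; the combined area is divided by the
# internal standard's area in the same sample (cancelling per-sample matrix
# effects and instrument drift) and by the litres filtered. Because lipid
# species differ in response factors, responses are comparable across
# samples, not across species; an internal-standard response factor of 1
# is assumed.

#' Combine adduct peak areas for one species in one sample
#'
#' Sums the areas of the adducts present; absent adducts contribute
#' nothing. Monotone: adding an adduct never decreases the combined area.
#'
#' @param areas Numeric vector of adduct areas (>= 0); may be empty.
#' @return The combined area.
#' @export
combine_adduct_areas <- function(areas) {
  if (length(areas) == 0) return(0)
  if (any(areas < 0)) tl_abort("adduct areas must be >= 0")
  sum(areas)
}

#' Internal-standard normalization to response units per litre
#'
#' `(combined_area / is_area) / litres`. Invariant under per-sample
#' multiplicative matrix effects applied to all areas including the
#' standard.
#'
#' @param combined_area Combined adduct area (>= 0).
#' @param is_area Internal-standard area (> 0).
#' @param litres Litres filtered (> 0).
#' @return Response units per litre.
#' @export
is_normalize <- function(combined_area, is_area, litres = 1) {
  if (any(is_area <= 0)) {
    tl_abort("is_area must be > 0", class = "tetralink_validation_error")
  }
  if (any(litres <= 0)) {
    tl_abort("litres must be > 0", class = "tetralink_validation_error")
  }
  if (any(combined_area < 0)) {
    tl_abort("combined_area must be >= 0", class = "tetralink_validation_error")
  }
  (combined_area / is_area) / litres
}

#' Quantify lipid species from a peak table
#'
#' Combines adduct areas per (lipid, sample), applies internal-standard
#' normalization and the litres filtered, and returns one response value
#' per (lipid, sample).
#'
#' @param peaks A peak tibble ([read_peak_table()]): `lipid`, `sample`,
#'   `adduct`, `area`, `is_area`, `litres`. `is_area` and `litres` must be
#'   consistent within a sample.
#' @param lipids Optional subset of lipid names to report.
#' @return A tibble (`lipid`, `sample`, `combined_area`, `response`).
#' @export
quantify_lipids <- function(peaks, lipids = NULL) {
  check_columns(peaks, c("lipid", "sample", "adduct", "area",
                         "is_area", "litres"), "peak table")
  if (!is.null(lipids)) peaks <- peaks %>% filter(.data$lipid %in% lipids)
  inconsistent <- peaks %>%
    group_by(.data$sample) %>%
    summarise(bad = n_distinct(.data$is_area) > 1 | n_distinct(.data$litres) > 1,
              .groups = "drop") %>%
    filter(.data$bad)
  if (nrow(inconsistent) > 0) {
    tl_abort(sprintf("is_area/litres differ within sample(s): %s",
                     paste(inconsistent$sample, collapse = ", ")),
             class = "tetralink_validation_error")
  }
  peaks %>%
    group_by(.data$lipid, .data$sample) %>%
    summarise(combined_area = combine_adduct_areas(.data$area),
              is_area = first(.data$is_area),
              litres = first(.data$litres),
              .groups = "drop") %>%
    mutate(response = is_normalize(.data$combined_area, .data$is_area,
                                   .data$litres)) %>%
    select("lipid", "sample", "combined_area", "response") %>%
    arrange(.data$lipid, .data$sample)
}

#' Per-sample relative abundances over a reported lipid set
#'
#' Fraction of each lipid's response in the summed response of the sample.
#' Samples where every reported lipid is zero are undefined and returned as
#' `NA`, never 0/0.
#'
#' @param profiles A tibble (`lipid`, `sample`, `response`) from
#'   [quantify_lipids()].
#' @return The input with a `rel_abund` column added (sums to 1 per defined
#'   sample).
#' @export
relative_abundance_profile <- function(profiles) {
  check_columns(profiles, c("lipid", "sample", "response"), "lipid profiles")
  profiles %>%
    group_by(.data$sample) %>%
    mutate(total = sum(.data$response),
           rel_abund = if_else(.data$total > 0,
                               .data$response / .data$total, NA_real_)) %>%
    ungroup() %>%
    select(-"total")
}
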