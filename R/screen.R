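# Homologue screening. Hits from a protein BLAST of gene-family queries
# against all predicted proteins are filtered with a strict e-value cutoff
# (< 1e-30) and an inclusive identity cutoff (>= 30%), reduced to one hit
# per protein, and collapsed to presence per unit (MAG, or the scaffold
# itself when unbinned). Presence, not hit multiplicity, is what the
# downstream abundance and fraction analyses consume, so tandem duplicates
# never inflate counts.

#' Screening thresholds
#'
#' @param evalue_max Exclusive e-value threshold: hits are kept only when
#'   `evalue < evalue_max`. Default `1e-30`.
#' @param pident_min Inclusive percent-identity threshold: hits are kept
#'   only when `pident >= pident_min`. Default `30`.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(evalue_max = 1e-30, pident_min = 30) {
  check_scalar(evalue_max, "evalue_max", min = 0, strict_min = TRUE)
  check_scalar(pident_min, "pident_min", min = 0, max = 100)
  structure(list(evalue_max = evalue_max, pident_min = pident_min),
            class = "screen_config")
}

#' Filter homologue hits by e-value and identity
#'
#' Keeps a hit iff `evalue < evalue_max` (strict) and `pident >= pident_min`
#' (inclusive). Order is preserved and the operation is idempotent.
#'
#' @param hits A hit tibble (from [read_blast6()]) with at least `evalue`
#'   and `pident` columns.
#' @param cfg A [screen_config()].
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, cfg = screen_config()) {
  check_columns(hits, c("evalue", "pident"), "hit table")
  hits %>% filter(.data$evalue < cfg$evalue_max, .data$pident >= cfg$pident_min)
}

#' Reduce hits to one per protein
#'
#' Keeps at most one hit per (family, scaffold, protein index): the lowest
#' e-value, ties broken by highest bitscore, then first occurrence.
#'
#' @param hits A filtered hit tibble.
#' @return The deduplicated hit tibble.
#' @export
dedupe_hits <- function(hits) {
  check_columns(hits, c("family", "scaffold_id", "protein_index",
                        "evalue", "bitscore"), "hit table")
  hits %>%
    mutate(.ord = row_number()) %>%
    group_by(.data$family, .data$scaffold_id, .data$protein_index) %>%
    arrange(.data$evalue, desc(.data$bitscore), .data$.ord, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$.ord) %>%
    select(-".ord")
}

#' Collapse hits to presence per unit
#'
#' The unit of presence is the MAG when the scaffold is binned, else the
#' scaffold itself (unit id `"unbinned:<scaffold_id>"`). A MAG is flagged
#' present for a family iff at least one of its scaffolds carries a
#' surviving hit.
#'
#' @param hits A deduplicated hit tibble.
#' @param bins Bin membership tibble (`scaffold_id`, `bin_id`); scaffolds
#'   absent from it are unbinned.
#' @return A tibble with one row per (family, unit): columns `family`,
#'   `unit`, `unit_type` (`"mag"` or `"unbinned"`), `n_hit_scaffolds`.
#' @export
presence_by_unit <- function(hits, bins) {
  check_columns(hits, c("family", "scaffold_id"), "hit table")
  check_columns(bins, c("scaffold_id", "bin_id"), "bin table")
  dup <- bins$scaffold_id[duplicated(bins$scaffold_id)]
  if (length(dup) > 0) {
    tl_abort(sprintf("scaffold '%s' is assigned to more than one bin", dup[1]),
             class = "tetralink_consistency_error")
  }
  hit_scaffold_units(hits, bins) %>%
    group_by(.data$family, .data$unit, .data$unit_type) %>%
    summarise(n_hit_scaffolds = n_distinct(.data$scaffold_id), .groups = "drop") %>%
    arrange(.data$family, .data$unit)
}

# one row per (family, hit scaffold) with its unit; shared by presence and
# the depth-profile builder
hit_scaffold_units <- function(hits, bins) {
  hits %>%
    distinct(.data$family, .data$scaffold_id) %>%
    left_join(bins, by = "scaffold_id") %>%
    mutate(
      unit_type = if_else(is.na(.data$bin_id), "unbinned", "mag"),
      unit = if_else(is.na(.data$bin_id),
                     paste0("unbinned:", .data$scaffold_id), .data$bin_id)
    ) %>%
    select(-"bin_id")
}

#' Smith-Waterman local-alignment percent identity
#'
#' Optimal local alignment of two protein sequences under simple scoring
#' (constant match/mismatch scores and a linear gap penalty), returning the
#' percent identity of the best-scoring alignment: matches divided by
#' alignment columns (gap columns included) times 100. This is a validation
#' oracle for synthetic hit tables, not a database-search replacement; it
#' uses no substitution matrix and computes no e-value.
#'
#' If the optimal local alignment is empty (best score 0, e.g. disjoint
#' alphabets under positive match score), identity is undefined and `NA`
#' is returned with the score 0.
#'
#' @param seq_a,seq_b Non-empty protein sequences (single strings).
#' @param match Match score (default 2).
#' @param mismatch Mismatch score (default -1).
#' @param gap Linear gap penalty per gapped column (default -2; applied as
#'   an addition, so use a negative value).
#' @return A list with `identity` (percent or `NA`), `score`, `matches`,
#'   `columns`.
#' @export
sw_identity <- function(seq_a, seq_b, match = 2, mismatch = -1, gap = -2) {
  if (!is.character(seq_a) || length(seq_a) != 1L || !nzchar(seq_a) ||
      !is.character(seq_b) || length(seq_b) != 1L || !nzchar(seq_b)) {
    tl_abort("sequences must be single non-empty strings")
  }
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  # traceback pointers: 0 stop, 1 diagonal, 2 up (gap in b), 3 left (gap in a)
  P <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      diag <- H[i, j] + sub[j]
      up <- H[i, j + 1] + gap
      left <- H[i + 1, j] + gap
      best <- max(0, diag, up, left)
      H[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- if (best == 0) 0L else if (best == diag) 1L
                         else if (best == up) 2L else 3L
    }
  }
  score <- max(H)
  if (score <= 0) {
    return(list(identity = NA_real_, score = 0, matches = 0L, columns = 0L))
  }
  idx <- which(H == score, arr.ind = TRUE)[1, ]
  i <- idx[1]; j <- idx[2]
  matches <- 0L; columns <- 0L
  while (P[i, j] != 0L) {
    columns <- columns + 1L
    if (P[i, j] == 1L) {
      if (a[i - 1] == b[j - 1]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (P[i, j] == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(identity = 100 * matches / columns, score = score,
       matches = matches, columns = columns)
}
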