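# Lineage handling. The canonical dialect is the rank-prefixed GTDB style
# ("d__Bacteria;p__Planctomycetota;..."); bare NCBI-style name lists are
# accepted on input and mapped positionally (superkingdom -> domain, ...).
# Invariant everywhere: no classified rank below an unclassified rank.

#' Canonical seven-rank order
#'
#' @return Character vector `domain` to `species`.
#' @export
lineage_ranks <- function() .tl_ranks

# canonicalize one classification string; errors on out-of-order prefixes
canonical_lineage <- function(classification) {
  if (is.na(classification) || !nzchar(trimws(classification))) return("")
  parts <- trimws(strsplit(classification, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) return("")
  has_prefix <- grepl("^[dpcofgs]__", parts)
  if (any(has_prefix) && !all(has_prefix)) {
    tl_abort(sprintf("mixed prefixed and bare ranks in lineage '%s'", classification),
             class = "tetralink_validation_error")
  }
  if (!any(has_prefix)) {
    # bare NCBI-style name list, mapped positionally
    if (length(parts) > 7) {
      tl_abort(sprintf("lineage '%s' has more than 7 ranks", classification),
               class = "tetralink_validation_error")
    }
    parts <- paste0(.tl_rank_prefixes[seq_along(parts)], parts)
  }
  prefixes <- substr(parts, 1, 3)
  pos <- match(prefixes, .tl_rank_prefixes)
  if (anyNA(pos) || any(diff(pos) != 1) || pos[1] != 1) {
    tl_abort(sprintf("rank prefixes out of order in lineage '%s'", classification),
             class = "tetralink_validation_error")
  }
  names <- substring(parts, 4)
  # drop trailing empty ranks ("p__" with no name) and anything below them
  classified <- nzchar(names)
  keep <- if (all(classified)) length(parts) else min(which(!classified)) - 1L
  if (keep == 0) return("")
  paste(parts[seq_len(keep)], collapse = ";")
}

#' Split a classification string into the seven canonical ranks
#'
#' @param classification Character vector of canonical rank-prefixed lineage
#'   strings ("" = fully unclassified).
#' @return A character matrix with one row per input and the seven ranks as
#'   columns; `NA` marks an unclassified rank.
#' @export
lineage_ranks_matrix <- function(classification) {
  out <- matrix(NA_character_, nrow = length(classification), ncol = 7,
                dimnames = list(NULL, .tl_ranks))
  for (i in seq_along(classification)) {
    cl <- classification[i]
    if (is.na(cl) || !nzchar(cl)) next
    parts <- strsplit(cl, ";", fixed = TRUE)[[1]]
    out[i, seq_along(parts)] <- substring(parts, 4)
  }
  out
}

#' Taxon name at a given rank
#'
#' @param classification Character vector of canonical lineage strings.
#' @param rank One of the seven canonical rank names.
#' @param unclassified Label used for an unclassified rank
#'   (default `"unclassified"`).
#' @return Character vector of taxon names at the rank.
#' @examples
#' lineage_at_rank("d__Bacteria;p__Planctomycetota", "phylum")
#' @export
lineage_at_rank <- function(classification, rank,
                            unclassified = "unclassified") {
  if (!is.character(rank) || length(rank) != 1L || !rank %in% .tl_ranks) {
    tl_abort(sprintf("unknown rank '%s'; expected one of %s",
                     paste(rank, collapse = ","), paste(.tl_ranks, collapse = ", ")))
  }
  m <- lineage_ranks_matrix(classification)
  out <- unname(m[, rank])
  out[is.na(out)] <- unclassified
  out
}

# truncate a canonical lineage string at a rank depth (1 = domain)
truncate_lineage <- function(classification, depth) {
  if (depth <= 0 || !nzchar(classification)) return("")
  parts <- strsplit(classification, ";", fixed = TRUE)[[1]]
  paste(parts[seq_len(min(depth, length(parts)))], collapse = ";")
}
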