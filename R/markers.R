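# Genome selection and supermatrix bookkeeping for concatenated marker
# phylogenies: representative scoring from CheckM-style quality, greedy
# dereplication over a supplied ANI matrix, single-copy marker selection,
# gap-fraction filtering of trimmed alignments, and per-genome
# concatenation with gap filling. Alignment and trimming themselves are
# consumed as inputs; tree inference is out of scope.

#' Representative score of a genome
#'
#' `completeness - 5 * contamination`, the standard quality score used to
#' pick representative genomes.
#'
#' @param completeness Percent completeness in \[0, 100\].
#' @param contamination Percent contamination (>= 0).
#' @return The score (vectorized).
#' @examples
#' representative_score(90, 4) # 70
#' @export
representative_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100)) {
    tl_abort("completeness must be in [0, 100]")
  }
  if (any(contamination < 0)) tl_abort("contamination must be >= 0")
  completeness - 5 * contamination
}

validate_ani_matrix <- function(ani) {
  if (!is.matrix(ani) || nrow(ani) != ncol(ani) ||
      is.null(rownames(ani)) || !identical(rownames(ani), colnames(ani))) {
    tl_abort("ANI must be a square matrix with matching row/column names",
             class = "tetralink_validation_error")
  }
  if (any(ani < 0 | ani > 1, na.rm = TRUE)) {
    tl_abort("ANI values must be in [0, 1]", class = "tetralink_validation_error")
  }
  if (any(abs(ani - t(ani)) > 1e-9)) {
    tl_abort("ANI matrix must be symmetric", class = "tetralink_validation_error")
  }
  if (any(abs(diag(ani) - 1) > 1e-9)) {
    tl_abort("ANI matrix diagonal must be 1", class = "tetralink_validation_error")
  }
  invisible(ani)
}

#' Greedy dereplication of genomes over an ANI matrix
#'
#' Genomes below `min_completeness` are removed; the rest are sorted by
#' representative score (descending, ties by id ascending) and processed
#' greedily: each genome joins the first existing cluster whose
#' representative it matches at `ANI >= secondary_ani`, otherwise it founds
#' a new cluster. Because of the sort order the founder of each cluster is
#' its highest-scoring member and therefore its representative. The result
#' is deterministic. `primary_ani` is validated (two-stage dereplicators
#' use it as a coarse pre-filter) but clustering here is the single greedy
#' pass at the secondary threshold.
#'
#' @param quality Tibble (`mag_id`, `completeness`, `contamination`).
#' @param ani Symmetric ANI matrix in \[0, 1\] with unit diagonal; row and
#'   column names must cover the retained genomes.
#' @param primary_ani,secondary_ani Clustering thresholds, defaults 0.90 and
#'   0.99; `0 < primary_ani <= secondary_ani <= 1`.
#' @param min_completeness Minimum percent completeness (default 50,
#'   inclusive).
#' @return A tibble (`mag_id`, `completeness`, `contamination`, `score`,
#'   `cluster`, `representative`, `is_representative`), one row per
#'   retained genome.
#' @export
greedy_dereplicate <- function(quality, ani, primary_ani = 0.90,
                               secondary_ani = 0.99, min_completeness = 50) {
  check_columns(quality, c("mag_id", "completeness", "contamination"),
                "quality table")
  check_scalar(primary_ani, "primary_ani", min = 0, max = 1, strict_min = TRUE)
  check_scalar(secondary_ani, "secondary_ani", min = primary_ani, max = 1)
  check_scalar(min_completeness, "min_completeness", min = 0, max = 100)
  validate_ani_matrix(ani)
  kept <- quality %>%
    filter(.data$completeness >= min_completeness) %>%
    mutate(score = representative_score(.data$completeness,
                                        .data$contamination)) %>%
    arrange(desc(.data$score), .data$mag_id)
  missing <- setdiff(kept$mag_id, rownames(ani))
  if (length(missing) > 0) {
    tl_abort(sprintf("genome(s) missing from ANI matrix: %s",
                     paste(missing, collapse = ", ")),
             class = "tetralink_validation_error")
  }
  reps <- character()
  cluster <- integer(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    id <- kept$mag_id[i]
    hit <- which(ani[id, reps] >= secondary_ani)
    if (length(reps) > 0 && length(hit) > 0) {
      cluster[i] <- hit[1]
    } else {
      reps <- c(reps, id)
      cluster[i] <- length(reps)
    }
  }
  kept %>%
    mutate(cluster = cluster,
           representative = reps[cluster],
           is_representative = .data$mag_id == .data$representative)
}

#' Single-copy marker selection
#'
#' A marker family is usable for a genome iff the genome carries exactly
#' one copy.
#'
#' @param counts Tibble (`genome`, `family`, `count`) of per-genome marker
#'   gene counts (>= 0).
#' @return The rows with `count == 1`, columns `genome`, `family`.
#' @export
single_copy_markers <- function(counts) {
  check_columns(counts, c("genome", "family", "count"), "marker counts")
  if (any(counts$count < 0)) tl_abort("marker counts must be >= 0")
  counts %>% filter(.data$count == 1) %>% select("genome", "family")
}

#' Gap-fraction filter for trimmed aligned sequences
#'
#' Drops a sequence iff its gap fraction strictly exceeds `gap_max`
#' (so exactly 60% gaps is kept at the default threshold).
#'
#' @param seq Aligned sequence(s) over the residue alphabet plus the gap
#'   symbol `-` (and `.`, also counted as a gap).
#' @param gap_max Maximum tolerated gap fraction (default 0.60, exclusive).
#' @return Logical vector: `TRUE` = keep.
#' @export
gap_fraction_filter <- function(seq, gap_max = 0.60) {
  check_scalar(gap_max, "gap_max", min = 0, max = 1)
  if (any(!nzchar(seq))) tl_abort("zero-length aligned sequence")
  gaps <- stringr::str_count(seq, "[-.]")
  gaps / nchar(seq) <= gap_max
}

#' Concatenate per-family alignments into a supermatrix
#'
#' One row per genome; a genome missing a family gets a run of gap symbols
#' of that family's alignment length. The partition map records each
#' family's span as 0-based half-open coordinates.
#'
#' @param alignments Named list, one element per marker family, each a
#'   named character vector of equal-length aligned sequences
#'   (genome -> sequence).
#' @param genomes Character vector of genome ids (rows of the supermatrix);
#'   defaults to every genome seen in any alignment, sorted. Duplicates are
#'   an error.
#' @param gap_char Gap symbol for absent families (default `"-"`).
#' @return A list with `alignment` (named character vector, one equal-length
#'   sequence per genome) and `partitions` (tibble `family`, `start`, `end`,
#'   0-based half-open).
#' @export
concatenate_supermatrix <- function(alignments, genomes = NULL, gap_char = "-") {
  if (length(alignments) == 0) tl_abort("no alignments supplied")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    tl_abort("alignments must be a named list (family names)")
  }
  lens <- purrr::imap_int(alignments, function(aln, fam) {
    l <- unique(nchar(aln))
    if (length(l) != 1) {
      tl_abort(sprintf("alignment '%s' has sequences of unequal length", fam))
    }
    l
  })
  genomes <- genomes %||% sort(unique(unlist(lapply(alignments, names))))
  if (anyDuplicated(genomes)) {
    tl_abort(sprintf("duplicate genome id '%s'",
                     genomes[duplicated(genomes)][1]))
  }
  rows <- vapply(genomes, function(g) {
    paste(purrr::imap_chr(alignments, function(aln, fam) {
      if (g %in% names(aln)) aln[[g]]
      else strrep(gap_char, lens[[fam]])
    }), collapse = "")
  }, character(1))
  ends <- unname(cumsum(lens))
  partitions <- tibble(family = names(alignments),
                       start = c(0L, head(ends, -1)),
                       end = as.integer(ends))
  list(alignment = rows, partitions = partitions)
}

#' Write a supermatrix as FASTA plus a RAxML-style partition file
#'
#' @param supermatrix Result of [concatenate_supermatrix()].
#' @param fasta_path,partition_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_supermatrix <- function(supermatrix, fasta_path, partition_path) {
  write_fasta(supermatrix$alignment, fasta_path)
  # RAxML partition lines are 1-based inclusive
  lines <- sprintf("AA, %s = %d-%d", supermatrix$partitions$family,
                   supermatrix$partitions$start + 1L,
                   supermatrix$partitions$end)
  writeLines(lines, partition_path)
  invisible(fasta_path)
}
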