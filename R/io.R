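# Readers and writers for every file dialect the pipeline touches.
# This is the single place where dialects are fixed: UTF-8, tab-separated,
# "#"-prefixed comment lines ignored, no quoting. BLAST tabular coordinates
# stay 1-based inclusive as in the format; any internal genomic interval is
# 0-based half-open, and conversions live only in this file.

# generic TSV reader with header validation; rows come back as character and
# are coerced (with row-numbered errors) by the specific readers
read_tl_tsv <- function(path, required, what = basename(path)) {
  if (!file.exists(path)) {
    tl_abort(sprintf("file not found: %s", path), class = "tetralink_io_error")
  }
  df <- readr::read_tsv(path, comment = "#", quote = "", na = character(),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  df <- as_tibble(df)
  check_columns(df, required, what)
  df
}

# coerce one character column to numeric, erroring with the first bad row
coerce_num <- function(df, col, what) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & nzchar(df[[col]]))
  if (length(bad) > 0 || anyNA(x)) {
    row <- if (length(bad) > 0) bad[1] else which(is.na(x))[1]
    tl_abort(sprintf("%s: cannot parse numeric value '%s' in column %s, row %d",
                     what, df[[col]][row], col, row),
             class = "tetralink_parse_error")
  }
  df[[col]] <- x
  df
}

#' Read BLAST tabular (outfmt 6) protein hits
#'
#' Parses the standard 12-column tab-separated BLAST output (query, subject,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore). The subject id is split into a scaffold id and a protein
#' (ORF) index at the last occurrence of `subject_sep`, the usual
#' gene-caller convention. Alignment coordinates are kept 1-based inclusive
#' as in the format.
#'
#' @param path Path to a BLAST outfmt-6 file. `#` comment lines are ignored.
#' @param subject_sep Separator between scaffold id and ORF number in the
#'   subject id (default `"_"`, split at its last occurrence).
#' @param query_map Optional named character vector mapping query accessions
#'   to gene-family names; unmapped queries keep the query id as family.
#' @return A tibble of hits with columns `family`, `query`, `subject`,
#'   `scaffold_id`, `protein_index`, `pident`, `length`, `mismatch`,
#'   `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @export
read_blast6 <- function(path, subject_sep = "_", query_map = NULL) {
  if (!file.exists(path)) {
    tl_abort(sprintf("file not found: %s", path), class = "tetralink_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(keep) == 0) {
    out <- tibble(family = character(), query = character(), subject = character(),
                  scaffold_id = character(), protein_index = integer())
    for (cl in cols[3:12]) out[[cl]] <- numeric()
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    bad <- which(nf < 12)[1]
    tl_abort(sprintf("%s: line %d has %d fields, expected at least 12",
                     basename(path), keep[bad], nf[bad]),
             class = "tetralink_parse_error")
  }
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  df <- as_tibble(setNames(as.data.frame(mat, stringsAsFactors = FALSE), cols))
  for (cl in cols[3:12]) df <- coerce_num(df, cl, basename(path))
  for (cl in c("length", "mismatch", "gapopen", "qstart", "qend",
               "sstart", "send")) df[[cl]] <- as.integer(df[[cl]])
  # split subject into scaffold id + ORF index at the last separator
  pos <- purrr::map_int(df$subject, function(s) {
    hits <- gregexpr(subject_sep, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) NA_integer_ else hits[length(hits)]
  })
  if (anyNA(pos)) {
    row <- which(is.na(pos))[1]
    tl_abort(sprintf("%s: subject id '%s' (row %d) has no '%s' separator",
                     basename(path), df$subject[row], row, subject_sep),
             class = "tetralink_parse_error")
  }
  df$scaffold_id <- substr(df$subject, 1, pos - 1L)
  idx <- suppressWarnings(as.integer(substring(df$subject, pos + nchar(subject_sep))))
  if (anyNA(idx)) {
    row <- which(is.na(idx))[1]
    tl_abort(sprintf("%s: subject id '%s' (row %d) has no numeric ORF index",
                     basename(path), df$subject[row], row),
             class = "tetralink_parse_error")
  }
  df$protein_index <- idx
  fam <- df$query
  if (!is.null(query_map)) {
    mapped <- unname(query_map[fam])
    fam <- ifelse(is.na(mapped), fam, mapped)
  }
  df$family <- fam
  df %>% select(all_of(c("family", "query", "subject", "scaffold_id",
                         "protein_index")), all_of(cols[3:12]))
}

#' Read a per-mapping scaffold depth table
#'
#' TSV with header `scaffold_id`, `assembly_sample`, `mapping_sample`,
#' `avg_depth` (mapped reads per base pair of the scaffold under that
#' mapping) and `mapping_total_reads` (total reads of the mapping sample
#' mapped against that assembly).
#'
#' @param path Path to the depth TSV.
#' @return A tibble of depth records.
#' @export
read_depth_table <- function(path) {
  df <- read_tl_tsv(path, c("scaffold_id", "assembly_sample", "mapping_sample",
                            "avg_depth", "mapping_total_reads"))
  df <- coerce_num(df, "avg_depth", basename(path))
  df <- coerce_num(df, "mapping_total_reads", basename(path))
  if (any(df$avg_depth < 0)) {
    tl_abort(sprintf("%s: negative avg_depth in row %d",
                     basename(path), which(df$avg_depth < 0)[1]),
             class = "tetralink_validation_error")
  }
  if (any(df$mapping_total_reads <= 0)) {
    tl_abort(sprintf("%s: mapping_total_reads must be > 0 (row %d)",
                     basename(path), which(df$mapping_total_reads <= 0)[1]),
             class = "tetralink_validation_error")
  }
  df
}

#' Read a scaffold or bin lineage table
#'
#' TSV with columns `id` and `classification`, the latter a rank-prefixed
#' GTDB-style string (`d__...;p__...;...`; trailing ranks may be absent;
#' an empty string means fully unclassified). Bare NCBI-style name lists
#' without rank prefixes are accepted and mapped positionally
#' (superkingdom to domain and so on).
#'
#' @param path Path to the lineage TSV.
#' @return A tibble with columns `id` and `classification` (canonicalized
#'   rank-prefixed form).
#' @export
read_lineage_table <- function(path) {
  df <- read_tl_tsv(path, c("id", "classification"))
  if (anyDuplicated(df$id)) {
    dup <- df$id[duplicated(df$id)][1]
    tl_abort(sprintf("%s: duplicate id '%s'", basename(path), dup),
             class = "tetralink_validation_error")
  }
  df$classification <- vapply(df$classification, canonical_lineage, character(1),
                              USE.NAMES = FALSE)
  df
}

#' Read a lipid peak table
#'
#' TSV with columns `lipid`, `sample`, `adduct` (one of `M+H`, `M+NH4`,
#' `M+Na`), `area` (>= 0), `is_area` (internal-standard area, > 0) and
#' `litres` (volume filtered, > 0). Rows absent for an adduct mean the
#' adduct was not detected.
#'
#' @param path Path to the peak TSV.
#' @return A tibble of peak rows.
#' @export
read_peak_table <- function(path) {
  df <- read_tl_tsv(path, c("lipid", "sample", "adduct", "area",
                            "is_area", "litres"))
  for (cl in c("area", "is_area", "litres")) df <- coerce_num(df, cl, basename(path))
  bad <- which(!df$adduct %in% names(.tl_adduct_masses))
  if (length(bad) > 0) {
    tl_abort(sprintf("%s: unknown adduct label '%s' in row %d",
                     basename(path), df$adduct[bad[1]], bad[1]),
             class = "tetralink_validation_error")
  }
  if (any(df$area < 0)) {
    tl_abort(sprintf("%s: negative area in row %d",
                     basename(path), which(df$area < 0)[1]),
             class = "tetralink_validation_error")
  }
  if (any(df$is_area <= 0)) {
    tl_abort(sprintf("%s: is_area must be > 0 (row %d); internal-standard normalization requires a positive standard response",
                     basename(path), which(df$is_area <= 0)[1]),
             class = "tetralink_validation_error")
  }
  if (any(df$litres <= 0)) {
    tl_abort(sprintf("%s: litres must be > 0 (row %d)",
                     basename(path), which(df$litres <= 0)[1]),
             class = "tetralink_validation_error")
  }
  df
}

#' Read a bin membership table
#'
#' TSV with columns `scaffold_id` and `bin_id`. Scaffolds absent from the
#' table are unbinned. A scaffold mapped to two bins is an error.
#'
#' @param path Path to the bin TSV.
#' @return A tibble with columns `scaffold_id`, `bin_id`.
#' @export
read_bin_table <- function(path) {
  df <- read_tl_tsv(path, c("scaffold_id", "bin_id"))
  dup <- df$scaffold_id[duplicated(df$scaffold_id)]
  if (length(dup) > 0) {
    tl_abort(sprintf("%s: scaffold '%s' is assigned to more than one bin",
                     basename(path), dup[1]),
             class = "tetralink_validation_error")
  }
  df
}

#' Read a MAG table (bin id and sample of binning)
#'
#' @param path TSV with columns `bin_id`, `sample`.
#' @return A tibble.
#' @export
read_mag_table <- function(path) {
  read_tl_tsv(path, c("bin_id", "sample"))
}

#' Read a MAG quality table (CheckM-style)
#'
#' @param path TSV with columns `mag_id`, `completeness` (percent, 0-100)
#'   and `contamination` (percent, >= 0).
#' @return A tibble.
#' @export
read_mag_quality <- function(path) {
  df <- read_tl_tsv(path, c("mag_id", "completeness", "contamination"))
  df <- coerce_num(df, "completeness", basename(path))
  df <- coerce_num(df, "contamination", basename(path))
  if (any(df$completeness < 0 | df$completeness > 100)) {
    tl_abort(sprintf("%s: completeness must be in [0, 100]", basename(path)),
             class = "tetralink_validation_error")
  }
  if (any(df$contamination < 0)) {
    tl_abort(sprintf("%s: contamination must be >= 0", basename(path)),
             class = "tetralink_validation_error")
  }
  df
}

#' Read a symmetric ANI matrix
#'
#' TSV with a leading id column and one column per genome; values in
#' \[0, 1\], symmetric, unit diagonal.
#'
#' @param path Path to the ANI TSV.
#' @return A numeric matrix with dimnames.
#' @export
read_ani_matrix <- function(path) {
  df <- read_tl_tsv(path, "id")
  ids <- df$id
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- ids
  validate_ani_matrix(m)
  m
}

#' Write a tibble as a pipeline TSV
#'
#' The inverse of the readers above: UTF-8, tab-separated, no quoting.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param params Optional named list of run parameters; when given, a YAML
#'   sidecar `<path>.yml` is written alongside the table.
#' @return `path`, invisibly.
#' @export
write_tl_tsv <- function(df, path, params = NULL) {
  readr::write_tsv(df, path, quote = "none", progress = FALSE)
  if (!is.null(params)) {
    yaml::write_yaml(params, paste0(path, ".yml"))
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @param type `"AA"` (default) or `"DNA"`.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    tl_abort("sequences must be named")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
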