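# Synthetic study generator. Emulates the data model of a multi-sample
# water-column metagenome study: 15 depth samples individually assembled,
# reads of every sample mapped back to every assembly that shares strains
# with it, scaffolds binned per sample into MAGs with tunable completeness
# and contamination, gene-family homologues planted in chosen phyla (plus
# boundary decoys that pin the screening thresholds), and lipid peak
# tables whose adduct areas track the summed abundance of the planted
# producers under a per-sample matrix effect that cancels on
# internal-standard normalization. Every draw flows from one seed, and the
# ground truth (who carries what, where, at what abundance) is returned
# alongside the tables so downstream attribution can be checked exactly.

.tl_archaeal_phyla <- c("Thermoproteota", "Thermoplasmatota", "Halobacteriota",
                        "Nanoarchaeota", "Asgardarchaeota")

# canonical 15-depth series (metres) used for default sample labels
.tl_depths15 <- c("50", "70", "80", "85", "100", "105", "110", "130",
                  "170", "250", "500", "750", "1000", "1500", "2000")

#' Configuration of a synthetic community
#'
#' Defaults describe a desk-scale version of a stratified-basin study:
#' 15 depth-labelled samples, lognormal genome abundances, strains shared
#' between adjacent depths (so cross-sample mappings exist and the
#' own-sample aggregation rule has something to correct), per-sample
#' binning with tunable completeness/contamination, and gene families
#' planted per phylum.
#'
#' @param n_samples Number of samples (default 15).
#' @param sample_labels Sample labels (depths in metres as strings); default
#'   the canonical 15-depth series, or an evenly spaced series for other
#'   `n_samples`.
#' @param n_genomes Number of genomes (default 24).
#' @param phylum_pool Phylum names cycled over the genomes.
#' @param abundance_logmean,abundance_logsd Lognormal parameters of
#'   per-sample genome abundance (defaults 0 and 1).
#' @param sharing_prob Probability in \[0, 1\] that a genome present in a
#'   sample is also present in the next adjacent sample (chain extension,
#'   both directions; default 0.3).
#' @param scaffolds_per_genome Scaffolds per genome per assembly (default 8).
#' @param scaffold_len_bp Scaffold length in bp (default 50000).
#' @param reads_per_sample Reads sequenced per sample (default 2e6).
#' @param planted_families Named list: gene family -> character vector of
#'   phyla carrying it.
#' @param bin_completeness Fraction of a genome's scaffolds recovered in its
#'   bin (default 0.75).
#' @param bin_contamination Per-scaffold probability of admitting a
#'   contaminant scaffold from another phylum (default 0.05).
#' @param unbinned_frac Probability that a (genome, sample) pair forms no
#'   bin at all (default 0.2).
#' @param litres Litres filtered per sample for the peak tables (default 1).
#' @param seed Integer seed; a fixed seed makes the bundle byte-identical
#'   across runs.
#' @return A validated list of class `community_config`.
#' @export
community_config <- function(n_samples = 15,
                             sample_labels = NULL,
                             n_genomes = 24,
                             phylum_pool = c("Desulfobacterota", "Planctomycetota",
                                             "Chloroflexota", "Actinobacteriota",
                                             "Cloacimonadota", "Myxococcota",
                                             "Bacteroidota", "Thermoproteota"),
                             abundance_logmean = 0,
                             abundance_logsd = 1,
                             sharing_prob = 0.3,
                             scaffolds_per_genome = 8,
                             scaffold_len_bp = 50000,
                             reads_per_sample = 2e6,
                             planted_families = list(
                               mss = "Desulfobacterota",
                               ger = c("Desulfobacterota", "Planctomycetota"),
                               gms = "Planctomycetota",
                               tes = "Thermoproteota",
                               grsA = "Thermoproteota"
                             ),
                             bin_completeness = 0.75,
                             bin_contamination = 0.05,
                             unbinned_frac = 0.2,
                             litres = 1,
                             seed = 1L) {
  check_scalar(n_samples, "n_samples", min = 1, integerish = TRUE)
  check_scalar(n_genomes, "n_genomes", min = 1, integerish = TRUE)
  check_scalar(scaffolds_per_genome, "scaffolds_per_genome", min = 1,
               integerish = TRUE)
  check_scalar(scaffold_len_bp, "scaffold_len_bp", min = 1, integerish = TRUE)
  check_scalar(reads_per_sample, "reads_per_sample", min = 1)
  check_scalar(abundance_logsd, "abundance_logsd", min = 0)
  check_scalar(abundance_logmean, "abundance_logmean")
  check_scalar(sharing_prob, "sharing_prob", min = 0, max = 1)
  check_scalar(bin_completeness, "bin_completeness", min = 0, max = 1)
  check_scalar(bin_contamination, "bin_contamination", min = 0, max = 1)
  check_scalar(unbinned_frac, "unbinned_frac", min = 0, max = 1)
  check_scalar(litres, "litres", min = 0, strict_min = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  if (length(phylum_pool) < 1) {
    tl_abort("invalid configuration: field `phylum_pool` must be non-empty",
             class = "tetralink_config_error")
  }
  if (length(planted_families) > 0) {
    if (is.null(names(planted_families)) || any(!nzchar(names(planted_families)))) {
      tl_abort("invalid configuration: field `planted_families` must be a named list",
               class = "tetralink_config_error")
    }
    unknown <- setdiff(unlist(planted_families), phylum_pool)
    if (length(unknown) > 0) {
      tl_abort(sprintf("invalid configuration: field `planted_families` names phyla outside phylum_pool: %s",
                       paste(unknown, collapse = ", ")),
               class = "tetralink_config_error")
    }
  }
  if (is.null(sample_labels)) {
    sample_labels <- if (n_samples == 15) .tl_depths15
      else as.character(round(seq(50, 2000, length.out = n_samples)))
  }
  if (length(sample_labels) != n_samples || anyDuplicated(sample_labels)) {
    tl_abort("invalid configuration: field `sample_labels` must have n_samples unique labels",
             class = "tetralink_config_error")
  }
  structure(list(
    n_samples = as.integer(n_samples), sample_labels = as.character(sample_labels),
    n_genomes = as.integer(n_genomes), phylum_pool = phylum_pool,
    abundance_logmean = abundance_logmean, abundance_logsd = abundance_logsd,
    sharing_prob = sharing_prob,
    scaffolds_per_genome = as.integer(scaffolds_per_genome),
    scaffold_len_bp = as.integer(scaffold_len_bp),
    reads_per_sample = reads_per_sample,
    planted_families = planted_families,
    bin_completeness = bin_completeness,
    bin_contamination = bin_contamination,
    unbinned_frac = unbinned_frac,
    litres = litres, seed = as.integer(seed)
  ), class = "community_config")
}

genome_lineage <- function(genome, phylum) {
  domain <- ifelse(phylum %in% .tl_archaeal_phyla, "Archaea", "Bacteria")
  sprintf("d__%s;p__%s;c__%s_c;o__%s_o;f__%s_f;g__%s",
          domain, phylum, phylum, phylum, phylum, genome)
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

mutate_aa <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  idx <- which(runif(length(chars)) < rate)
  if (length(idx) > 0) {
    chars[idx] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         length(idx), replace = TRUE)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic study bundle
#'
#' Produces every input table the attribution pipeline consumes -- depth
#' records, a BLAST-style hit table (planted homologues plus boundary
#' decoys at e-value exactly 1e-30 and identity 29.99), bin membership,
#' MAG metadata and quality, scaffold and bin lineages, protein FASTA --
#' together with the generating ground truth.
#'
#' The depth model: a genome present in a sample has lognormal abundance,
#' normalized to relative abundance within the sample; the expected reads
#' landing on each of its scaffolds under a mapping are
#' `reads_per_sample * rel_abund / scaffolds_per_genome`, realized as a
#' Poisson count and converted to reads per base pair. A scaffold receives
#' a mapping record from every sample in which its genome (strain) is
#' present, so strains shared across samples produce exactly the
#' cross-sample mappings whose double counting the own-sample rule removes.
#' `mapping_total_reads` of a record is the summed realized read count of
#' its (assembly, mapping) pair, so depth times length sums to the mapping
#' total exactly.
#'
#' @param config A [community_config()].
#' @return A list of class `tetra_bundle`: `config`, `tables` (tibbles
#'   `depth`, `hits`, `bins`, `mags`, `mag_quality`, `scaffold_lineages`,
#'   `bin_lineages`; named character vectors `proteins`, `queries`) and
#'   `truth` (tibbles `genomes`, `presence`, `genes`, `scaffolds`,
#'   `bin_provenance`).
#' @export
generate_community <- function(config = community_config()) {
  if (!inherits(config, "community_config")) {
    tl_abort("config must be a community_config()")
  }
  withr::local_seed(config$seed)
  samples <- config$sample_labels
  n_s <- config$n_samples

  # --- genomes and lineages (every pool phylum represented round-robin) ---
  phyla <- sample(rep_len(config$phylum_pool, config$n_genomes))
  genomes <- tibble(
    genome = sprintf("g%02d", seq_len(config$n_genomes)),
    phylum = phyla,
    lineage = genome_lineage(sprintf("g%02d", seq_len(config$n_genomes)), phyla),
    length_bp = config$scaffolds_per_genome * config$scaffold_len_bp
  )

  # --- presence: a home sample, chain-extended to neighbours ---
  presence <- purrr::map_dfr(seq_len(config$n_genomes), function(gi) {
    home <- sample.int(n_s, 1)
    lo <- home
    while (lo > 1 && runif(1) < config$sharing_prob) lo <- lo - 1
    hi <- home
    while (hi < n_s && runif(1) < config$sharing_prob) hi <- hi + 1
    tibble(genome = genomes$genome[gi], sample = samples[lo:hi])
  })
  presence$abundance <- rlnorm(nrow(presence), config$abundance_logmean,
                               config$abundance_logsd)
  presence <- presence %>%
    group_by(.data$sample) %>%
    mutate(rel_abund = .data$abundance / sum(.data$abundance)) %>%
    ungroup()

  # --- scaffolds: one strain assembly per (genome, present sample) ---
  scaffolds <- presence %>%
    select("genome", assembly_sample = "sample") %>%
    tidyr::crossing(idx = seq_len(config$scaffolds_per_genome)) %>%
    mutate(scaffold_id = sprintf("%s_a%s_c%02d", .data$genome,
                                 .data$assembly_sample, .data$idx)) %>%
    select("scaffold_id", "genome", "assembly_sample")

  # --- depth records: Poisson reads per (scaffold, mapping sample) ---
  depth <- scaffolds %>%
    inner_join(presence %>% select("genome", mapping_sample = "sample",
                                   "rel_abund"),
               by = "genome", relationship = "many-to-many") %>%
    mutate(
      expected_reads = config$reads_per_sample * .data$rel_abund /
        config$scaffolds_per_genome,
      reads = rpois(dplyr::n(), .data$expected_reads),
      avg_depth = .data$reads / config$scaffold_len_bp
    ) %>%
    group_by(.data$assembly_sample, .data$mapping_sample) %>%
    mutate(mapping_total_reads = sum(.data$reads)) %>%
    ungroup() %>%
    filter(.data$mapping_total_reads > 0) %>%
    select("scaffold_id", "assembly_sample", "mapping_sample",
           "avg_depth", "mapping_total_reads", "reads")

  # --- planted gene-family homologues and boundary decoys ---
  families <- names(config$planted_families)
  queries <- setNames(vapply(families, function(f) random_aa(200), character(1)),
                      families)
  gene_truth <- purrr::map_dfr(families, function(f) {
    carriers <- genomes$genome[genomes$phylum %in% config$planted_families[[f]]]
    tibble(genome = carriers, family = f)
  })
  planted <- gene_truth %>%
    inner_join(scaffolds %>% filter(endsWith(.data$scaffold_id, "_c01")),
               by = "genome", relationship = "many-to-many") %>%
    mutate(
      protein_index = 7L,
      evalue = 10^-runif(dplyr::n(), 35, 60),
      pident = runif(dplyr::n(), 35, 80),
      bitscore = round(runif(dplyr::n(), 150, 400), 1)
    )
  # decoys on non-carrier scaffolds: one violating the e-value strictness
  # (exactly 1e-30), one violating the identity bound (29.99)
  decoys <- purrr::map_dfr(families, function(f) {
    carriers <- genomes$genome[genomes$phylum %in% config$planted_families[[f]]]
    hosts <- scaffolds %>%
      filter(!.data$genome %in% carriers, endsWith(.data$scaffold_id, "_c02"))
    if (nrow(hosts) == 0) return(tibble())
    hosts <- hosts %>% group_by(.data$assembly_sample) %>% slice(1:2) %>% ungroup()
    hosts %>%
      mutate(family = f, protein_index = 3L,
             evalue = rep_len(c(1e-30, 1e-40), dplyr::n()),
             pident = rep_len(c(55, 29.99), dplyr::n()),
             bitscore = 120)
  })
  hits <- bind_rows(planted, decoys) %>%
    mutate(
      query = .data$family,
      subject = paste(.data$scaffold_id, .data$protein_index, sep = "_"),
      length = 200L, mismatch = 40L, gapopen = 2L,
      qstart = 1L, qend = 200L, sstart = 1L, send = 200L
    ) %>%
    select("family", "query", "subject", "scaffold_id", "protein_index",
           "pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  proteins <- setNames(
    vapply(hits$family, function(f) mutate_aa(queries[[f]], 0.35), character(1)),
    hits$subject)
  proteins <- proteins[!duplicated(names(proteins))]

  # --- binning: per-sample bins with completeness, contamination, and
  #     wholly unbinned genomes ---
  bin_rows <- list()
  mag_rows <- list()
  for (s in samples) {
    sc_s <- scaffolds %>% filter(.data$assembly_sample == s)
    if (nrow(sc_s) == 0) next
    genome_ids <- unique(sc_s$genome)
    binned_mask <- runif(length(genome_ids)) >= config$unbinned_frac
    assigned <- character()
    k <- 0
    bins_s <- list()
    for (gi in seq_along(genome_ids)) {
      if (!binned_mask[gi]) next
      g <- genome_ids[gi]
      own <- sc_s$scaffold_id[sc_s$genome == g]
      n_keep <- max(1L, as.integer(round(config$bin_completeness * length(own))))
      kept <- if (n_keep >= length(own)) own else sample(own, n_keep)
      k <- k + 1
      bin_id <- sprintf("s%s_bin%02d", s, k)
      bins_s[[k]] <- list(bin_id = bin_id, genome = g, own = kept)
      assigned <- c(assigned, kept)
    }
    free <- setdiff(sc_s$scaffold_id, assigned)
    for (b in bins_s) {
      g_phylum <- genomes$phylum[genomes$genome == b$genome]
      pool <- free[scaffolds$genome[match(free, scaffolds$scaffold_id)] %in%
                     genomes$genome[genomes$phylum != g_phylum]]
      n_contam <- rbinom(1, length(b$own), config$bin_contamination)
      contam <- if (n_contam > 0 && length(pool) > 0) {
        sample(pool, min(n_contam, length(pool)))
      } else character()
      free <- setdiff(free, contam)
      bin_rows[[length(bin_rows) + 1]] <- tibble(
        scaffold_id = c(b$own, contam),
        bin_id = b$bin_id,
        source_genome = b$genome,
        role = c(rep("own", length(b$own)), rep("contaminant", length(contam)))
      )
      mag_rows[[length(mag_rows) + 1]] <- tibble(
        bin_id = b$bin_id, sample = s, genome = b$genome,
        completeness = 100 * length(b$own) / config$scaffolds_per_genome,
        contamination = 100 * length(contam) / length(b$own)
      )
    }
  }
  bin_provenance <- if (length(bin_rows) > 0) bind_rows(bin_rows) else tibble(
    scaffold_id = character(), bin_id = character(),
    source_genome = character(), role = character())
  mags_full <- if (length(mag_rows) > 0) bind_rows(mag_rows) else tibble(
    bin_id = character(), sample = character(), genome = character(),
    completeness = numeric(), contamination = numeric())

  scaffold_lineages <- scaffolds %>%
    left_join(genomes %>% select("genome", "lineage"), by = "genome") %>%
    select(id = "scaffold_id", classification = "lineage")
  bin_lineages <- mags_full %>%
    left_join(genomes %>% select("genome", "lineage"), by = "genome") %>%
    select(id = "bin_id", classification = "lineage")

  structure(list(
    config = config,
    tables = list(
      depth = depth %>% select(-"reads"),
      hits = hits,
      bins = bin_provenance %>% select("scaffold_id", "bin_id"),
      mags = mags_full %>% select("bin_id", "sample"),
      mag_quality = mags_full %>%
        select(mag_id = "bin_id", "completeness", "contamination"),
      scaffold_lineages = scaffold_lineages,
      bin_lineages = bin_lineages,
      proteins = proteins,
      queries = queries
    ),
    truth = list(
      genomes = genomes,
      presence = presence,
      genes = gene_truth,
      scaffolds = scaffolds,
      bin_provenance = bin_provenance,
      mapping_reads = depth %>%
        select("scaffold_id", "mapping_sample", "reads")
    )
  ), class = "tetra_bundle")
}

#' @export
print.tetra_bundle <- function(x, ...) {
  cat("<tetra_bundle>\n")
  cat(sprintf("  samples:  %d (%s ... %s m)\n", x$config$n_samples,
              x$config$sample_labels[1],
              x$config$sample_labels[x$config$n_samples]))
  cat(sprintf("  genomes:  %d across %d phyla\n", x$config$n_genomes,
              length(unique(x$truth$genomes$phylum))))
  cat(sprintf("  scaffolds: %d; depth records: %d\n",
              nrow(x$truth$scaffolds), nrow(x$tables$depth)))
  cat(sprintf("  hits: %d (families: %s)\n", nrow(x$tables$hits),
              paste(names(x$config$planted_families), collapse = ", ")))
  cat(sprintf("  MAGs: %d\n", nrow(x$tables$mags)))
  invisible(x)
}

#' Generate a lipid peak table matching a synthetic bundle
#'
#' For every (lipid, sample, adduct): the peak area is proportional to the
#' summed relative abundance of the genomes carrying the producing gene
#' family in that sample, split over the three adducts, and scaled by a
#' per-sample lognormal matrix factor that equally scales the
#' internal-standard area -- so IS-normalized responses are unaffected by
#' the matrix effect, which is the point of the standard.
#'
#' @param bundle A `tetra_bundle` from [generate_community()].
#' @param producer_map Named character vector: gene family -> lipid name.
#'   Keys must be planted families. Default maps `mss`, `ger`, `gms` (where
#'   planted) onto `brGDGT-1a`, `brGDGT-3a`, `brGMGT-1a`.
#' @param base_area Full-abundance analyte area scale (default 1e6).
#' @param is_base Internal-standard base area (default 5e5).
#' @param adduct_shares Named shares of the three adducts (sum 1).
#' @param matrix_logsd Log-sd of the per-sample matrix factor (default 0.3).
#' @return A peak tibble (`lipid`, `sample`, `adduct`, `area`, `is_area`,
#'   `litres`).
#' @export
generate_lipid_peaks <- function(bundle,
                                 producer_map = NULL,
                                 base_area = 1e6, is_base = 5e5,
                                 adduct_shares = c("M+H" = 0.6, "M+NH4" = 0.3,
                                                   "M+Na" = 0.1),
                                 matrix_logsd = 0.3) {
  if (!inherits(bundle, "tetra_bundle")) tl_abort("bundle must be a tetra_bundle")
  config <- bundle$config
  planted <- names(config$planted_families)
  if (is.null(producer_map)) {
    producer_map <- c(mss = "brGDGT-1a", ger = "brGDGT-3a", gms = "brGMGT-1a")
    producer_map <- producer_map[names(producer_map) %in% planted]
  }
  if (length(producer_map) == 0 ||
      !all(names(producer_map) %in% planted)) {
    tl_abort("producer_map keys must be a non-empty subset of the planted families")
  }
  withr::local_seed(config$seed + 104729L)
  samples <- config$sample_labels
  matrix_factor <- setNames(exp(rnorm(length(samples), 0, matrix_logsd)), samples)
  carriers <- bundle$truth$genes
  abund <- bundle$truth$presence
  purrr::imap_dfr(producer_map, function(lipid, fam) {
    fam_genomes <- carriers$genome[carriers$family == fam]
    prod <- abund %>%
      filter(.data$genome %in% fam_genomes) %>%
      group_by(.data$sample) %>%
      summarise(p = sum(.data$rel_abund), .groups = "drop")
    p <- setNames(rep(0, length(samples)), samples)
    p[prod$sample] <- prod$p
    tidyr::crossing(sample = samples, adduct = names(adduct_shares)) %>%
      mutate(lipid = lipid,
             area = base_area * p[.data$sample] *
               adduct_shares[.data$adduct] * matrix_factor[.data$sample],
             is_area = is_base * matrix_factor[.data$sample],
             litres = config$litres) %>%
      select("lipid", "sample", "adduct", "area", "is_area", "litres")
  }) %>%
    arrange(.data$lipid, .data$sample, .data$adduct)
}

#' Write a synthetic bundle to disk
#'
#' Emits every table in the pipeline's file dialects (hits as 12-column
#' BLAST outfmt 6; the rest as headed TSVs), the protein FASTA, the ground
#' truth under `truth/`, and a YAML manifest listing every emitted path.
#'
#' @param bundle A `tetra_bundle`.
#' @param dir Output directory (created if needed).
#' @param peaks Optional peak tibble from [generate_lipid_peaks()].
#' @return The manifest path, invisibly.
#' @export
write_bundle <- function(bundle, dir, peaks = NULL) {
  if (!inherits(bundle, "tetra_bundle")) tl_abort("bundle must be a tetra_bundle")
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  t <- bundle$tables
  paths <- list(
    depth = "depth.tsv", bins = "bins.tsv", mags = "mags.tsv",
    mag_quality = "mag_quality.tsv",
    scaffold_lineages = "scaffold_lineages.tsv",
    bin_lineages = "bin_lineages.tsv"
  )
  for (nm in names(paths)) {
    df <- t[[nm]]
    if (nm %in% c("scaffold_lineages", "bin_lineages")) {
      names(df) <- c("id", "classification")
    }
    write_tl_tsv(df, file.path(dir, paths[[nm]]))
  }
  b6 <- t$hits %>%
    mutate(evalue = format(.data$evalue, scientific = TRUE, digits = 6)) %>%
    select("query", "subject", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  readr::write_tsv(b6, file.path(dir, "hits.b6"), col_names = FALSE,
                   quote = "none", progress = FALSE)
  write_fasta(t$proteins, file.path(dir, "proteins.faa"))
  write_fasta(t$queries, file.path(dir, "queries.faa"))
  for (nm in names(bundle$truth)) {
    write_tl_tsv(bundle$truth[[nm]], file.path(dir, "truth", paste0(nm, ".tsv")))
  }
  if (!is.null(peaks)) write_tl_tsv(peaks, file.path(dir, "peaks.tsv"))
  manifest <- list(
    seed = bundle$config$seed,
    samples = bundle$config$sample_labels,
    planted_families = lapply(bundle$config$planted_families, as.list),
    files = c(unname(unlist(paths)), "hits.b6", "proteins.faa", "queries.faa",
              if (!is.null(peaks)) "peaks.tsv"),
    truth_files = file.path("truth", paste0(names(bundle$truth), ".tsv"))
  )
  manifest_path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}
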