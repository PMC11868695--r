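# Shared fixture builders. Everything is generated in code; nothing binary.

# minimal hit tibble with sensible defaults
make_hits <- function(family = "mss", scaffold_id = "scf1", protein_index = 1L,
                      pident = 50, evalue = 1e-40, bitscore = 200) {
  tibble::tibble(
    family = family, query = family,
    subject = paste(scaffold_id, protein_index, sep = "_"),
    scaffold_id = scaffold_id, protein_index = as.integer(protein_index),
    pident = pident, length = 200L, mismatch = 40L, gapopen = 2L,
    qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
    evalue = evalue, bitscore = bitscore
  )
}

# depth record builder; totals default to the normalization scale so that
# normalized depth equals avg_depth
make_depth <- function(scaffold_id, assembly_sample, mapping_sample,
                       avg_depth, mapping_total_reads = 1e8) {
  tibble::tibble(scaffold_id = scaffold_id, assembly_sample = assembly_sample,
                 mapping_sample = mapping_sample, avg_depth = avg_depth,
                 mapping_total_reads = mapping_total_reads)
}

# write lines to a temp file, return the path
write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small, fast community configuration used across tests
small_config <- function(seed = 1L, ...) {
  community_config(
    n_genomes = 12, scaffolds_per_genome = 6, scaffold_len_bp = 10000,
    reads_per_sample = 5e5,
    phylum_pool = c("Desulfobacterota", "Planctomycetota", "Chloroflexota",
                    "Actinobacteriota"),
    planted_families = list(mss = "Desulfobacterota",
                            gms = "Planctomycetota"),
    seed = seed, ...
  )
}

# run the screen + presence + taxonomy + profile chain on a bundle
bundle_profiles <- function(bundle, mode = "own", rank = "phylum") {
  t <- bundle$tables
  hits <- dedupe_hits(filter_hits(t$hits))
  sl <- t$scaffold_lineages
  bl <- t$bin_lineages
  names(sl) <- names(bl) <- c("id", "classification")
  profile_by_taxon_gene(hits, t$bins, sl, bl, t$depth,
                        rank = rank, samples = bundle$config$sample_labels,
                        mode = mode)
}
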