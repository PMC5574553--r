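#' Simulate the full labelled four-species cohort
#'
#' Assembles every synthetic artifact — genomes and gene models, the
#' 1-to-1-to-1-to-1 ortholog table, the expression matrix with sample
#' metadata, the zebrafish/mouse segment matrices, the peak sets, signal
#' tracks and CNE records — together with the complete truth manifest of
#' planted labels. All randomness derives from the configuration seed
#' through per-artifact sub-streams, so identical configurations produce
#' bit-identical cohorts and individual artifacts can be regenerated
#' independently.
#'
#' @param config An [sim_config()] object.
#' @param pwms Motif library for consensus planting (default [iec_pwms()]).
#' @return An object of class `iec_cohort`.
#' @export
simulate_cohort <- function(config = sim_config(), pwms = iec_pwms()) {
  stopifnot(inherits(config, "iec_sim_config"))
  gen <- simulate_genomes(config, pwms)
  expr <- simulate_expression(config)
  seg <- simulate_segments(config)
  pk <- simulate_peaks(config)
  ids <- gene_ids(config)
  quart <- data.frame(lapply(config$species, function(sp)
    if (sp == "zebrafish") ids else
      paste0(species_prefix(sp), "_", ids)), stringsAsFactors = FALSE)
  colnames(quart) <- config$species
  orth <- ortholog_table(quart)
  structure(list(
    config = config, pwms = pwms,
    genomes = gen$genomes, gene_tables = gen$gene_tables,
    ortholog_table = orth,
    expression = expr[c("values", "meta")],
    segments = seg[c("zebrafish", "mouse")],
    peak_sets = pk$peak_sets, cnes = pk$cnes, tracks = pk$tracks,
    datasets = pk$datasets,
    truth = list(signature_genes = expr$truth$signature_genes,
                 baseline = expr$truth$baseline,
                 regional = seg$truth,
                 regions = pk$truth,
                 motifs = gen$motif_truth)),
    class = "iec_cohort")
}

#' @export
print.iec_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic IEC cohort\n")
  cat(sprintf("  %d genes x %d species; %d expression samples\n",
              cfg$n_genes, length(cfg$species), ncol(x$expression$values)))
  cat(sprintf("  %d regional pairs, %d test regions, %d peak datasets\n",
              nrow(x$truth$regional), nrow(x$truth$regions),
              length(x$peak_sets)))
  invisible(x)
}

#' Write a cohort to disk in standard formats
#'
#' FASTA genomes, TSV gene/ortholog/expression/segment tables, BED peaks and
#' CNEs, bedGraph signal tracks, and a JSON truth manifest.
#'
#' @param cohort An `iec_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "iec_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(cohort$genomes)) {
    write_genome_fasta(cohort$genomes[[sp]],
                       file.path(dir, paste0(sp, "_genome.fa")))
    write_tsv(cohort$gene_tables[[sp]],
              file.path(dir, paste0(sp, "_genes.tsv")))
  }
  write_ortholog_table(cohort$ortholog_table,
                       file.path(dir, "orthologs.tsv"))
  write_tsv(as.data.frame(cohort$expression$values),
            file.path(dir, "expression_fpkm.tsv"), row_names = TRUE)
  write_tsv(cohort$expression$meta, file.path(dir, "sample_meta.tsv"))
  write_tsv(as.data.frame(cohort$segments$zebrafish$values),
            file.path(dir, "zebrafish_segments.tsv"), row_names = TRUE)
  write_tsv(as.data.frame(cohort$segments$mouse$values),
            file.path(dir, "mouse_segments.tsv"), row_names = TRUE)
  peaks_dir <- file.path(dir, "peaks")
  tracks_dir <- file.path(dir, "tracks")
  dir.create(peaks_dir, showWarnings = FALSE)
  dir.create(tracks_dir, showWarnings = FALSE)
  for (d in names(cohort$peak_sets)) {
    iv <- cohort$peak_sets[[d]]$intervals
    if (nrow(iv))
      write_bed(iv, file.path(peaks_dir, paste0(d, ".bed")))
    tr <- cohort$tracks[[d]]
    if (nrow(tr))
      write_bedgraph(tr, file.path(tracks_dir, paste0(d, ".bedGraph")))
  }
  write_tsv(cohort$cnes, file.path(dir, "cnes.tsv"))
  write_tsv(cohort$datasets, file.path(dir, "datasets.tsv"))
  truth <- cohort$truth
  truth$baseline <- NULL    # large and derivable; keep the manifest light
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
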