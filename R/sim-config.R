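#' Configuration for the synthetic four-species cohort
#'
#' Builds the single configuration object consumed by all `simulate_*()`
#' generators and by [simulate_cohort()]. Defaults reproduce the study
#' conditions exercised throughout the package: a four-species cohort
#' (zebrafish, stickleback, mouse, human) with species-specific genome AT
#' composition (51/46/35/35 percent), a block of genes elevated in IEC samples
#' of all species (log2 effect 4, noise sd 0.25), anteroposterior segment
#' matrices for zebrafish (7 sections) and mouse (4 segments) with planted
#' regional archetypes, accessible-chromatin peak sets over 5 IEC and 17
#' non-IEC datasets with planted accessibility classes, and promoters carrying
#' planted motif consensus instances.
#'
#' @param seed Integer master seed. Every generator derives its own sub-stream
#'   from it, so identical configurations yield byte-identical cohorts.
#' @param n_genes Number of 1-to-1-to-1-to-1 ortholog quartets simulated.
#' @param species Ordered species names; the first is the anchor species.
#' @param at_fraction Named fractions in `[0,1]`: per-species genomic AT
#'   composition.
#' @param gene_spacing Base pairs between consecutive gene starts on the
#'   single simulated chromosome.
#' @param n_signature Number of planted IEC-elevated genes.
#' @param signature_log2_effect Log2 fold elevation of planted genes in IEC
#'   samples.
#' @param noise_sd Standard deviation of additive log2-expression noise.
#' @param n_iec_per_species IEC replicates per species.
#' @param n_noniec Number of non-IEC (mouse tissue) samples.
#' @param n_ribosomal Number of background genes given ribosomal-protein style
#'   identifiers (RPL/RPS) to exercise the ribosomal exclusion rule.
#' @param n_conserved_regional,n_shuffled_regional,n_flat_regional Numbers of
#'   ortholog pairs in the segment matrices whose mouse member shares the
#'   zebrafish archetype (conserved), carries a different archetype (shuffled),
#'   or is regionally flat.
#' @param segment_amplitude Height of the archetype templates on the common
#'   anteroposterior `[0,1]` axis, in z-score-comparable intensity units.
#' @param segment_noise_sd Standard deviation of additive segment noise.
#' @param segment_baseline Baseline intensity added to every segment value.
#' @param n_iec_specific,n_constitutive,n_background Numbers of planted test
#'   regions per accessibility class.
#' @param n_iec_datasets,n_noniec_datasets Peak-set roster sizes. The default
#'   classification thresholds (absent in >= 9/17 non-IEC sets; present in
#'   >= 14/17) assume 17 non-IEC datasets; requesting fewer with default
#'   thresholds is a configuration error at simulation time.
#' @param background_prob Per-dataset occupancy probability of background
#'   regions.
#' @param region_width Width (bp) of planted test regions.
#' @param cne_unmapped_prob Probability that a test region has no mapped
#'   coordinate in a given mammalian species (recorded, not an error).
#' @param n_cooccur Genes whose promoters carry both planted motifs in every
#'   species (the cross-species co-occurrence truth).
#' @param n_single_motif Genes carrying only the first motif (negative
#'   controls for the co-occurrence conjunction).
#' @param planted_motifs Optional data frame (`gene`, `motif`, `offset`)
#'   overriding the default planting plan; `offset` is the distance from the
#'   TSS to the motif's 5'-most base in gene orientation.
#'
#' @return An object of class `iec_sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 4100L,
                       species = c("zebrafish", "stickleback", "mouse", "human"),
                       at_fraction = c(zebrafish = 0.51, stickleback = 0.46,
                                       mouse = 0.35, human = 0.35),
                       gene_spacing = 2000L,
                       n_signature = 100L,
                       signature_log2_effect = 4,
                       noise_sd = 0.25,
                       n_iec_per_species = 3L,
                       n_noniec = 20L,
                       n_ribosomal = 10L,
                       n_conserved_regional = 60L,
                       n_shuffled_regional = 60L,
                       n_flat_regional = 40L,
                       segment_amplitude = 2,
                       segment_noise_sd = 0.3,
                       segment_baseline = 8,
                       n_iec_specific = 50L,
                       n_constitutive = 50L,
                       n_background = 100L,
                       n_iec_datasets = 5L,
                       n_noniec_datasets = 17L,
                       background_prob = 0.1,
                       region_width = 200L,
                       cne_unmapped_prob = 0,
                       n_cooccur = 25L,
                       n_single_motif = 25L,
                       planted_motifs = NULL) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes), species = species,
    at_fraction = at_fraction, gene_spacing = as.integer(gene_spacing),
    n_signature = as.integer(n_signature),
    signature_log2_effect = signature_log2_effect, noise_sd = noise_sd,
    n_iec_per_species = as.integer(n_iec_per_species),
    n_noniec = as.integer(n_noniec), n_ribosomal = as.integer(n_ribosomal),
    n_conserved_regional = as.integer(n_conserved_regional),
    n_shuffled_regional = as.integer(n_shuffled_regional),
    n_flat_regional = as.integer(n_flat_regional),
    segment_amplitude = segment_amplitude,
    segment_noise_sd = segment_noise_sd,
    segment_baseline = segment_baseline,
    n_iec_specific = as.integer(n_iec_specific),
    n_constitutive = as.integer(n_constitutive),
    n_background = as.integer(n_background),
    n_iec_datasets = as.integer(n_iec_datasets),
    n_noniec_datasets = as.integer(n_noniec_datasets),
    background_prob = background_prob,
    region_width = as.integer(region_width),
    cne_unmapped_prob = cne_unmapped_prob,
    n_cooccur = as.integer(n_cooccur),
    n_single_motif = as.integer(n_single_motif),
    planted_motifs = planted_motifs
  )
  validate_sim_config(cfg)
  structure(cfg, class = "iec_sim_config")
}

validate_sim_config <- function(cfg) {
  if (!all(cfg$species %in% names(cfg$at_fraction)))
    stop2("at_fraction must be named for every species")
  af <- cfg$at_fraction[cfg$species]
  if (any(af < 0 | af > 1)) stop2("AT fractions must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop2("noise_sd must be non-negative")
  if (cfg$segment_noise_sd < 0) stop2("segment_noise_sd must be non-negative")
  if (cfg$n_signature > cfg$n_genes)
    stop2("n_signature cannot exceed n_genes")
  if (cfg$background_prob < 0 || cfg$background_prob > 1)
    stop2("background_prob must lie in [0, 1]")
  if (cfg$cne_unmapped_prob < 0 || cfg$cne_unmapped_prob > 1)
    stop2("cne_unmapped_prob must lie in [0, 1]")
  n_reg <- cfg$n_conserved_regional + cfg$n_shuffled_regional + cfg$n_flat_regional
  if (n_reg > cfg$n_genes)
    stop2("regional gene counts exceed n_genes")
  if (cfg$n_cooccur + cfg$n_single_motif > cfg$n_genes)
    stop2("motif planting counts exceed n_genes")
  invisible(cfg)
}

#' @export
print.iec_sim_config <- function(x, ...) {
  cat("Synthetic IEC cohort configuration\n")
  cat("  seed:", x$seed, " genes:", x$n_genes,
      " species:", paste(x$species, collapse = ", "), "\n")
  cat("  AT fractions:", paste(sprintf("%s=%.2f", x$species,
                                       x$at_fraction[x$species]),
                               collapse = " "), "\n")
  cat("  signature:", x$n_signature, "genes, log2 effect",
      x$signature_log2_effect, ", noise sd", x$noise_sd, "\n")
  cat("  regional pairs:", x$n_conserved_regional, "conserved /",
      x$n_shuffled_regional, "shuffled /", x$n_flat_regional, "flat\n")
  cat("  regions:", x$n_iec_specific, "IEC-specific /", x$n_constitutive,
      "constitutive /", x$n_background, "background over",
      x$n_iec_datasets, "IEC +", x$n_noniec_datasets, "non-IEC datasets\n")
  invisible(x)
}

# Species id prefixes used for per-species gene identifiers.
species_prefix <- function(species) {
  pre <- c(zebrafish = "dre", stickleback = "gac", mouse = "mmu", human = "hsa")
  ifelse(species %in% names(pre), pre[species], substr(species, 1, 3))
}

# Anchor-species gene identifiers; a handful of background genes get
# ribosomal-protein style names to exercise the exclusion rule.
gene_ids <- function(cfg) {
  ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  if (cfg$n_ribosomal > 0) {
    # place ribosomal decoys at the end, outside every planted block
    k <- cfg$n_ribosomal
    idx <- seq(cfg$n_genes - k + 1L, cfg$n_genes)
    ids[idx] <- sprintf("%s%d", rep(c("RPL", "RPS"), length.out = k), seq_len(k))
  }
  ids
}
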