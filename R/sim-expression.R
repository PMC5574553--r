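#' Simulate the ortholog-anchored expression matrix
#'
#' Log2 expression for gene g in sample s is
#' `baseline(g) + effect * [g is planted and s is IEC] + Normal(0, noise_sd)`,
#' reported as FPKM (`2^log2`). The planted block of `n_signature` genes is
#' elevated in the IEC samples of all species, emulating a conserved
#' epithelial signature over log-normal noise. Sample roster:
#' `n_iec_per_species` IEC replicates per species plus `n_noniec` mouse
#' non-IEC tissue samples.
#'
#' @param config An [sim_config()] object.
#' @return A list with `values` (genes x samples FPKM matrix, rownames =
#'   anchor-species gene ids), `meta` (per-sample data frame: `sample`,
#'   `species`, `tissue`, `is_iec`), and `truth` (`signature_genes`,
#'   `baseline`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "iec_sim_config"))
  if (config$noise_sd < 0) stop2("noise_sd must be non-negative")
  n_iec_total <- config$n_iec_per_species * length(config$species)
  if (n_iec_total < 2L || config$n_noniec < 2L)
    stop2("need at least 2 IEC and 2 non-IEC samples")
  set.seed(sub_seed(config$seed, "expression"))
  ids <- gene_ids(config)
  iec_samples <- unlist(lapply(config$species, function(sp)
    sprintf("%s_IEC_%d", sp, seq_len(config$n_iec_per_species))))
  noniec_samples <- sprintf("mouse_tissue_%02d", seq_len(config$n_noniec))
  samples <- c(iec_samples, noniec_samples)
  meta <- data.frame(
    sample = samples,
    species = c(rep(config$species, each = config$n_iec_per_species),
                rep("mouse", config$n_noniec)),
    tissue = c(rep("IEC", n_iec_total),
               sprintf("tissue_%02d", seq_len(config$n_noniec))),
    is_iec = c(rep(TRUE, n_iec_total), rep(FALSE, config$n_noniec)),
    stringsAsFactors = FALSE)

  # planted genes sampled from the non-ribosomal pool
  pool <- ids[!grepl("^RP[LS]", ids)]
  signature_genes <- sort(sample(pool, config$n_signature))
  baseline <- stats::rnorm(config$n_genes, mean = 5, sd = 2)
  names(baseline) <- ids

  eff <- matrix(0, nrow = config$n_genes, ncol = length(samples),
                dimnames = list(ids, samples))
  eff[signature_genes, meta$is_iec] <- config$signature_log2_effect
  noise <- if (config$noise_sd > 0)
    matrix(stats::rnorm(length(eff), 0, config$noise_sd), nrow = nrow(eff))
  else 0
  log2v <- baseline + eff + noise
  values <- 2^log2v
  dimnames(values) <- list(ids, samples)
  list(values = values, meta = meta,
       truth = list(signature_genes = signature_genes, baseline = baseline))
}

#' Simulate per-species anteroposterior segment intensity matrices
#'
#' Regional archetypes are fixed piecewise-linear templates on a common
#' anteroposterior `[0,1]` axis, evaluated at the 7 zebrafish sections and at
#' the 4 mouse segments (which occupy positions 1, 3, 5, 7 of the 7-slot
#' axis): `anterior` declines from the anterior end, `ileal` is a narrow
#' spike at zebrafish section 5 / mouse ileum, `posterior` rises towards the
#' posterior end, and `flat` is constant. Raw intensities are
#' `baseline + amplitude * template + Normal(0, segment_noise_sd)`.
#'
#' Pair truth: the first `n_conserved_regional` ortholog pairs share their
#' archetype between species; the next `n_shuffled_regional` pairs are
#' "shuffled" (the mouse member carries a different, uniformly drawn
#' archetype, breaking the regional correspondence); `n_flat_regional` pairs
#' are flat in both species.
#'
#' @param config An [sim_config()] object.
#' @return A list with `zebrafish` and `mouse` (each `values` genes x
#'   segments raw intensity matrix plus `segments` labels) and `truth`
#'   (data frame: `zebrafish_gene`, `mouse_gene`, `zf_archetype`,
#'   `ms_archetype`, `status` in conserved/shuffled/flat).
#' @export
simulate_segments <- function(config) {
  stopifnot(inherits(config, "iec_sim_config"))
  set.seed(sub_seed(config$seed, "segments"))
  archs <- c("anterior", "ileal", "posterior")
  n_c <- config$n_conserved_regional
  n_s <- config$n_shuffled_regional
  n_f <- config$n_flat_regional
  n <- n_c + n_s + n_f
  ids <- gene_ids(config)[seq_len(n)]
  zf_arch <- c(rep_len(archs, n_c), rep_len(archs, n_s), rep("flat", n_f))
  ms_arch <- zf_arch
  if (n_s > 0) {
    idx <- n_c + seq_len(n_s)
    ms_arch[idx] <- vapply(zf_arch[idx], function(a)
      sample(setdiff(archs, a), 1L), character(1))
  }
  status <- c(rep("conserved", n_c), rep("shuffled", n_s), rep("flat", n_f))

  zf_x <- (0:6) / 6
  ms_x <- c(0, 2, 4, 6) / 6
  zf <- t(vapply(zf_arch, function(a) segment_template(a, zf_x), numeric(7)))
  ms <- t(vapply(ms_arch, function(a) segment_template(a, ms_x), numeric(4)))
  zf <- config$segment_baseline + config$segment_amplitude * zf +
    matrix(stats::rnorm(length(zf), 0, config$segment_noise_sd), nrow = n)
  ms <- config$segment_baseline + config$segment_amplitude * ms +
    matrix(stats::rnorm(length(ms), 0, config$segment_noise_sd), nrow = n)
  # zebrafish is the anchor species and keeps bare identifiers
  zf_ids <- ids
  ms_ids <- paste0(species_prefix("mouse"), "_", ids)
  dimnames(zf) <- list(zf_ids, sprintf("section_%d", 1:7))
  dimnames(ms) <- list(ms_ids, c("duodenum", "jejunum", "ileum", "colon"))
  list(
    zebrafish = list(values = zf, segments = colnames(zf)),
    mouse = list(values = ms, segments = colnames(ms)),
    truth = data.frame(zebrafish_gene = zf_ids, mouse_gene = ms_ids,
                       zf_archetype = zf_arch, ms_archetype = ms_arch,
                       status = status, stringsAsFactors = FALSE))
}

#' Regional archetype template
#'
#' @param archetype One of `anterior`, `ileal`, `posterior`, `flat`.
#' @param x Positions on the common anteroposterior `[0,1]` axis.
#' @return Template values at `x` (unit amplitude).
#' @export
segment_template <- function(archetype, x) {
  switch(archetype,
         anterior  = 1 - x,
         ileal     = pmax(0, 1 - abs(x - 2 / 3) / 0.2),
         posterior = x,
         flat      = rep(1, length(x)),
         stop2("unknown archetype '", archetype, "'"))
}
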