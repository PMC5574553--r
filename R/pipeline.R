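#' Run the end-to-end analysis pipeline on a synthetic cohort
#'
#' Orchestrates the stages in dependency order — simulate, signature,
#' regional, chromatin, motifs, atprofile, report — writing each stage's
#' outputs under `outdir` plus a machine-readable run manifest recording the
#' seed, the full configuration and every defaulted parameter, and md5
#' digests of all outputs. Outputs contain no timestamps, so re-running with
#' the same configuration reproduces byte-identical files.
#'
#' @param config An [sim_config()] object, a list of `sim_config()`
#'   arguments, or a path to a YAML/JSON file of such arguments.
#' @param outdir Output directory.
#' @param stages Stages to run (subset, in canonical order).
#' @param params Analysis parameters; see Details. Defaults are recorded in
#'   the manifest.
#' @param force Re-run stages whose outputs already exist.
#' @details `params` may override: `detect_min_fpkm` (1), `signature_threshold`
#'   (0.7), `regional_threshold` (0.6), `regional_k` (3), `sort_segment`
#'   (`"duodenum"`), `cooccur_window_bp` (150), `at_flank` (500),
#'   `at_window` (20).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = c("simulate", "signature", "regional",
                                    "chromatin", "motifs", "atprofile",
                                    "report"),
                         params = list(), force = FALSE) {
  config <- resolve_config(config)
  defaults <- list(detect_min_fpkm = 1, signature_threshold = 0.7,
                   regional_threshold = 0.6, regional_k = 3L,
                   sort_segment = "duodenum", cooccur_window_bp = 150L,
                   at_flank = 500L, at_window = 20L)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop2("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, params)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cohort <- simulate_cohort(config)
  if ("simulate" %in% stages) {
    stage_dir <- file.path(outdir, "cohort")
    if (force || !file.exists(file.path(stage_dir, "truth.json")))
      write_cohort(cohort, stage_dir)
  }

  if ("signature" %in% stages) {
    f <- file.path(outdir, "signature.tsv")
    if (force || !file.exists(f)) {
      vals <- detectable_filter(cohort$expression$values, p$detect_min_fpkm)
      pc <- pca_pc1(vals, cohort$expression$meta$is_iec)
      sig <- call_signature(vals, pc$scores, threshold = p$signature_threshold)
      write_signature(sig, f)
      write_tsv(data.frame(sample = names(pc$scores),
                           pc1 = unname(pc$scores)),
                file.path(outdir, "pc1_scores.tsv"))
    }
  }

  if ("regional" %in% stages) {
    f <- file.path(outdir, "regional_matches.tsv")
    if (force || !file.exists(f)) {
      reg <- regional_stage(cohort, p)
      write_tsv(reg$matches, f)
      write_tsv(as.data.frame(reg$display),
                file.path(outdir, "regional_display.tsv"), row_names = TRUE)
    }
  }

  if ("chromatin" %in% stages) {
    f <- file.path(outdir, "region_classes.tsv")
    if (force || !file.exists(f)) {
      mat <- build_overlap_matrix(cohort$cnes, cohort$peak_sets)
      cls <- classify_regions(
        mat,
        iec_datasets = cohort$datasets$dataset_id[cohort$datasets$role == "IEC"],
        noniec_datasets = cohort$datasets$dataset_id[cohort$datasets$role == "non_IEC"])
      write_tsv(cls, f)
    }
  }

  if ("motifs" %in% stages) {
    f <- file.path(outdir, "cooccurrence.tsv")
    if (force || !file.exists(f)) {
      pos <- list()
      for (sp in config$species) {
        co <- cooccurrence(cohort$gene_tables[[sp]], cohort$genomes[[sp]],
                           cohort$pwms, window_bp = p$cooccur_window_bp)
        pos[[sp]] <- co$per_gene$gene_id[co$per_gene$positive]
        if (sp == config$species[1])
          write_tsv(co$per_gene, f)
      }
      shared <- cross_species_cooccurrence(pos, cohort$ortholog_table)
      write_tsv(shared, file.path(outdir, "cooccurrence_shared.tsv"))
    }
  }

  if ("atprofile" %in% stages) {
    f <- file.path(outdir, "at_profiles.tsv")
    if (force || !file.exists(f)) {
      rows <- lapply(config$species, function(sp) {
        gt <- cohort$gene_tables[[sp]]
        prof <- at_profile(cohort$genomes[[sp]],
                           data.frame(chrom = gt$chrom, pos = gt$tss,
                                      strand = gt$strand,
                                      stringsAsFactors = FALSE),
                           flank = p$at_flank, window = p$at_window)
        data.frame(species = sp, offset = prof$offsets,
                   at_fraction = prof$fraction, stringsAsFactors = FALSE)
      })
      write_tsv(do.call(rbind, rows), f)
    }
  }

  manifest <- list(tool = "iecreg",
                   version = as.character(utils::packageVersion("iecreg")),
                   seed = config$seed,
                   config = unclass(config)[!vapply(unclass(config), is.null,
                                                    logical(1))],
                   params = p,
                   stages = stages)
  if ("report" %in% stages)
    pipeline_report(outdir, manifest_params = p)
  manifest$digests <- output_digests(outdir)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

resolve_config <- function(config) {
  if (inherits(config, "iec_sim_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop2("config must be an iec_sim_config, list, or path")
  known <- names(formals(sim_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$at_fraction)) config$at_fraction <- unlist(config$at_fraction)
  do.call(sim_config, config)
}

regional_stage <- function(cohort, p) {
  zf_z <- zscore_rows(cohort$segments$zebrafish$values)
  ms_z <- zscore_rows(cohort$segments$mouse$values)
  zf_e <- expressed_filter(zf_z$values)
  cl <- uncentered_complete_cluster(zf_e, k = p$regional_k)
  pair_tab <- ortholog_table(cohort$truth$regional[, c("zebrafish_gene",
                                                       "mouse_gene")] |>
                               stats::setNames(c("zebrafish", "mouse")))
  matches <- match_regional(zf_e, ms_z$values, pair_tab,
                            cluster_labels = cl$labels,
                            threshold = p$regional_threshold)
  display <- if (nrow(matches))
    median_center_and_sort(matches, zf_e, ms_z$values,
                           sort_segment = p$sort_segment)
  else matrix(numeric(0), 0, 14)
  list(matches = matches, display = display, clusters = cl,
       dropped = c(zf_z$dropped, ms_z$dropped))
}

output_digests <- function(outdir) {
  files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  md5 <- tools::md5sum(files)
  stats::setNames(as.list(unname(md5)),
                  sub(paste0("^", outdir, "/?"), "", files))
}

#' Summarise pipeline outputs
#'
#' Reads the stage outputs under `outdir` and writes `report.json` (and a
#' regional display heatmap when requested): signature counts, regional
#' match counts per source cluster, accessibility classification tallies,
#' co-occurrence counts and fractions, and mean AT% per species. Missing
#' stage outputs are omitted with a warning. Running the report twice
#' produces identical files.
#'
#' @param outdir Pipeline output directory.
#' @param heatmap Also render `regional_heatmap.pdf`.
#' @param manifest_params Internal (parameters echoed into the report).
#' @return The report list, invisibly.
#' @export
pipeline_report <- function(outdir, heatmap = FALSE, manifest_params = NULL) {
  rep <- list()
  f <- file.path(outdir, "signature.tsv")
  if (file.exists(f)) {
    sig <- utils::read.delim(f)
    rep$signature <- list(n_signature = sum(sig$in_signature),
                          n_ribosomal_excluded = sum(sig$ribosomal_excluded))
  } else warning("signature output missing; section omitted")
  f <- file.path(outdir, "regional_matches.tsv")
  if (file.exists(f)) {
    m <- utils::read.delim(f)
    rep$regional <- list(
      n_matches = nrow(m),
      per_cluster = if (nrow(m)) as.list(table(m$source_cluster))
      else list())
  } else warning("regional output missing; section omitted")
  f <- file.path(outdir, "region_classes.tsv")
  if (file.exists(f)) {
    cls <- utils::read.delim(f)
    rep$chromatin <- as.list(table(cls$label, useNA = "ifany"))
  } else warning("chromatin output missing; section omitted")
  f <- file.path(outdir, "cooccurrence.tsv")
  if (file.exists(f)) {
    co <- utils::read.delim(f)
    rep$motifs <- list(n_positive = sum(co$positive),
                       fraction_positive = mean(co$positive))
    fs <- file.path(outdir, "cooccurrence_shared.tsv")
    if (file.exists(fs))
      rep$motifs$n_shared_orthologs <- nrow(utils::read.delim(fs))
  } else warning("motif output missing; section omitted")
  f <- file.path(outdir, "at_profiles.tsv")
  if (file.exists(f)) {
    at <- utils::read.delim(f)
    rep$at_percent <- as.list(round(
      100 * tapply(at$at_fraction, at$species, mean), 2))
  } else warning("AT profile output missing; section omitted")
  if (!is.null(manifest_params)) rep$params <- manifest_params
  jsonlite::write_json(rep, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (heatmap) {
    fd <- file.path(outdir, "regional_display.tsv")
    if (file.exists(fd)) {
      m <- as.matrix(utils::read.delim(fd, row.names = 1,
                                       check.names = FALSE))
      grDevices::pdf(file.path(outdir, "regional_heatmap.pdf"),
                     width = 6, height = 8)
      graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                      axes = FALSE, xlab = "segments (zf 1-7 | ms 1-7)",
                      ylab = "matched ortholog pairs",
                      col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
      grDevices::dev.off()
    }
  }
  invisible(rep)
}
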