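#' Simulate accessible-chromatin peak sets, signal tracks and CNE records
#'
#' Plants conserved nonexonic test regions carrying known accessibility-class
#' labels over a roster of 5 IEC-like and 17 non-IEC-like datasets:
#' `IEC_specific` regions receive peaks in every IEC dataset and in at most 8
#' non-IEC datasets (i.e. absent in at least 9 of 17); `constitutive` regions
#' in every IEC dataset and at least 14 of 17 non-IEC datasets; `background`
#' regions occupy each dataset independently with probability
#' `background_prob`. Regions live in a tail margin of each species'
#' simulated chromosome, with cross-species mapped coordinates recorded as
#' CNE records (a mapping can be absent with probability
#' `cne_unmapped_prob`, a recorded state rather than an error). Each peak
#' gets a triangular signal pulse in its dataset's bedGraph track.
#'
#' @param config An [sim_config()] object.
#' @return A list with `peak_sets` (list of `iec_peakset`), `cnes` (long data
#'   frame `id`, `species`, `chrom`, `start`, `end`; one row per available
#'   mapping), `tracks` (per dataset, a bedGraph data frame `chrom`, `start`,
#'   `end`, `score`), `datasets` (roster data frame with `dataset_id`,
#'   `species`, `role`), and `truth` (region class labels).
#' @export
simulate_peaks <- function(config) {
  stopifnot(inherits(config, "iec_sim_config"))
  if (config$n_noniec_datasets < 17L)
    stop2("default accessibility-class thresholds assume 17 non-IEC datasets; ",
          "requested ", config$n_noniec_datasets)
  set.seed(sub_seed(config$seed, "peaks"))

  iec_ds <- data.frame(
    dataset_id = c("zebrafish_IEC", "stickleback_IEC", "mouse_ileum_IEC",
                   "mouse_colon_IEC", "human_colon_IEC")[seq_len(config$n_iec_datasets)],
    species = c("zebrafish", "stickleback", "mouse", "mouse",
                "human")[seq_len(config$n_iec_datasets)],
    role = "IEC", stringsAsFactors = FALSE)
  nn <- config$n_noniec_datasets
  noniec_sp <- rep(c("mouse", "human"), length.out = nn)
  noniec_ds <- data.frame(
    dataset_id = sprintf("%s_tissue_%02d", noniec_sp, seq_len(nn)),
    species = noniec_sp, role = "non_IEC", stringsAsFactors = FALSE)
  datasets <- rbind(iec_ds, noniec_ds)

  n_regions <- config$n_iec_specific + config$n_constitutive + config$n_background
  classes <- c(rep("IEC_specific", config$n_iec_specific),
               rep("constitutive", config$n_constitutive),
               rep("background", config$n_background))
  region_ids <- sprintf("CNE_%04d", seq_len(n_regions))
  margin0 <- config$n_genes * config$gene_spacing + 1000L
  w <- config$region_width

  # per-species mapped coordinates (small species-specific jitter)
  cnes <- list()
  for (sp in config$species) {
    jit <- sample(-50:50, n_regions, replace = TRUE)
    start <- margin0 + (seq_len(n_regions) - 1L) * 1000L + 400L + jit
    keep <- if (sp == "zebrafish") rep(TRUE, n_regions) else
      stats::runif(n_regions) >= config$cne_unmapped_prob
    cnes[[sp]] <- data.frame(id = region_ids, species = sp, chrom = "chr1",
                             start = start, end = start + w,
                             stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  cnes <- do.call(rbind, cnes)
  rownames(cnes) <- NULL

  # presence matrix regions x datasets
  present <- matrix(FALSE, n_regions, nrow(datasets),
                    dimnames = list(region_ids, datasets$dataset_id))
  is_iec <- datasets$role == "IEC"
  for (i in seq_len(n_regions)) {
    if (classes[i] == "IEC_specific") {
      present[i, is_iec] <- TRUE
      k <- sample(0:(nn - 9L), 1L)
      if (k > 0) present[i, sample(which(!is_iec), k)] <- TRUE
    } else if (classes[i] == "constitutive") {
      present[i, is_iec] <- TRUE
      k <- sample(14:nn, 1L)
      present[i, sample(which(!is_iec), k)] <- TRUE
    } else {
      present[i, ] <- stats::runif(ncol(present)) < config$background_prob
    }
  }

  peak_sets <- vector("list", nrow(datasets))
  tracks <- vector("list", nrow(datasets))
  names(peak_sets) <- names(tracks) <- datasets$dataset_id
  for (d in seq_len(nrow(datasets))) {
    sp <- datasets$species[d]
    co <- cnes[cnes$species == sp, , drop = FALSE]
    idx <- which(present[, d])
    co <- co[co$id %in% region_ids[idx], , drop = FALSE]
    if (nrow(co)) {
      pad_l <- sample(0:60, nrow(co), replace = TRUE)
      pad_r <- sample(0:60, nrow(co), replace = TRUE)
      iv <- data.frame(chrom = co$chrom, start = co$start - pad_l,
                       end = co$end + pad_r, stringsAsFactors = FALSE)
    } else {
      iv <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
    }
    peak_sets[[d]] <- peak_set(datasets$dataset_id[d], sp,
                               ifelse(is_iec[d], "IEC", "non_IEC"), iv)
    tracks[[d]] <- triangular_track(peak_sets[[d]]$intervals)
  }
  list(peak_sets = peak_sets, cnes = cnes, tracks = tracks,
       datasets = datasets,
       truth = data.frame(id = region_ids, class = classes,
                          stringsAsFactors = FALSE))
}

# A symmetric triangular pulse (10 bins, peak height 10) over each interval.
triangular_track <- function(intervals, height = 10, bins = 10L) {
  if (!nrow(intervals))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    br <- unique(round(seq(s, e, length.out = bins + 1L)))
    nb <- length(br) - 1L
    mid <- (seq_len(nb) - 0.5) / nb
    val <- round(height * (1 - abs(mid - 0.5) * 2), 2)
    data.frame(chrom = intervals$chrom[i], start = br[-length(br)],
               end = br[-1L], score = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$score > 0, , drop = FALSE]
}
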