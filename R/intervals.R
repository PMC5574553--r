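#' Genomic interval utilities (0-based half-open, BED convention)
#'
#' All interval coordinates in this package are 0-based half-open. Two
#' intervals overlap exactly when they share at least one base pair:
#' same chromosome and `max(starts) < min(ends)`.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end` (rows are
#'   recycled to a common length).
#' @return Logical vector of pairwise overlap calls.
#' @export
interval_overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] &
    pmax(a$start[ai], b$start[bi]) < pmin(a$end[ai], b$end[bi])
}

validate_intervals <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    stop2(what, " table must have chrom, start, end columns")
  if (any(x$start < 0)) stop2(what, " with negative start")
  if (any(x$start >= x$end)) stop2(what, " with start >= end")
  if (any(!nzchar(x$chrom))) stop2(what, " with empty chromosome name")
  invisible(x)
}

df_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Accessible-chromatin peak set
#'
#' Wraps a dataset's peak intervals; overlapping peaks are collapsed at load
#' time (replicate merging), leaving a sorted, non-overlapping set.
#'
#' @param dataset_id Dataset name.
#' @param species Species name.
#' @param role `"IEC"` or `"non_IEC"`.
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return An object of class `iec_peakset`.
#' @export
peak_set <- function(dataset_id, species, role = c("IEC", "non_IEC"),
                     intervals) {
  role <- match.arg(role)
  if (nrow(intervals)) {
    validate_intervals(intervals, "peak")
    intervals <- granges_to_df(GenomicRanges::reduce(df_to_granges(intervals)))
    intervals <- intervals[order(intervals$chrom, intervals$start), ,
                           drop = FALSE]
    rownames(intervals) <- NULL
  }
  structure(list(dataset_id = dataset_id, species = species, role = role,
                 intervals = intervals), class = "iec_peakset")
}

#' @export
print.iec_peakset <- function(x, ...) {
  cat(sprintf("Peak set '%s' (%s, %s): %d merged peaks\n", x$dataset_id,
              x$species, x$role, nrow(x$intervals)))
  invisible(x)
}

#' Strand-aware windows around gene landmarks
#'
#' Computes the regulatory-region proxies used throughout: the 1 kb region
#' upstream of the TSS, the 1 kb or 100 bp window centred on the TSS, or the
#' gene regulatory domain (gene span extended by 10 kb on both sides).
#' "Upstream" means 5' of the TSS relative to the gene's strand. Windows
#' clipped at position 0 are flagged in a `clipped` column.
#'
#' @param genes Gene table with `gene_id`, `chrom`, `strand`, `tss` (and
#'   `tts` for `regulatory_domain`); 0-based coordinates.
#' @param mode One of `upstream1000`, `centered1000`, `centered100`,
#'   `regulatory_domain`.
#' @param upstream_bp Width for `upstream1000` mode (default 1000; set 150
#'   for the motif co-occurrence window).
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `clipped`.
#' @export
tss_window <- function(genes, mode = c("upstream1000", "centered1000",
                                       "centered100", "regulatory_domain"),
                       upstream_bp = 1000L) {
  mode <- match.arg(mode)
  tss <- genes$tss
  if (mode == "upstream1000") {
    start <- ifelse(genes$strand == "+", tss - upstream_bp, tss)
    end <- start + upstream_bp
  } else if (mode == "centered1000") {
    start <- tss - 500L; end <- tss + 500L
  } else if (mode == "centered100") {
    start <- tss - 50L; end <- tss + 50L
  } else {
    if (is.null(genes$tts)) stop2("regulatory_domain mode requires a tts column")
    start <- pmin(tss, genes$tts) - 10000L
    end <- pmax(tss, genes$tts) + 10000L
  }
  clipped <- start < 0L
  start <- pmax(start, 0L)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, start = start,
             end = end, strand = genes$strand, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Region x dataset accessibility overlap matrix
#'
#' For each region and each peak set, records whether the region shares at
#' least one base pair with any peak of that dataset. Regions are tested in
#' the coordinate space of each dataset's species: `regions` is a long table
#' with one row per available (region, species) mapping, so a region with no
#' mapped coordinate in a dataset's species yields a missing (`NA`) cell, not
#' `FALSE`.
#'
#' @param regions Data frame with `id`, `species`, `chrom`, `start`, `end`
#'   (e.g. the `cnes` element of [simulate_peaks()], or TSS windows given a
#'   constant `species` column).
#' @param peak_sets List of [peak_set()] objects.
#' @return Logical matrix regions x datasets with `NA` for unmapped cells;
#'   attribute `totals` carries per-dataset overlap totals.
#' @export
build_overlap_matrix <- function(regions, peak_sets) {
  validate_intervals(regions, "region")
  if (is.null(regions$id)) stop2("regions need an id column")
  if (is.null(regions$species)) stop2("regions need a species column")
  ids <- unique(regions$id)
  ds <- vapply(peak_sets, function(p) p$dataset_id, character(1))
  hits <- matrix(NA, length(ids), length(peak_sets),
                 dimnames = list(ids, ds))
  for (j in seq_along(peak_sets)) {
    ps <- peak_sets[[j]]
    reg <- regions[regions$species == ps$species, , drop = FALSE]
    if (!nrow(reg)) next
    ov <- if (nrow(ps$intervals)) {
      q <- df_to_granges(reg)
      s <- df_to_granges(ps$intervals)
      IRanges::overlapsAny(q, s)
    } else rep(FALSE, nrow(reg))
    hits[match(reg$id, ids), j] <- ov
  }
  attr(hits, "totals") <- colSums(hits, na.rm = TRUE)
  hits
}

#' Classify regions by tissue-specific accessibility
#'
#' A region is `IEC_specific` when it is accessible in every IEC dataset and
#' inaccessible in at least `min_noniec_absent` non-IEC datasets; it is
#' `constitutive` when accessible in every IEC dataset and in at least
#' `constitutive_min_present` non-IEC datasets; otherwise `other`. The
#' default thresholds are the absolute counts 9 (absent) and 14 (present) of
#' a 17-dataset non-IEC roster; when the available (non-missing) roster for a
#' region differs in size, the thresholds generalise to the fractions 9/17
#' and 14/17 (rounded up). Missing cells are excluded from denominators; a
#' region whose cells are all missing is labelled `NA` and reported.
#'
#' @param matrix Overlap matrix from [build_overlap_matrix()].
#' @param iec_datasets,noniec_datasets Column names by role.
#' @param min_noniec_absent,constitutive_min_present Absolute thresholds used
#'   when a region has exactly 17 available non-IEC cells; otherwise scaled
#'   as fractions of the available roster.
#' @return Data frame `id`, `label`, `n_iec_present`, `n_noniec_present`,
#'   `n_noniec_available`.
#' @export
classify_regions <- function(matrix, iec_datasets, noniec_datasets,
                             min_noniec_absent = 9L,
                             constitutive_min_present = 14L) {
  miss <- setdiff(c(iec_datasets, noniec_datasets), colnames(matrix))
  if (length(miss)) stop2("datasets absent from matrix: ",
                          paste(miss, collapse = ", "))
  ref_n <- 17L
  out <- lapply(rownames(matrix), function(r) {
    iec <- matrix[r, iec_datasets]
    non <- matrix[r, noniec_datasets]
    iec_avail <- iec[!is.na(iec)]
    non_avail <- non[!is.na(non)]
    n_av <- length(non_avail)
    if (!length(iec_avail) && !n_av)
      return(data.frame(id = r, label = NA_character_, n_iec_present = NA_integer_,
                        n_noniec_present = NA_integer_,
                        n_noniec_available = 0L, stringsAsFactors = FALSE))
    thr_abs <- ceiling(min_noniec_absent / ref_n * n_av)
    thr_pres <- ceiling(constitutive_min_present / ref_n * n_av)
    all_iec <- length(iec_avail) > 0 && all(iec_avail)
    n_pres <- sum(non_avail)
    label <- if (all_iec && (n_av - n_pres) >= thr_abs) "IEC_specific"
    else if (all_iec && n_pres >= thr_pres) "constitutive"
    else "other"
    data.frame(id = r, label = label, n_iec_present = sum(iec_avail),
               n_noniec_present = n_pres, n_noniec_available = n_av,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
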