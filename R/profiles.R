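#' Signal metaprofile around genomic centers
#'
#' Extracts per-base signal from a bedGraph-style track over
#' `[center - flank, center + flank)` for each center, one row per center and
#' one column per offset. Rows for minus-strand centers are mirror-flipped so
#' profiles are reported in a 5' to 3' gene-relative frame (set
#' `orient = "genome"` to keep genomic orientation). Centers on chromosomes
#' absent from `chrom_sizes` (when given) or from the track produce rows of
#' missing values and are flagged.
#'
#' @param track Data frame `chrom`, `start`, `end`, `score` (bedGraph
#'   semantics: 0-based half-open, uncovered positions are 0).
#' @param centers Data frame with `chrom`, `pos` (0-based base coordinate)
#'   and optionally `strand` (default `+`).
#' @param flank Half-width in bp (default 500, the 1 kb window).
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   flag off-chromosome centers.
#' @param orient `"gene"` (strand-flipped) or `"genome"`.
#' @return Numeric matrix centers x offsets (columns named by offset,
#'   `-flank` to `flank - 1`); attribute `flagged` lists off-chromosome
#'   center indices.
#' @export
signal_profile <- function(track, centers, flank = 500L, chrom_sizes = NULL,
                           orient = c("gene", "genome")) {
  orient <- match.arg(orient)
  strand <- centers$strand %||% rep("+", nrow(centers))
  offsets <- seq(-flank, flank - 1L)
  prof <- matrix(0, nrow(centers), 2L * flank,
                 dimnames = list(NULL, offsets))
  flagged <- integer(0)
  by_chr <- split(track, track$chrom)
  by_chr <- lapply(by_chr, function(d) d[order(d$start), , drop = FALSE])
  for (i in seq_len(nrow(centers))) {
    chr <- centers$chrom[i]
    off_chrom <- !is.null(chrom_sizes) &&
      (!chr %in% names(chrom_sizes) ||
         centers$pos[i] < 0 || centers$pos[i] >= chrom_sizes[[chr]])
    if (off_chrom || (is.null(chrom_sizes) && !chr %in% names(by_chr))) {
      if (off_chrom) {
        prof[i, ] <- NA_real_
        flagged <- c(flagged, i)
        next
      }
      # chromosome simply uncovered by the track: all-zero row
      next
    }
    d <- by_chr[[chr]]
    pos <- centers$pos[i] + offsets
    v <- numeric(length(pos))
    if (!is.null(d) && nrow(d)) {
      idx <- findInterval(pos, d$start)
      ok <- idx >= 1L & pos < d$end[pmax(idx, 1L)]
      v[ok] <- d$score[idx[ok]]
    }
    v[pos < 0] <- 0
    if (orient == "gene" && strand[i] == "-") v <- rev(v)
    prof[i, ] <- v
  }
  attr(prof, "flagged") <- flagged
  prof
}

#' Order profile rows by signal
#'
#' Rows can be ordered by the signal at the center base (offset 0) or by the
#' total signal in a centred window (e.g. the TSS +/- 50 bp sum).
#'
#' @param profile Matrix from [signal_profile()].
#' @param by `"center"` or `"sum"`.
#' @param window Window width (bp) for `by = "sum"`, centred on offset 0.
#' @param decreasing Sort direction.
#' @return Integer row order.
#' @export
profile_order <- function(profile, by = c("center", "sum"), window = 100L,
                          decreasing = TRUE) {
  by <- match.arg(by)
  offs <- as.integer(colnames(profile))
  key <- if (by == "center") profile[, which(offs == 0L)]
  else rowSums(profile[, offs >= -window / 2 & offs < window / 2,
                       drop = FALSE])
  order(key, decreasing = decreasing)
}

#' Moving median over an ordered vector
#'
#' Median of each sliding window, reported at window centers with truncated
#' edges (no padding): the output has `floor((n - window) / step) + 1`
#' values. The study-style smoothing uses 500- or 250-element windows with a
#' 1-element step.
#'
#' @param values Ordered numeric vector.
#' @param window Window size (elements), `1 <= window <= length(values)`.
#' @param step Step size (elements).
#' @return Numeric vector of window medians.
#' @export
moving_median <- function(values, window, step = 1L) {
  n <- length(values)
  if (window < 1L || step < 1L) stop2("window and step must be >= 1")
  if (window > n) stop2("window (", window, ") exceeds vector length (", n, ")")
  as.numeric(zoo::rollapply(values, width = window, FUN = stats::median,
                            by = step, align = "center"))
}

#' Sliding-mean smoothing (for AT% profiles)
#'
#' @param values Numeric vector.
#' @param window Window size (elements).
#' @param step Step size.
#' @return Window means at window centers, truncated edges.
#' @export
moving_mean <- function(values, window, step = 1L) {
  n <- length(values)
  if (window < 1L || step < 1L) stop2("window and step must be >= 1")
  if (window > n) stop2("window (", window, ") exceeds vector length (", n, ")")
  as.numeric(zoo::rollapply(values, width = window, FUN = mean, by = step,
                            align = "center"))
}
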