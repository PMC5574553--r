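#' Extract strand-aware upstream promoter sequences
#'
#' Returns, for each gene, the `window_bp` bases immediately upstream of the
#' TSS in gene orientation (reverse-complemented for minus-strand genes so
#' motifs read 5' to 3'). Windows running off the chromosome start are
#' clipped and flagged.
#'
#' @param genome Named list of chromosome strings.
#' @param genes Gene table (`gene_id`, `chrom`, `strand`, `tss`).
#' @param window_bp Window width (default 150).
#' @return Named character vector of sequences; attribute `clipped` names
#'   clipped genes.
#' @export
upstream_sequences <- function(genome, genes, window_bp = 150L) {
  out <- character(nrow(genes))
  clipped <- character(0)
  chrom_len <- vapply(genome, nchar, integer(1))
  for (i in seq_len(nrow(genes))) {
    chrom <- genome[[genes$chrom[i]]]
    if (is.null(chrom)) stop2("chromosome '", genes$chrom[i], "' not in genome")
    n <- chrom_len[[genes$chrom[i]]]
    if (genes$strand[i] == "+") {
      s0 <- genes$tss[i] - window_bp
      if (s0 < 0) { clipped <- c(clipped, genes$gene_id[i]); s0 <- 0L }
      e0 <- genes$tss[i]
      seq <- substr(chrom, s0 + 1L, e0)
    } else {
      s0 <- genes$tss[i]
      e0 <- genes$tss[i] + window_bp
      if (e0 > n) { clipped <- c(clipped, genes$gene_id[i]); e0 <- n }
      seq <- revcomp(substr(chrom, s0 + 1L, e0))
    }
    out[i] <- seq
  }
  names(out) <- genes$gene_id
  attr(out, "clipped") <- clipped
  out
}

#' Motif co-occurrence in promoter windows
#'
#' A gene is positive when every supplied PWM has at least one hit in the
#' gene's `window_bp` upstream window (a conjunction over motifs). Reports
#' the per-gene calls and the count and fraction of positive genes, the
#' promoter-co-occurrence statistic used to ask how often a motif cassette
#' occurs by chance.
#'
#' @param genes Gene table.
#' @param genome Named list of chromosome strings.
#' @param pwms List of `iec_pwm`.
#' @param window_bp Upstream window width (default 150).
#' @param both_strands Scan both orientations.
#' @return List with `per_gene` (data frame: gene_id, one logical column per
#'   motif, `positive`), `count`, `fraction`.
#' @export
cooccurrence <- function(genes, genome, pwms, window_bp = 150L,
                         both_strands = TRUE) {
  seqs <- upstream_sequences(genome, genes, window_bp)
  hit <- vapply(pwms, function(p)
    vapply(seqs, function(s)
      nrow(scan_pwm(s, p, both_strands = both_strands)) > 0L, logical(1)),
    logical(length(seqs)))
  hit <- matrix(hit, nrow = length(seqs),
                dimnames = list(genes$gene_id, names(pwms)))
  positive <- rowSums(hit) == length(pwms)
  per_gene <- data.frame(gene_id = genes$gene_id, hit,
                         positive = unname(positive),
                         stringsAsFactors = FALSE, row.names = NULL)
  list(per_gene = per_gene, count = sum(positive),
       fraction = mean(positive))
}

#' Cross-species intersection of co-occurrence-positive genes
#'
#' Given per-species positive gene sets, returns the ortholog tuples that
#' are positive in every queried species (projected through the 1-to-1
#' table).
#'
#' @param per_species_positives Named list (by species) of positive gene
#'   identifier vectors.
#' @param orthologs An [ortholog_table()].
#' @return Data frame of ortholog rows (columns = queried species) positive
#'   in all of them.
#' @export
cross_species_cooccurrence <- function(per_species_positives, orthologs) {
  stopifnot(inherits(orthologs, "iec_orthologs"))
  sps <- names(per_species_positives)
  missing_sp <- setdiff(sps, orthologs$species_order)
  if (length(missing_sp))
    stop2("species absent from ortholog table: ",
          paste(missing_sp, collapse = ", "))
  q <- orthologs$quartets
  keep <- rep(TRUE, nrow(q))
  for (sp in sps)
    keep <- keep & !is.na(q[[sp]]) & q[[sp]] %in% per_species_positives[[sp]]
  q[keep, sps, drop = FALSE]
}

#' Motif enrichment between foreground and background sequence sets
#'
#' ZOOPS counting (each sequence contributes once regardless of hit
#' multiplicity) followed by a one-sided hypergeometric test for foreground
#' presence given pooled presence, with Benjamini-Hochberg adjustment across
#' the motif library. Repeat masking is honoured: lowercase/N windows are
#' skipped by the scanner.
#'
#' @param fg,bg Non-empty character vectors of sequences.
#' @param pwms List of `iec_pwm` (the library).
#' @param both_strands Scan both orientations.
#' @return Data frame `motif`, `fg_frac`, `bg_frac`, `p`, `q` (BH-adjusted).
#' @export
motif_enrichment <- function(fg, bg, pwms, both_strands = TRUE) {
  if (!length(fg) || !length(bg)) stop2("fg and bg must be non-empty")
  rows <- lapply(pwms, function(p) {
    fg_hit <- sum(vapply(fg, function(s)
      nrow(scan_pwm(s, p, both_strands = both_strands)) > 0L, logical(1)))
    bg_hit <- sum(vapply(bg, function(s)
      nrow(scan_pwm(s, p, both_strands = both_strands)) > 0L, logical(1)))
    data.frame(motif = p$name, fg_frac = fg_hit / length(fg),
               bg_frac = bg_hit / length(bg),
               p = presence_hyper_p(fg_hit, bg_hit, length(fg), length(bg)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

# One-sided hypergeometric tail: probability of >= fg_hit foreground
# presences when (fg_hit + bg_hit) present sequences are distributed at
# random over the pooled n_fg + n_bg sequences.
presence_hyper_p <- function(fg_hit, bg_hit, n_fg, n_bg) {
  stats::phyper(fg_hit - 1, fg_hit + bg_hit, n_fg + n_bg - fg_hit - bg_hit,
                n_fg, lower.tail = FALSE)
}

#' AT-content metaprofile around genomic centers
#'
#' For each offset relative to the centers, the fraction of bases that are A
#' or T, averaged over centers (strand-aware, minus-strand windows mirror
#' flipped) and then smoothed with a sliding mean (default 20 bp window,
#' 1 bp step). Off-chromosome positions are excluded from the per-offset
#' denominator.
#'
#' @param genome Named list of chromosome strings.
#' @param centers Data frame `chrom`, `pos`, optional `strand`.
#' @param flank Half-width in bp (`flank >= window`).
#' @param window,step Smoothing window and step in bp.
#' @return List of class `iec_at_profile`: `offsets` (of the smoothed
#'   values), `fraction` (smoothed), `raw` (unsmoothed per-offset
#'   fractions at offsets `-flank .. flank-1`), `n_centers`.
#' @export
at_profile <- function(genome, centers, flank = 500L, window = 20L,
                       step = 1L) {
  if (flank < window) stop2("flank must be at least the smoothing window")
  offsets <- seq(-flank, flank - 1L)
  strand <- centers$strand %||% rep("+", nrow(centers))
  acc <- numeric(length(offsets))
  cnt <- numeric(length(offsets))
  # per-chromosome AT indicator, computed once
  at_ind <- lapply(genome, function(chrom) {
    ints <- utf8ToInt(chrom)
    as.numeric(ints %in% c(65L, 84L, 97L, 116L))   # A/T, either case
  })
  for (i in seq_len(nrow(centers))) {
    ind <- at_ind[[centers$chrom[i]]]
    if (is.null(ind)) next
    n <- length(ind)
    pos <- centers$pos[i] + offsets
    ok <- pos >= 0 & pos < n
    if (!any(ok)) next
    v <- rep(NA_real_, length(offsets))
    v[ok] <- ind[pos[ok] + 1L]
    if (strand[i] == "-") v <- rev(v)
    use <- !is.na(v)
    acc[use] <- acc[use] + v[use]
    cnt[use] <- cnt[use] + 1
  }
  raw <- ifelse(cnt > 0, acc / cnt, NA_real_)
  sm <- moving_mean(raw, window = window, step = step)
  off_sm <- zoo::rollapply(offsets, width = window, FUN = function(z)
    mean(range(z)), by = step, align = "center")
  structure(list(offsets = as.numeric(off_sm), fraction = sm, raw = raw,
                 raw_offsets = offsets, n_centers = nrow(centers)),
            class = "iec_at_profile")
}

#' @export
print.iec_at_profile <- function(x, ...) {
  cat(sprintf("AT%% profile over %d centers: mean %.1f%% (range %.1f-%.1f%%)\n",
              x$n_centers, 100 * mean(x$fraction, na.rm = TRUE),
              100 * min(x$fraction, na.rm = TRUE),
              100 * max(x$fraction, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.iec_at_profile <- function(x, ...) {
  graphics::plot(x$offsets, 100 * x$fraction, type = "l",
                 xlab = "offset from center (bp)", ylab = "AT%", ...)
  invisible(x)
}
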