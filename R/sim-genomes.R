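#' Simulate per-species genomes and gene models
#'
#' Each species receives a single chromosome drawn i.i.d. per base with the
#' configured species AT fraction (A and T equiprobable, likewise C and G),
#' and a gene table of `n_genes` evenly spaced genes with alternating strand.
#' Planted motif consensus strings are overwritten at their recorded promoter
#' offsets (reverse-complemented on minus-strand genes), so every planted
#' instance is retrievable verbatim from the genome at its recorded
#' coordinates.
#'
#' The default planting plan places both default motifs (see [iec_pwms()]) in
#' the 150 bp upstream of the first `n_cooccur` genes of every species, and
#' only the first motif in the next `n_single_motif` genes.
#'
#' @param config An [sim_config()] object.
#' @param pwms Named list of `iec_pwm` used for consensus planting.
#' @return A list with elements `genomes` (per species, a named list of
#'   chromosome strings), `gene_tables` (per species, a data frame with
#'   `gene_id`, `chrom`, `strand`, `tss`, `tts`; 0-based coordinates), and
#'   `motif_truth` (data frame of planted instances: species, gene, motif,
#'   chrom, start, end, strand, seq).
#' @export
simulate_genomes <- function(config, pwms = iec_pwms()) {
  stopifnot(inherits(config, "iec_sim_config"))
  plan <- config$planted_motifs %||% default_motif_plan(config, pwms)
  ids <- gene_ids(config)
  spacing <- config$gene_spacing
  # tail margin hosts the CNE-like test regions of simulate_peaks()
  n_regions <- config$n_iec_specific + config$n_constitutive + config$n_background
  glen <- config$n_genes * spacing + n_regions * 1000L + 2000L

  genomes <- list()
  gene_tables <- list()
  truth <- list()
  for (sp in config$species) {
    set.seed(sub_seed(config$seed, paste0("genome_", sp)))
    at <- config$at_fraction[[sp]]
    bases <- sample(c("A", "T", "C", "G"), glen, replace = TRUE,
                    prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
    strand <- rep(c("+", "-"), length.out = config$n_genes)
    body_len <- 800L
    a <- (seq_len(config$n_genes) - 1L) * spacing + 600L
    tss <- ifelse(strand == "+", a, a + body_len - 1L)
    tts <- ifelse(strand == "+", a + body_len - 1L, a)
    # zebrafish is the anchor species and keeps bare identifiers
    sp_ids <- if (sp == "zebrafish") ids else
      paste0(species_prefix(sp), "_", ids)
    gt <- data.frame(gene_id = sp_ids, chrom = "chr1", strand = strand,
                     tss = tss, tts = tts, stringsAsFactors = FALSE)
    # plant motif consensus strings at recorded upstream offsets
    # (the plan names genes by their anchor-species identifier)
    if (nrow(plan)) {
      gi <- match(plan$gene, ids)
      if (anyNA(gi)) stop2("planted motif refers to unknown gene")
      for (k in seq_len(nrow(plan))) {
        mot <- pwms[[plan$motif[k]]]
        if (is.null(mot)) stop2("unknown motif '", plan$motif[k], "' in plan")
        cons <- pwm_consensus(mot)
        L <- nchar(cons)
        o <- plan$offset[k]
        g <- gi[k]
        if (gt$strand[g] == "+") {
          start0 <- gt$tss[g] - o
          ins <- cons
          hs <- "+"
        } else {
          start0 <- gt$tss[g] + o - L + 1L
          ins <- revcomp(cons)
          hs <- "-"
        }
        if (start0 < 0L || start0 + L > glen)
          stop2("motif '", plan$motif[k], "' planted outside sequence bounds ",
                "for gene ", plan$gene[k])
        bases[(start0 + 1L):(start0 + L)] <- strsplit(ins, "")[[1]]
        truth[[length(truth) + 1L]] <-
          data.frame(species = sp, gene = sp_ids[g], motif = plan$motif[k],
                     chrom = "chr1", start = start0, end = start0 + L,
                     strand = hs, seq = ins, stringsAsFactors = FALSE)
      }
    }
    # scrub chance consensus occurrences from promoter windows so planted
    # instances are the only ones there and recovery is deterministic
    bases <- scrub_promoter_windows(bases, gt, pwms, plan, ids,
                                    window_bp = 150L)
    genomes[[sp]] <- list(chr1 = paste(bases, collapse = ""))
    gene_tables[[sp]] <- gt
  }
  motif_truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species = character(0), gene = character(0),
               motif = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               seq = character(0), stringsAsFactors = FALSE)
  list(genomes = genomes, gene_tables = gene_tables, motif_truth = motif_truth)
}

# Remove chance (non-planted) exact consensus occurrences, either strand,
# from every gene's upstream co-occurrence window by flipping one base.
# Near-deterministic planted PWMs admit no mismatches at their default
# threshold, so exact-string scrubbing suffices to make planted instances
# the only detectable ones in promoter windows.
scrub_promoter_windows <- function(bases, gt, pwms, plan, anchor_ids,
                                   window_bp = 150L) {
  pats <- lapply(pwms, function(p) {
    cons <- pwm_consensus(p)
    unique(c(cons, revcomp(cons)))
  })
  glen <- length(bases)
  for (g in seq_len(nrow(gt))) {
    if (gt$strand[g] == "+") {
      s0 <- max(gt$tss[g] - window_bp, 0L)
      e0 <- gt$tss[g]
    } else {
      s0 <- gt$tss[g]
      e0 <- min(gt$tss[g] + window_bp, glen)
    }
    if (e0 <= s0) next
    win <- paste(bases[(s0 + 1L):e0], collapse = "")
    planted_here <- plan[anchor_ids[g] == plan$gene, , drop = FALSE]
    for (m in seq_along(pwms)) {
      L <- nchar(pats[[m]][1])
      # genomic starts (0-based) of planted instances of this motif here
      keep <- integer(0)
      hit_rows <- planted_here[planted_here$motif == names(pwms)[m], ,
                               drop = FALSE]
      if (nrow(hit_rows)) {
        keep <- if (gt$strand[g] == "+") gt$tss[g] - hit_rows$offset else
          gt$tss[g] + hit_rows$offset - L + 1L
      }
      for (pat in pats[[m]]) {
        hits <- gregexpr(pat, win, fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        for (h in hits) {
          start0 <- s0 + h - 1L
          if (start0 %in% keep) next
          mid <- start0 + (L %/% 2) + 1L
          bases[mid] <- chartr("ACGT", "CTAG", bases[mid])
          win <- paste(bases[(s0 + 1L):e0], collapse = "")
        }
      }
    }
  }
  bases
}

# Both motifs upstream of the first n_cooccur genes, the first motif only in
# the next n_single_motif genes; offsets chosen to sit inside the 150 bp
# co-occurrence window without overlapping each other.
default_motif_plan <- function(config, pwms) {
  ids <- gene_ids(config)
  nm <- names(pwms)
  plan <- list()
  if (config$n_cooccur > 0) {
    g <- ids[seq_len(config$n_cooccur)]
    plan[[1]] <- data.frame(gene = rep(g, each = length(nm)),
                            motif = rep(nm, length(g)),
                            offset = rep(c(120L, 60L)[seq_along(nm)], length(g)),
                            stringsAsFactors = FALSE)
  }
  if (config$n_single_motif > 0) {
    g <- ids[config$n_cooccur + seq_len(config$n_single_motif)]
    plan[[length(plan) + 1L]] <-
      data.frame(gene = g, motif = nm[1], offset = 120L,
                 stringsAsFactors = FALSE)
  }
  if (!length(plan))
    return(data.frame(gene = character(0), motif = character(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, plan)
}

#' AT fraction of a genome or sequence set
#' @param genome A named list of chromosome strings, or a character vector.
#' @return Fraction of bases that are A or T.
#' @export
at_fraction <- function(genome) {
  seqs <- if (is.list(genome)) unlist(genome, use.names = FALSE) else genome
  comp <- base_composition(seqs)
  unname(comp["A"] + comp["T"])
}
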