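#' Position weight matrix with log-odds scoring
#'
#' Constructs a PWM object from a 4 x L matrix of per-position base
#' probabilities (or counts, which are normalised column-wise). Scores are
#' log2 odds against a background mononucleotide composition, with a small
#' pseudocount added to probabilities before taking logs so absent bases score
#' finitely rather than -Inf.
#'
#' @param name Motif name.
#' @param mat 4 x L numeric matrix with rows A, C, G, T (counts or
#'   probabilities; columns are normalised to sum to 1).
#' @param background Base frequencies (A, C, G, T); defaults to uniform.
#'   Composition-aware backgrounds (e.g. computed from the scanned genome via
#'   [base_composition()]) avoid AT-driven false hits in AT-rich genomes.
#' @param threshold Minimum log-odds detection score. Default is 80% of the
#'   maximum attainable score; motif-file thresholds override it.
#' @param pseudocount Probability added before the log (default `1e-3`).
#' @return An object of class `iec_pwm`.
#' @export
pwm <- function(name, mat, background = rep(0.25, 4), threshold = NULL,
                pseudocount = 1e-3) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop2("PWM matrix must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4L) stop2("PWM must be at least 4 positions long")
  if (any(mat < 0)) stop2("PWM entries must be non-negative")
  cs <- colSums(mat)
  if (any(cs <= 0)) stop2("PWM column with zero total")
  mat <- sweep(mat, 2, cs, "/")
  rownames(mat) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  score_mat <- log2((mat + pseudocount) / background)
  max_score <- sum(apply(score_mat, 2, max))
  if (is.null(threshold)) threshold <- 0.8 * max_score
  if (threshold > max_score + 1e-9)
    stop2("threshold exceeds the maximum attainable score")
  structure(list(name = name, probabilities = mat, background = background,
                 score_matrix = score_mat, threshold = threshold,
                 max_score = max_score, length = ncol(mat)),
            class = "iec_pwm")
}

#' @export
print.iec_pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': length %d, max score %.2f bits, threshold %.2f\n",
              x$name, x$length, x$max_score, x$threshold))
  cat("  consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (per-position argmax base)
#' @param x An `iec_pwm` object.
#' @return A character string of length `x$length`.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$probabilities)[apply(x$probabilities, 2, which.max)],
        collapse = "")
}

#' Build a near-deterministic PWM from a consensus string
#'
#' Consensus bases receive probability `1 - 3 * eps`; all others `eps`.
#' Useful for planting recoverable motif instances in simulations.
#'
#' @param name Motif name.
#' @param consensus Consensus string over A/C/G/T.
#' @param eps Off-consensus base probability.
#' @inheritParams pwm
#' @return An `iec_pwm` object.
#' @export
consensus_pwm <- function(name, consensus, eps = 1e-3,
                          background = rep(0.25, 4), threshold = NULL) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop2("consensus must be over A/C/G/T")
  m <- matrix(eps, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- 1 - 3 * eps
  pwm(name, m, background = background, threshold = threshold)
}

#' Default intestinal transcription-factor motifs
#'
#' The two-motif library used by the synthetic cohort: an HNF4A-like
#' nuclear-receptor half-site motif and a GATA-family motif. Both are
#' near-deterministic consensus PWMs so planted instances are recovered at any
#' sensible threshold.
#'
#' @return A named list of two `iec_pwm` objects (`HNF4A`, `GATA4`).
#' @export
iec_pwms <- function() {
  list(HNF4A = consensus_pwm("HNF4A", "GGGGCAAAGGTCA"),
       GATA4 = consensus_pwm("GATA4", "AGATAAGA"))
}

#' Read motifs in JASPAR PFM format
#'
#' Supports the four-line `A [ ... ]` count layout under `>` headers; counts
#' are normalised column-wise.
#'
#' @param path Motif file.
#' @inheritParams pwm
#' @return A named list of `iec_pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), threshold = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop2("no JASPAR records found in ", path)
  out <- list()
  for (s in starts) {
    name <- sub("^>\\s*\\S*\\s*", "", lines[s])
    if (!nzchar(name)) name <- sub("^>\\s*", "", lines[s])
    rows <- lines[s + 1:4]
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      as.numeric(strsplit(trimws(gsub("[][]", " ", r)), "\\s+")[[1]])
    })
    m <- do.call(rbind, vals)
    out[[name]] <- pwm(name, m, background = background, threshold = threshold)
  }
  out
}

#' Read motifs in Homer `.motif` format
#'
#' Header lines are `>consensus name log-odds-threshold`; body rows are L x 4
#' per-position probabilities (A, C, G, T). The file threshold is kept when
#' present (converted from natural-log to log2 units); otherwise the package
#' default of 80% of the maximum score applies.
#'
#' @inheritParams read_jaspar
#' @param use_file_threshold Keep the per-motif threshold stored in the file.
#' @return A named list of `iec_pwm` objects.
#' @export
read_homer <- function(path, background = rep(0.25, 4),
                       use_file_threshold = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop2("no Homer records found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[i]]), "\t|\\s+")[[1]]
    name <- if (length(hdr) >= 2) hdr[2] else hdr[1]
    thr <- if (use_file_threshold && length(hdr) >= 3 &&
               !is.na(suppressWarnings(as.numeric(hdr[3]))))
      as.numeric(hdr[3]) / log(2) else NULL
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    m <- t(vapply(body, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    out[[name]] <- pwm(name, t(m), background = background, threshold = thr)
  }
  out
}

#' Mononucleotide composition of sequences
#'
#' @param seqs Character vector of nucleotide sequences.
#' @return Named frequencies over A, C, G, T (N and masked bases ignored).
#' @export
base_composition <- function(seqs) {
  tab <- table(factor(strsplit(toupper(paste(seqs, collapse = "")), "")[[1]],
                      levels = c("A", "C", "G", "T")))
  as.numeric(tab) / sum(tab) -> f
  names(f) <- c("A", "C", "G", "T")
  f
}

#' Reverse complement of a nucleotide string
#' @param seq Character string over A/C/G/T/N (case preserved).
#' @return Reverse complement string.
#' @export
revcomp <- function(seq) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", seq))))
}

# Encode a sequence as integer codes 1..4 (A,C,G,T); anything else (N) is NA.
# Lowercase (repeat-masked) bases are flagged separately.
encode_seq <- function(seq) {
  ints <- utf8ToInt(seq)
  lower <- ints >= 97L
  masked <- lower | ints == 78L        # lowercase or N
  up <- ifelse(lower, ints - 32L, ints)
  code <- match(up, c(65L, 67L, 71L, 84L))
  list(code = code, masked = masked)
}

scan_one_strand <- function(code, masked, pwm, honor_mask) {
  L <- pwm$length
  n <- length(code)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  bad <- logical(nw)
  S <- pwm$score_matrix
  miss0 <- is.na(code)
  code_f <- code
  code_f[miss0] <- 1L
  for (j in seq_len(L)) {
    idx <- j:(j + nw - 1L)
    bad <- bad | miss0[idx]
    if (honor_mask) bad <- bad | masked[idx]
    sc <- sc + S[code_f[idx], j]
  }
  sc[bad] <- -Inf
  sc
}

#' Scan a sequence for PWM hits
#'
#' Slides the PWM over every window of the sequence and reports windows whose
#' log2-odds score reaches the detection threshold, on both strands by
#' default. Windows containing `N` are skipped; lowercase (repeat-masked)
#' bases are also skipped unless `honor_mask = FALSE`. Coordinates are
#' 0-based half-open within the supplied sequence (plus `offset`).
#'
#' @param seq Nucleotide string.
#' @param pwm An `iec_pwm` object.
#' @param both_strands Scan the reverse complement as well.
#' @param threshold Override the PWM's stored threshold.
#' @param offset Constant added to reported coordinates (e.g. a chromosomal
#'   start).
#' @param honor_mask Skip windows containing lowercase-masked bases.
#' @return Data frame with columns `start`, `end`, `strand`, `score`,
#'   `motif`; zero rows when nothing reaches threshold. A sequence shorter
#'   than the motif yields an empty result with attribute `too_short = TRUE`.
#' @export
scan_pwm <- function(seq, pwm, both_strands = TRUE, threshold = NULL,
                     offset = 0L, honor_mask = TRUE) {
  stopifnot(inherits(pwm, "iec_pwm"))
  thr <- threshold %||% pwm$threshold
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      motif = character(0), stringsAsFactors = FALSE)
  n <- nchar(seq)
  L <- pwm$length
  if (n < L) {
    attr(empty, "too_short") <- TRUE
    return(empty)
  }
  enc <- encode_seq(seq)
  sc_f <- scan_one_strand(enc$code, enc$masked, pwm, honor_mask)
  hits_f <- which(sc_f >= thr)
  res <- list()
  if (length(hits_f))
    res[[1]] <- data.frame(start = hits_f - 1L, end = hits_f - 1L + L,
                           strand = "+", score = sc_f[hits_f],
                           motif = pwm$name, stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- revcomp(seq)
    # preserve mask by mirroring the mask vector
    enc_rc <- list(code = encode_seq(rc)$code, masked = rev(enc$masked))
    sc_r <- scan_one_strand(enc_rc$code, enc_rc$masked, pwm, honor_mask)
    hits_r <- which(sc_r >= thr)
    if (length(hits_r)) {
      start0 <- n - (hits_r - 1L) - L
      res[[length(res) + 1L]] <-
        data.frame(start = start0, end = start0 + L, strand = "-",
                   score = sc_r[hits_r], motif = pwm$name,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out$start <- out$start + offset
  out$end <- out$end + offset
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Verify an in-silico motif knockout
#'
#' Mirrors site-directed mutagenesis screening: the mutation ablates the motif
#' exactly when the original sequence carries at least one hit and the mutated
#' sequence carries none at the same threshold.
#'
#' @param original,mutated Equal-length nucleotide strings.
#' @inheritParams scan_pwm
#' @return `TRUE` if the motif is ablated, `FALSE` otherwise. It is an error
#'   to call this when the original has no hit (nothing to ablate).
#' @export
verify_knockout <- function(original, mutated, pwm, threshold = NULL,
                            both_strands = TRUE) {
  if (nchar(original) != nchar(mutated))
    stop2("original and mutated sequences must have equal length")
  h0 <- scan_pwm(original, pwm, both_strands = both_strands,
                 threshold = threshold)
  if (nrow(h0) == 0L)
    stop2("no '", pwm$name, "' hit in the original sequence: nothing to ablate")
  h1 <- scan_pwm(mutated, pwm, both_strands = both_strands,
                 threshold = threshold)
  nrow(h1) == 0L
}
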