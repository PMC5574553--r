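# Small cohort configuration for fast unit tests; full-scale study
# conditions (sim_config() defaults) are exercised in test-acceptance.R.
small_config <- function(seed = 42L, ...) {
  args <- list(seed = seed, n_genes = 150L, n_signature = 15L,
               n_conserved_regional = 24L, n_shuffled_regional = 24L,
               n_flat_regional = 8L, n_iec_specific = 8L, n_constitutive = 8L,
               n_background = 12L, n_cooccur = 6L, n_single_motif = 6L,
               n_ribosomal = 4L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Naive O(n^3) complete-linkage agglomeration: returns sorted merge heights.
naive_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# Per-base set intersection oracle for the interval overlap rule.
overlap_per_base_oracle <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1L), seq(b$start, b$end - 1L))) > 0L
}

# Exhaustive per-window PWM scoring oracle (forward strand, uppercase only).
naive_scan_scores <- function(seq, pwm) {
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- pwm$length
  n <- length(ch)
  if (n < L) return(numeric(0))
  vapply(seq_len(n - L + 1L), function(i) {
    w <- ch[i:(i + L - 1L)]
    if (any(!w %in% c("A", "C", "G", "T"))) return(-Inf)
    sum(pwm$score_matrix[cbind(match(w, c("A", "C", "G", "T")), seq_len(L))])
  }, numeric(1))
}

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}
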