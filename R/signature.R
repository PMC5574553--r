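#' Filter to genes with detectable expression
#'
#' Retains genes whose FPKM reaches `min_value` in at least one sample
#' ("detectable mRNA signal across tissues").
#'
#' @param values Genes x samples FPKM matrix (non-negative).
#' @param min_value Detection threshold in FPKM (>= 0).
#' @return The filtered matrix; a warning is issued when no gene survives.
#' @export
detectable_filter <- function(values, min_value = 1) {
  if (min_value < 0) stop2("min_value must be non-negative")
  if (any(values < 0)) stop2("FPKM values must be non-negative")
  keep <- apply(values, 1, max) >= min_value
  if (!any(keep)) warning("no genes pass the detectable-expression filter")
  values[keep, , drop = FALSE]
}

#' Pairwise Pearson distance between samples
#'
#' `d(i, j) = 1 - Pearson(i, j)` over genes; symmetric with a zero diagonal.
#' Constant sample vectors make the correlation undefined; the affected pairs
#' are set to `NA` and flagged with a warning.
#'
#' @param values Genes x samples matrix.
#' @return Square samples x samples distance matrix; attribute
#'   `constant_samples` names flagged samples.
#' @export
pearson_distance_matrix <- function(values) {
  if (ncol(values) < 2L) stop2("need at least 2 samples")
  sds <- apply(values, 2, stats::sd)
  const <- colnames(values)[sds == 0]
  d <- 1 - suppressWarnings(stats::cor(values))
  diag(d) <- 0
  if (length(const))
    warning("constant sample vector(s), distance undefined: ",
            paste(const, collapse = ", "))
  attr(d, "constant_samples") <- const
  d
}

#' Complete-linkage hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under maximum linkage via [stats::hclust()]
#' (deterministic merge order; ties broken by lowest index).
#'
#' @param dist Square distance matrix (e.g. from
#'   [pearson_distance_matrix()]).
#' @return An `hclust` object (merge tree, heights, leaf order).
#' @export
complete_linkage_cluster <- function(dist) {
  d <- as.matrix(dist)
  bad <- which(!is.finite(d) & row(d) < col(d), arr.ind = TRUE)
  if (nrow(bad))
    stop2("non-finite distance between ",
          paste(rownames(d)[bad[1, 1]], colnames(d)[bad[1, 2]], sep = " and "))
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' First principal component of the samples
#'
#' PCA with samples as observations and genes as variables. By default the
#' FPKM matrix is `log10(FPKM + 1)`-transformed and gene-centred before the
#' decomposition (`transform = "raw"` uses centred FPKM directly). The PC1
#' sign is oriented so the mean score of IEC samples is at least the mean of
#' the others, making the signature-gene call invariant to the arbitrary
#' eigenvector sign.
#'
#' @param values Genes x samples FPKM matrix.
#' @param is_iec Logical per sample, used for sign orientation.
#' @param transform `"log10"` (default) or `"raw"`.
#' @return List with `scores` (named per-sample PC1 coordinates),
#'   `explained_variance` (fraction), and `transform`.
#' @export
pca_pc1 <- function(values, is_iec, transform = c("log10", "raw")) {
  transform <- match.arg(transform)
  if (ncol(values) < 2L || nrow(values) < 2L)
    stop2("need at least 2 samples and 2 genes")
  x <- if (transform == "log10") log10(values + 1) else values
  xt <- t(x)                      # samples x genes
  if (all(apply(xt, 2, stats::sd) == 0))
    stop2("matrix has zero variance; PCA undefined")
  pc <- stats::prcomp(xt, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  if (mean(scores[is_iec]) < mean(scores[!is_iec])) scores <- -scores
  list(scores = scores,
       explained_variance = pc$sdev[1]^2 / sum(pc$sdev^2),
       transform = transform)
}

#' Call tissue signature genes by PC1 loading correlation
#'
#' Computes, for each gene, the Pearson correlation between its expression
#' vector across samples (on the same transform used for the PCA) and the
#' PC1 sample scores; genes exceeding the threshold (strictly) form the
#' signature, after removal of ribosomal-protein genes. Genes with constant
#' expression have undefined correlation and are excluded with a flag.
#'
#' @param values Genes x samples FPKM matrix.
#' @param pc1_scores Per-sample PC1 scores from [pca_pc1()].
#' @param threshold Correlation cutoff in (0, 1]; strictly-greater-than.
#' @param ribosomal_ids Identifiers to exclude as ribosomal proteins; when
#'   `NULL`, identifiers matching the RPL/RPS prefix convention are used.
#' @param transform Transform applied before correlating (match the PCA).
#' @return List of class `iec_signature`: `gene_correlation` (named, `NA`
#'   for constant genes), `threshold`, `signature_genes`,
#'   `excluded_ribosomal` (signature-passing genes removed as ribosomal),
#'   `n_before_ribosomal_exclusion`, `flagged_constant`.
#' @export
call_signature <- function(values, pc1_scores, threshold = 0.7,
                           ribosomal_ids = NULL,
                           transform = c("log10", "raw")) {
  transform <- match.arg(transform)
  if (threshold <= 0 || threshold > 1)
    stop2("threshold must lie in (0, 1]")
  x <- if (transform == "log10") log10(values + 1) else values
  s <- pc1_scores[colnames(values)]
  sds <- apply(x, 1, stats::sd)
  r <- rep(NA_real_, nrow(x))
  names(r) <- rownames(x)
  ok <- sds > 0
  r[ok] <- suppressWarnings(stats::cor(t(x[ok, , drop = FALSE]), s))[, 1]
  passing <- names(r)[!is.na(r) & r > threshold]
  ribo <- ribosomal_ids %||% grep("^RP[LS]", rownames(x), value = TRUE)
  excluded <- intersect(passing, ribo)
  structure(list(gene_correlation = r, threshold = threshold,
                 signature_genes = setdiff(passing, ribo),
                 excluded_ribosomal = excluded,
                 n_before_ribosomal_exclusion = length(passing),
                 flagged_constant = names(r)[is.na(r)]),
            class = "iec_signature")
}

#' @export
print.iec_signature <- function(x, ...) {
  cat(sprintf(paste0("IEC signature: %d genes at correlation > %.2f ",
                     "(%d before ribosomal exclusion, %d excluded)\n"),
              length(x$signature_genes), x$threshold,
              x$n_before_ribosomal_exclusion, length(x$excluded_ribosomal)))
  invisible(x)
}

#' Write a signature result as TSV
#'
#' One row per gene: correlation, signature membership, ribosomal exclusion.
#'
#' @param x An `iec_signature` object.
#' @param path Output TSV path.
#' @export
write_signature <- function(x, path) {
  stopifnot(inherits(x, "iec_signature"))
  df <- data.frame(gene = names(x$gene_correlation),
                   correlation = unname(x$gene_correlation),
                   in_signature = names(x$gene_correlation) %in%
                     x$signature_genes,
                   ribosomal_excluded = names(x$gene_correlation) %in%
                     x$excluded_ribosomal,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
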