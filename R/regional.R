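#' Row-wise z-scoring of segment matrices
#'
#' Transforms each gene row to mean 0 and standard deviation 1. The
#' population (n) convention is the default, matching single-channel
#' microarray z-scoring; a sample (n-1) mode is available. Constant rows
#' (zero variance) cannot be z-scored: they are dropped and reported.
#'
#' @param values Genes x segments matrix of raw intensities.
#' @param sd_type `"population"` or `"sample"`.
#' @return List with `values` (z-scored matrix) and `dropped` (gene ids of
#'   constant rows).
#' @export
zscore_rows <- function(values, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (ncol(values) < 2L) stop2("need at least 2 segments")
  mu <- rowMeans(values)
  sds <- apply(values, 1, sd2, type = sd_type)
  const <- sds == 0
  z <- (values - mu) / sds
  list(values = z[!const, , drop = FALSE],
       dropped = rownames(values)[const])
}

#' Filter to genes expressed somewhere along the intestine
#'
#' Retains genes with at least one segment z-score greater than 0.
#'
#' @param values Z-scored genes x segments matrix.
#' @return The filtered matrix (empty-result warning, not an error).
#' @export
expressed_filter <- function(values) {
  keep <- apply(values, 1, max) > 0
  if (!any(keep)) warning("no genes pass the expressed filter")
  values[keep, , drop = FALSE]
}

#' Uncentered correlation similarity between rows
#'
#' `s(x, y) = sum(x * y) / sqrt(sum(x^2) * sum(y^2))`: cosine similarity
#' without mean-centering, invariant to positive scaling and bounded in
#' `[-1, 1]`.
#'
#' @param values Genes x segments matrix; zero-norm rows are an error naming
#'   the gene.
#' @return Square similarity matrix.
#' @export
uncentered_similarity <- function(values) {
  norms <- sqrt(rowSums(values^2))
  zero <- norms == 0
  if (any(zero))
    stop2("zero-norm row(s): ",
          paste(utils::head(rownames(values)[zero], 5), collapse = ", "))
  tcrossprod(values / norms)
}

#' Complete-linkage clustering under the uncentered metric
#'
#' Clusters gene rows with distance `1 - s` (uncentered similarity) and
#' maximum linkage, cuts the tree, and labels each cluster by the
#' anteroposterior position of its centroid maximum: positions in the
#' anterior half of the axis give `anterior`, the section-5-like window
#' gives `ileal`, and the posterior end gives `posterior`.
#'
#' @param values Z-scored genes x segments matrix.
#' @param k Number of clusters to cut (default 3); alternatively supply
#'   `h`, a cut height.
#' @param h Optional cut height (overrides `k`).
#' @return List with `labels` (named per-gene cluster label),
#'   `cluster_archetype` (per-cluster label), `tree` (`hclust`), and
#'   `leaf_order`.
#' @export
uncentered_complete_cluster <- function(values, k = 3L, h = NULL) {
  s <- uncentered_similarity(values)
  d <- 1 - s
  diag(d) <- 0
  tree <- stats::hclust(stats::as.dist(d), method = "complete")
  cl <- if (is.null(h)) stats::cutree(tree, k = k) else
    stats::cutree(tree, h = h)
  x <- seq(0, 1, length.out = ncol(values))
  arch <- vapply(sort(unique(cl)), function(g) {
    cen <- colMeans(values[cl == g, , drop = FALSE])
    xm <- x[which.max(cen)]
    if (xm < 0.55) "anterior" else if (xm < 0.8) "ileal" else "posterior"
  }, character(1))
  names(arch) <- sort(unique(cl))
  labels <- arch[as.character(cl)]
  names(labels) <- rownames(values)
  list(labels = labels, cluster_archetype = arch, tree = tree,
       leaf_order = tree$order)
}

#' Interpolate 4 mouse segments onto the 7-slot axis
#'
#' The four segments (duodenum, jejunum, ileum, colon) occupy positions
#' 1, 3, 5, 7 of a 7-slot anteroposterior axis; the three intermediate
#' values are the pairwise midpoints. The map is linear.
#'
#' @param values Numeric vector of exactly 4 finite values in
#'   anterior-to-posterior order.
#' @return Numeric vector of 7 values.
#' @export
interpolate_4_to_7 <- function(values) {
  if (length(values) != 4L || any(!is.finite(values)))
    stop2("need exactly 4 finite values (duodenum, jejunum, ileum, colon)")
  d <- values[1]; j <- values[2]; i <- values[3]; cc <- values[4]
  c(d, (d + j) / 2, j, (j + i) / 2, i, (i + cc) / 2, cc)
}

#' Match regional expression patterns between zebrafish and mouse
#'
#' For each 1-to-1 ortholog pair whose zebrafish member falls in one of the
#' selected zebrafish clusters, computes the Pearson correlation between the
#' zebrafish 7-section z-score vector and the mouse 4-segment vector
#' interpolated to 7 slots, and retains pairs with `r >= threshold`
#' (exclusion of pairs "below" the cutoff keeps the boundary value).
#' Ortholog pairs absent from either matrix are skipped and logged.
#'
#' @param zf_values Z-scored zebrafish genes x 7 sections matrix.
#' @param ms_values Z-scored mouse genes x 4 segments matrix.
#' @param orthologs An [ortholog_table()] containing `zebrafish` and `mouse`
#'   columns (pairwise table).
#' @param cluster_labels Named per-gene archetype labels for the zebrafish
#'   genes (from [uncentered_complete_cluster()]); pass `NULL` to match all
#'   genes with label `all`.
#' @param threshold Correlation cutoff (default 0.6, closed at the cutoff).
#' @param clusters_use Cluster labels eligible for matching.
#' @return Data frame `zebrafish_gene`, `mouse_gene`, `correlation`,
#'   `source_cluster` for retained pairs; attribute `skipped` lists pairs
#'   missing from either matrix, attribute `tested` the number of scored
#'   pairs.
#' @export
match_regional <- function(zf_values, ms_values, orthologs,
                           cluster_labels = NULL, threshold = 0.6,
                           clusters_use = c("anterior", "ileal", "posterior")) {
  stopifnot(inherits(orthologs, "iec_orthologs"))
  q <- orthologs$quartets
  if (!all(c("zebrafish", "mouse") %in% colnames(q)))
    stop2("ortholog table must contain zebrafish and mouse columns")
  rows <- list()
  skipped <- character(0)
  tested <- 0L
  for (i in seq_len(nrow(q))) {
    zg <- q$zebrafish[i]; mg <- q$mouse[i]
    if (is.na(zg) || is.na(mg)) next
    if (!zg %in% rownames(zf_values) || !mg %in% rownames(ms_values)) {
      skipped <- c(skipped, zg)
      next
    }
    lab <- if (is.null(cluster_labels)) "all" else cluster_labels[[zg]]
    if (is.null(lab) || is.na(lab)) {
      skipped <- c(skipped, zg)
      next
    }
    if (!is.null(cluster_labels) && !lab %in% clusters_use) next
    tested <- tested + 1L
    r <- stats::cor(zf_values[zg, ], interpolate_4_to_7(ms_values[mg, ]))
    if (!is.na(r) && r >= threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(zebrafish_gene = zg, mouse_gene = mg, correlation = r,
                   source_cluster = lab, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(zebrafish_gene = character(0), mouse_gene = character(0),
               correlation = numeric(0), source_cluster = character(0),
               stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "tested") <- tested
  out
}

#' Median-centre matched genes and order by a mouse segment
#'
#' Builds the display matrix for matched ortholog pairs: the zebrafish
#' 7-section and interpolated mouse 7-slot z-scores are median-centred per
#' gene (within each species block) and rows are ordered by decreasing value
#' of the chosen mouse segment.
#'
#' @param matches Data frame from [match_regional()] (non-empty).
#' @param zf_values,ms_values The z-scored matrices used for matching.
#' @param sort_segment Mouse segment name (column of `ms_values`).
#' @return Numeric matrix with 14 columns (`zf_` sections then `ms_` slots),
#'   one row per matched pair, ordered by the chosen segment.
#' @export
median_center_and_sort <- function(matches, zf_values, ms_values,
                                   sort_segment = "duodenum") {
  if (!nrow(matches)) stop2("no matches to display")
  if (!sort_segment %in% colnames(ms_values))
    stop2("unknown segment label '", sort_segment, "'")
  zf <- zf_values[matches$zebrafish_gene, , drop = FALSE]
  ms4 <- ms_values[matches$mouse_gene, , drop = FALSE]
  ms7 <- t(apply(ms4, 1, interpolate_4_to_7))
  zf_c <- zf - apply(zf, 1, stats::median)
  ms7_c <- ms7 - apply(ms7, 1, stats::median)
  key_col <- which(colnames(ms_values) == sort_segment)
  slot <- c(1L, 3L, 5L, 7L)[key_col]
  ord <- order(ms7_c[, slot], decreasing = TRUE)
  out <- cbind(zf_c, ms7_c)
  zf_names <- colnames(zf_values) %||% paste0("s", seq_len(ncol(zf_values)))
  colnames(out) <- c(paste0("zf_", zf_names), paste0("ms_slot", 1:7))
  rownames(out) <- paste(matches$zebrafish_gene, matches$mouse_gene,
                         sep = "|")
  out[ord, , drop = FALSE]
}
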