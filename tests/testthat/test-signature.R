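test_that("detectable filter keeps genes with signal in any sample", {
  m <- rbind(a = c(0, 0, 0), b = c(0.05, 0, 0), c = c(0, 2, 0))
  colnames(m) <- paste0("s", 1:3)
  expect_identical(detectable_filter(m, 0), m)
  expect_identical(rownames(detectable_filter(m, 0.1)), "c")
  # row-max oracle on random values
  set.seed(3)
  r <- matrix(stats::rexp(600), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  kept <- rownames(detectable_filter(r, 1))
  expect_identical(kept, rownames(r)[apply(r, 1, max) >= 1])
  expect_warning(detectable_filter(m, 10), "no genes")
  expect_error(detectable_filter(m, -1), "non-negative")
})

test_that("Pearson distance matrix matches its closed forms and the direct formula", {
  set.seed(4)
  m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  m2 <- cbind(m, s5 = m[, 1])                 # duplicated sample
  m2 <- cbind(m2, s6 = -m2[, 1])              # anti-correlated sample
  d <- pearson_distance_matrix(m2)
  expect_equal(d["s1", "s5"], 0)
  expect_equal(d["s1", "s6"], 2)
  expect_equal(diag(d), rep(0, 6), ignore_attr = TRUE)
  expect_equal(d, t(d), ignore_attr = TRUE)
  # naive per-pair oracle
  for (i in 1:4) for (j in 1:4) {
    r <- sum((m[, i] - mean(m[, i])) * (m[, j] - mean(m[, j]))) /
      sqrt(sum((m[, i] - mean(m[, i]))^2) * sum((m[, j] - mean(m[, j]))^2))
    expect_equal(d[i, j], 1 - r)
  }
  # constant sample is flagged
  mc <- cbind(m, s5 = rep(1, 5))
  expect_warning(dc <- pearson_distance_matrix(mc), "constant")
  expect_identical(attr(dc, "constant_samples"), "s5")
})

test_that("sample distances are invariant to positive rescaling of a sample", {
  set.seed(5)
  m <- matrix(rexp(40), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  d1 <- pearson_distance_matrix(m)
  m[, 2] <- m[, 2] * 37.5
  expect_equal(pearson_distance_matrix(m), d1, tolerance = 1e-12)
})

test_that("complete linkage clustering matches forced topologies and a naive oracle", {
  # two samples: single merge at their distance
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- complete_linkage_cluster(d2)
  expect_equal(h2$height, 0.3)
  # forced topology: {A,B} at 1, then C at 10
  d3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h3 <- complete_linkage_cluster(d3)
  expect_equal(h3$height, c(1, 10))
  expect_setequal(h3$merge[1, ], c(-1, -2))   # first merge joins A and B
  # naive O(n^3) oracle on random points
  set.seed(6)
  x <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(x))
  h <- complete_linkage_cluster(d)
  expect_equal(sort(h$height), naive_complete_linkage_heights(d),
               tolerance = 1e-12)
  d[1, 2] <- d[2, 1] <- NaN
  expect_error(complete_linkage_cluster(d), "non-finite")
})

test_that("PC1 scores agree with an independent eigen-decomposition", {
  set.seed(7)
  vals <- matrix(rexp(60, 0.2), 10, 6,
                 dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  is_iec <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  pc <- pca_pc1(vals, is_iec)
  # oracle: eigen-decomposition of the covariance of centred samples
  x <- t(log10(vals + 1))
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc))
  scores <- drop(xc %*% ev$vectors[, 1])
  if (mean(scores[is_iec]) < mean(scores[!is_iec])) scores <- -scores
  expect_equal(unname(pc$scores), unname(scores), tolerance = 1e-8)
  expect_equal(pc$explained_variance, ev$values[1] / sum(ev$values),
               tolerance = 1e-8)
  # degenerate input: all samples identical
  same <- vals[, c(1, 1, 1, 1)]
  colnames(same) <- paste0("s", 1:4)
  expect_error(pca_pc1(same, c(TRUE, TRUE, FALSE, FALSE)), "zero variance")
})

test_that("sign orientation makes the signature invariant to eigenvector sign", {
  cfg <- small_config(seed = 21)
  e <- simulate_expression(cfg)
  vals <- detectable_filter(e$values, 1)
  pc <- pca_pc1(vals, e$meta$is_iec)
  expect_gte(mean(pc$scores[e$meta$is_iec]), mean(pc$scores[!e$meta$is_iec]))
  sig_a <- call_signature(vals, pc$scores)
  sig_b <- call_signature(vals, pc$scores)   # deterministic path
  expect_identical(sig_a$signature_genes, sig_b$signature_genes)
  # a gene vector equal to the scores correlates perfectly
  vals2 <- rbind(vals, probe = 2^(pc$scores - min(pc$scores) + 1))
  r <- call_signature(vals2, pc$scores, transform = "raw")$gene_correlation
  expect_gt(r[["probe"]], 0.99)
})

test_that("planted signature genes are recovered with few false positives", {
  cfg <- sim_config(seed = 13, n_genes = 800, n_signature = 40,
                    signature_log2_effect = 4, noise_sd = 0.25,
                    n_cooccur = 0, n_single_motif = 0)
  e <- simulate_expression(cfg)
  vals <- detectable_filter(e$values, 1)
  pc <- pca_pc1(vals, e$meta$is_iec)
  sig <- call_signature(vals, pc$scores, threshold = 0.7)
  planted <- e$truth$signature_genes
  recovered <- intersect(sig$signature_genes, planted)
  fp <- setdiff(sig$signature_genes, planted)
  expect_gte(length(recovered) / length(planted), 0.95)
  expect_lte(length(fp) / (nrow(vals) - length(planted)), 0.02)
  # raising the threshold never adds genes
  sig_hi <- call_signature(vals, pc$scores, threshold = 0.8)
  expect_true(all(sig_hi$signature_genes %in% sig$signature_genes))
  # threshold 1.0 keeps only exact correlation 1 (none under noise)
  sig_1 <- call_signature(vals, pc$scores, threshold = 1)
  expect_length(sig_1$signature_genes, 0)
})

test_that("ribosomal identifiers are excluded from the signature and recorded", {
  cfg <- small_config(seed = 22)
  e <- simulate_expression(cfg)
  vals <- e$values
  # plant a strongly IEC-elevated ribosomal-named gene
  riboname <- grep("^RPL", rownames(vals), value = TRUE)[1]
  vals[riboname, e$meta$is_iec] <- vals[riboname, e$meta$is_iec] * 2^6
  pc <- pca_pc1(vals, e$meta$is_iec)
  sig <- call_signature(vals, pc$scores)
  expect_true(riboname %in% sig$excluded_ribosomal)
  expect_false(riboname %in% sig$signature_genes)
  expect_equal(sig$n_before_ribosomal_exclusion,
               length(sig$signature_genes) + length(sig$excluded_ribosomal))
  # constant gene vectors are flagged, not scored
  vals2 <- rbind(vals, flatgene = rep(7, ncol(vals)))
  sig2 <- call_signature(vals2, pc$scores)
  expect_true("flatgene" %in% sig2$flagged_constant)
})
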