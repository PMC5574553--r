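test_that("simulated genome composition follows the configured AT fraction", {
  cfg <- small_config(seed = 9, n_genes = 60, n_signature = 5,
                      n_conserved_regional = 6, n_shuffled_regional = 6,
                      n_flat_regional = 3, n_cooccur = 0, n_single_motif = 0,
                      n_ribosomal = 0,
                      at_fraction = c(zebrafish = 1, stickleback = 0.5,
                                      mouse = 0.35, human = 0.35))
  gen <- simulate_genomes(cfg, pwms = iec_pwms())
  # degenerate composition: AT fraction 1 leaves only A and T
  zf <- gen$genomes$zebrafish$chr1
  expect_true(all(strsplit(substr(zf, 1, 1e4), "")[[1]] %in% c("A", "T")))
  # binomial 3-sigma bound at AT fraction 0.5
  gac <- gen$genomes$stickleback$chr1
  n <- nchar(gac)
  obs <- at_fraction(list(gac))
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / n))
})

test_that("planted motif instances are retrievable verbatim at recorded coordinates", {
  cfg <- small_config()
  gen <- simulate_genomes(cfg)
  mt <- gen$motif_truth
  expect_gt(nrow(mt), 0)
  for (i in seq_len(nrow(mt))) {
    g <- gen$genomes[[mt$species[i]]][[mt$chrom[i]]]
    expect_identical(substr(g, mt$start[i] + 1, mt$end[i]), mt$seq[i])
  }
  # a plus-strand plant at offset 60 occupies [TSS-60, TSS-60+L)
  plan <- data.frame(gene = "g00001", motif = "HNF4A", offset = 60L)
  cfg2 <- small_config(planted_motifs = plan)
  gen2 <- simulate_genomes(cfg2)
  gt <- gen2$gene_tables$zebrafish
  stopifnot(gt$strand[1] == "+")
  tss <- gt$tss[1]
  expect_identical(substr(gen2$genomes$zebrafish$chr1, tss - 60 + 1, tss - 47),
                   "GGGGCAAAGGTCA")
})

test_that("planting outside sequence bounds is a coordinate error", {
  plan <- data.frame(gene = "g00001", motif = "HNF4A", offset = 10000L)
  cfg <- small_config(planted_motifs = plan)
  expect_error(simulate_genomes(cfg), "outside sequence bounds")
})

test_that("expression generator obeys its closed forms", {
  # null model: no effect, no noise => identical across samples
  cfg0 <- small_config(signature_log2_effect = 0, noise_sd = 0)
  e0 <- simulate_expression(cfg0)
  expect_true(all(apply(e0$values, 1, function(r) diff(range(r)) == 0)))
  # noiseless planted gene: IEC/non-IEC FPKM ratio is exactly 2^effect
  cfg1 <- small_config(signature_log2_effect = 3, noise_sd = 0)
  e1 <- simulate_expression(cfg1)
  g <- e1$truth$signature_genes[1]
  ratio <- e1$values[g, e1$meta$is_iec][1] / e1$values[g, !e1$meta$is_iec][1]
  expect_equal(unname(ratio), 2^3)
  # law of large numbers: planted log2 separation near the configured effect
  cfg2 <- sim_config(seed = 11, n_genes = 500, n_signature = 100,
                     signature_log2_effect = 4, noise_sd = 0.25,
                     n_cooccur = 0, n_single_motif = 0)
  e2 <- simulate_expression(cfg2)
  lg <- log2(e2$values[e2$truth$signature_genes, ])
  sep <- rowMeans(lg[, e2$meta$is_iec]) - rowMeans(lg[, !e2$meta$is_iec])
  se <- 0.25 * sqrt(1 / sum(e2$meta$is_iec) + 1 / sum(!e2$meta$is_iec)) /
    sqrt(length(sep))
  expect_lt(abs(mean(sep) - 4), 3 * se * sqrt(length(sep)))
  expect_error(simulate_expression(small_config(noise_sd = -1)),
               "noise_sd")
})

test_that("segment archetype templates have the advertised shapes", {
  cfg <- small_config(segment_noise_sd = 0)
  seg <- simulate_segments(cfg)
  tr <- seg$truth
  # ileal zebrafish profile peaks at section 5 of 7
  il <- tr$zebrafish_gene[tr$zf_archetype == "ileal"][1]
  expect_equal(unname(which.max(seg$zebrafish$values[il, ])), 5L)
  # anterior mouse profile is monotone duodenum >= jejunum >= ileum >= colon
  an <- tr$mouse_gene[tr$ms_archetype == "anterior"][1]
  v <- seg$mouse$values[an, ]
  expect_true(all(diff(v) <= 0))
  # flat archetype with zero noise is constant and flagged at z-scoring
  fl <- tr$zebrafish_gene[tr$zf_archetype == "flat"]
  z <- zscore_rows(seg$zebrafish$values)
  expect_true(all(fl %in% z$dropped))
  expect_error(segment_template("jejunal", 0.5), "unknown archetype")
})

test_that("planted peak classes satisfy their construction rules", {
  cfg <- small_config()
  pk <- simulate_peaks(cfg)
  mat <- build_overlap_matrix(pk$cnes, pk$peak_sets)
  iec <- pk$datasets$dataset_id[pk$datasets$role == "IEC"]
  non <- pk$datasets$dataset_id[pk$datasets$role == "non_IEC"]
  cls <- pk$truth$class
  for (i in seq_len(nrow(mat))) {
    n_iec <- sum(mat[i, iec], na.rm = TRUE)
    n_non <- sum(mat[i, non], na.rm = TRUE)
    if (cls[i] == "IEC_specific") {
      expect_equal(n_iec, length(iec))
      expect_lte(n_non, 8L)
    } else if (cls[i] == "constitutive") {
      expect_equal(n_iec, length(iec))
      expect_gte(n_non, 14L)
    }
  }
  # background occupancy matches the binomial expectation (3-sigma)
  cfgb <- small_config(seed = 5, n_iec_specific = 0, n_constitutive = 0,
                       n_background = 150)
  pkb <- simulate_peaks(cfgb)
  matb <- build_overlap_matrix(pkb$cnes, pkb$peak_sets)
  nonb <- pkb$datasets$dataset_id[pkb$datasets$role == "non_IEC"]
  counts <- rowSums(matb[, nonb], na.rm = TRUE)
  mu <- 17 * 0.1
  sdv <- sqrt(17 * 0.1 * 0.9)
  expect_lt(abs(mean(counts) - mu), 3 * sdv / sqrt(length(counts)))
  # fewer than 17 non-IEC datasets conflicts with the default thresholds
  expect_error(simulate_peaks(small_config(n_noniec_datasets = 12)),
               "17 non-IEC")
})

test_that("identical configurations write byte-identical cohorts", {
  cfg <- small_config(seed = 77)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  md1 <- unname(tools::md5sum(file.path(d1, f1)))
  md2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(md1, md2)
})

test_that("written cohort artifacts round-trip through standard readers", {
  cfg <- small_config(seed = 78)
  co <- simulate_cohort(cfg)
  d <- file.path(tempdir(), "cohort_rt")
  unlink(d, recursive = TRUE)
  write_cohort(co, d)
  g <- read_genome_fasta(file.path(d, "zebrafish_genome.fa"))
  expect_identical(g$chr1, co$genomes$zebrafish$chr1)
  ot <- load_ortholog_table(file.path(d, "orthologs.tsv"))
  expect_identical(ot$quartets, co$ortholog_table$quartets)
  ds <- names(co$peak_sets)[1]
  bed <- read_bed(file.path(d, "peaks", paste0(ds, ".bed")))
  expect_equal(bed[, c("chrom", "start", "end")],
               co$peak_sets[[ds]]$intervals, ignore_attr = TRUE)
  tr <- read_bedgraph(file.path(d, "tracks", paste0(ds, ".bedGraph")))
  expect_equal(tr, co$tracks[[ds]], ignore_attr = TRUE)
})
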