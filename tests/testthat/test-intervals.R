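iv <- function(chrom, start, end)
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)

test_that("the one-shared-base-pair overlap rule handles its boundaries", {
  expect_true(interval_overlaps(iv("chr1", 0, 100), iv("chr1", 99, 200)))
  expect_false(interval_overlaps(iv("chr1", 0, 100), iv("chr1", 100, 200)))
  expect_false(interval_overlaps(iv("chr1", 0, 100), iv("chr2", 50, 60)))
  # symmetric and reflexive
  a <- iv("chr1", 10, 50); b <- iv("chr1", 40, 60)
  expect_identical(interval_overlaps(a, b), interval_overlaps(b, a))
  expect_true(interval_overlaps(a, a))
})

test_that("overlap calls agree with a per-base set-intersection oracle", {
  set.seed(12)
  n <- 1000
  a <- iv(sample(c("chr1", "chr2"), n, TRUE), s <- sample(0:500, n, TRUE),
          s + sample(1:80, n, TRUE))
  b <- iv(sample(c("chr1", "chr2"), n, TRUE), s2 <- sample(0:500, n, TRUE),
          s2 + sample(1:80, n, TRUE))
  got <- interval_overlaps(a, b)
  oracle <- vapply(seq_len(n), function(i)
    overlap_per_base_oracle(a[i, ], b[i, ]), logical(1))
  expect_identical(got, oracle)
})

test_that("TSS windows are strand-aware and clip at the chromosome start", {
  genes <- data.frame(gene_id = c("gp", "gm", "gc", "gd"), chrom = "chr1",
                      strand = c("+", "-", "+", "+"),
                      tss = c(5000L, 5000L, 2000L, 15000L),
                      tts = c(9000L, 1000L, 7000L, 19000L),
                      stringsAsFactors = FALSE)
  up <- tss_window(genes, "upstream1000")
  expect_equal(up$start[1], 4000); expect_equal(up$end[1], 5000)
  expect_equal(up$start[2], 5000); expect_equal(up$end[2], 6000)
  c1000 <- tss_window(genes, "centered1000")
  expect_equal(c(c1000$start[1], c1000$end[1]), c(4500, 5500))
  c100 <- tss_window(genes, "centered100")
  expect_equal(c(c100$start[1], c100$end[1]), c(4950, 5050))
  rd <- tss_window(genes, "regulatory_domain")
  expect_equal(c(rd$start[3], rd$end[3]), c(0, 17000))
  expect_true(rd$clipped[3])
  expect_equal(c(rd$start[4], rd$end[4]), c(5000, 29000))
  expect_false(rd$clipped[4])
})

test_that("overlap matrices match brute force and respect missing mappings", {
  regions <- data.frame(id = c("r1", "r2", "r3"),
                        species = "zebrafish", chrom = "chr1",
                        start = c(100L, 300L, 500L), end = c(200L, 400L, 600L),
                        stringsAsFactors = FALSE)
  ps1 <- peak_set("d1", "zebrafish", "IEC", iv("chr1", 150, 180))
  ps2 <- peak_set("d2", "zebrafish", "non_IEC",
                  iv(character(0), integer(0), integer(0)))
  m <- build_overlap_matrix(regions, list(ps1, ps2))
  expect_identical(unname(m[, "d1"]), c(TRUE, FALSE, FALSE))
  expect_identical(unname(m[, "d2"]), c(FALSE, FALSE, FALSE))
  expect_equal(unname(attr(m, "totals")), c(1, 0))
  # a region with no mapping in the dataset species is missing, not FALSE
  regions_ms <- regions[regions$id != "r2", ]
  regions_ms$species <- "mouse"
  both <- rbind(regions, regions_ms)
  ps3 <- peak_set("d3", "mouse", "non_IEC", iv("chr1", 510, 520))
  m2 <- build_overlap_matrix(both, list(ps1, ps3))
  expect_true(is.na(m2["r2", "d3"]))
  expect_true(m2["r3", "d3"])
  # brute-force pairwise oracle on a simulated cohort
  cfg <- small_config(seed = 33)
  pk <- simulate_peaks(cfg)
  mat <- build_overlap_matrix(pk$cnes, pk$peak_sets)
  for (d in sample(names(pk$peak_sets), 5)) {
    ps <- pk$peak_sets[[d]]
    reg <- pk$cnes[pk$cnes$species == ps$species, ]
    for (i in sample(nrow(reg), 10)) {
      brute <- any(interval_overlaps(reg[i, c("chrom", "start", "end")],
                                     ps$intervals))
      expect_identical(unname(mat[reg$id[i], d]), brute)
    }
  }
})

test_that("region classification follows the closed-form thresholds", {
  mk <- function(n_iec_true, n_non_true, n_iec = 5, n_non = 17) {
    m <- matrix(c(rep(TRUE, n_iec_true), rep(FALSE, n_iec - n_iec_true),
                  rep(TRUE, n_non_true), rep(FALSE, n_non - n_non_true)),
                1, dimnames = list("r", c(paste0("i", 1:n_iec),
                                          paste0("n", 1:n_non))))
    classify_regions(m, paste0("i", 1:n_iec), paste0("n", 1:n_non))$label
  }
  # boundary instances of the published thresholds
  expect_equal(mk(5, 8), "IEC_specific")    # absent in exactly 9/17
  expect_equal(mk(5, 9), "other")           # absent in only 8/17
  expect_equal(mk(5, 14), "constitutive")   # present in exactly 14/17
  expect_equal(mk(5, 13), "other")          # present in only 13/17
  expect_equal(mk(4, 0), "other")           # not always accessible in IECs
  expect_equal(mk(4, 17), "other")
})

test_that("classification is monotone in added absent datasets and handles NAs", {
  m <- matrix(c(rep(TRUE, 5), rep(FALSE, 9), rep(TRUE, 8)), 1,
              dimnames = list("r", c(paste0("i", 1:5), paste0("n", 1:17))))
  base <- classify_regions(m, paste0("i", 1:5), paste0("n", 1:17))
  expect_equal(base$label, "IEC_specific")
  # adding a non-IEC dataset in which the region is absent keeps the label
  m2 <- cbind(m, n18 = FALSE)
  more <- classify_regions(m2, paste0("i", 1:5), paste0("n", 1:18))
  expect_equal(more$label, "IEC_specific")
  # missing cells shrink the denominator (fraction generalisation)
  m3 <- m
  m3[1, paste0("n", 10:17)] <- NA    # 9 available non-IEC, all FALSE
  part <- classify_regions(m3, paste0("i", 1:5), paste0("n", 1:17))
  expect_equal(part$n_noniec_available, 9L)
  expect_equal(part$label, "IEC_specific")
  # all cells missing: label undefined, reported
  m4 <- m
  m4[1, ] <- NA
  allna <- classify_regions(m4, paste0("i", 1:5), paste0("n", 1:17))
  expect_true(is.na(allna$label))
})

test_that("planted accessibility classes are recovered without error", {
  cfg <- small_config(seed = 34)
  pk <- simulate_peaks(cfg)
  mat <- build_overlap_matrix(pk$cnes, pk$peak_sets)
  cls <- classify_regions(
    mat, pk$datasets$dataset_id[pk$datasets$role == "IEC"],
    pk$datasets$dataset_id[pk$datasets$role == "non_IEC"])
  truthmap <- c(IEC_specific = "IEC_specific", constitutive = "constitutive",
                background = "other")
  expect_identical(cls$label[match(pk$truth$id, cls$id)],
                   unname(truthmap[pk$truth$class]))
})
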