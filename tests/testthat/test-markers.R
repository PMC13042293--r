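# Marker loading, filtering, standardization and the genomic relationship.

test_that("delimited -1/0/1 files load verbatim", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,m1,m2", "g1,-1,1", "g2,1,1"), f)
  m <- load_markers(f, format = "delimited", coding = "minus1_0_1")
  expect_equal(unname(m$scores), matrix(c(-1L, 1L, 1L, 1L), 2))
  expect_equal(m$genotype_ids, c("g1", "g2"))
})

test_that("0/1/2 input is oriented so +1 is the major homozygote", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tm1", "g1\t0", "g2\t0", "g3\t2"), f)
  m <- load_markers(f, format = "delimited", coding = "0_1_2")
  # allele coded 2 has frequency 1/3: the 0-homozygote is the major class
  expect_equal(unname(m$scores[, 1]), c(1L, 1L, -1L))
  # auto-detection picks 0/1/2 when no negative scores appear
  m2 <- load_markers(f, format = "delimited", coding = "auto")
  expect_identical(m2$scores, m$scores)
})

test_that("frequency ties keep the file orientation", {
  dos <- matrix(c(0L, 2L), 2, 1)
  expect_equal(unname(metgs:::orient_dosage(dos))[, 1], c(-1L, 1L))
})

test_that("VCF genotypes map to three score classes", {
  skip_if_not_installed("vcfR")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tsnp2\tA\tG,C\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"
  ), f)
  expect_warning(m <- load_markers(f, format = "vcf"), "multi-allelic")
  expect_equal(ncol(m$scores), 1L)
  expect_setequal(as.vector(m$scores), c(-1L, 0L, 1L))
})

test_that("missing scores error by default and mean-impute on request", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,m1,m2", "g1,-1,NA", "g2,1,1", "g3,1,1"), f)
  expect_error(load_markers(f, coding = "minus1_0_1"), "missing")
  m <- load_markers(f, coding = "minus1_0_1", missing_policy = "mean_impute")
  expect_equal(unname(m$scores[1, 2]), 1L)  # column mean 1 rounds to 1
})

test_that("MAF filtering matches hand-counted allele frequencies", {
  m <- marker_matrix(cbind(c(1L, 1L, 1L, 1L), c(1L, 1L, 1L, -1L)))
  expect_equal(marker_maf(m), c(0, 0.25), ignore_attr = TRUE)
  kept <- filter_maf(m, 0.05)
  expect_equal(kept$marker_ids, "m2")       # monomorphic column removed
  expect_identical(filter_maf(m, 0), m)     # threshold 0 is a no-op
  twice <- filter_maf(filter_maf(m, 0.05), 0.05)
  expect_identical(twice, kept)             # idempotent
  expect_error(filter_maf(m, 0.6), "0.5")
})

test_that("standardization yields unit-variance zero-mean columns", {
  m <- marker_matrix(cbind(c(-1L, 1L), c(1L, 1L)))
  expect_warning(w <- standardize_markers(m), "monomorphic")
  expect_equal(w$kept_marker_ids, "m1")
  expect_equal(w$w[, 1], c(-1, 1) / sqrt(2), ignore_attr = TRUE)

  pm <- simulate_marker_matrix(10, 50, seed = 7)
  pm <- filter_maf(pm, 0.05)
  ws <- standardize_markers(pm)
  expect_lt(max(abs(colMeans(ws$w))), 1e-10)
  expect_equal(apply(ws$w, 2, sd), rep(1, ncol(ws$w)), ignore_attr = TRUE)
})

test_that("GRM worked example and identities hold", {
  m <- marker_matrix(cbind(c(-1L, 1L), c(1L, 1L)))
  suppressWarnings(g <- compute_grm(standardize_markers(m)))
  expect_equal(unname(g$K), matrix(c(0.5, -0.5, -0.5, 0.5), 2))

  for (seed in 1:3) {
    pm <- filter_maf(simulate_marker_matrix(25, 400, seed = seed), 0.05)
    K <- compute_grm(standardize_markers(pm))$K
    expect_lt(abs(sum(diag(K)) - (nrow(K) - 1)), 1e-8)
    expect_lt(max(abs(rowSums(K))), 1e-8)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})

test_that("GRM round-trips through the TSV writer", {
  g <- panel_grm(10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_grm(g, f)
  g2 <- read_grm(f)
  expect_equal(g2$genotype_ids, g$genotype_ids)
  expect_equal(g2$K, g$K, tolerance = 1e-10)
})

test_that("simulated panels are deterministic, valid and structured", {
  a <- simulate_marker_matrix(4, 10, seed = 1)
  b <- simulate_marker_matrix(4, 10, seed = 1)
  expect_identical(a$scores, b$scores)
  expect_true(all(a$scores %in% c(-1L, 0L, 1L)))
  expect_equal(dim(a$scores), c(4L, 10L))

  m <- simulate_marker_matrix(200, 2000, n_subpops = 2, fst = 0.3, seed = 5)
  K <- compute_grm(standardize_markers(filter_maf(m, 0.01)))$K
  sp <- attr(m, "subpop")
  within <- outer(sp, sp, `==`) & !diag(TRUE, length(sp))
  between <- outer(sp, sp, `!=`)
  expect_gt(mean(K[within]), mean(K[between]))
})

test_that("genotype relabeling permutes the GRM rows consistently", {
  m <- filter_maf(simulate_marker_matrix(12, 200, seed = 11), 0.05)
  K1 <- compute_grm(standardize_markers(m))$K
  perm <- metgs:::with_seed(3, sample(12))
  m2 <- marker_matrix(m$scores[perm, ], m$genotype_ids[perm], m$marker_ids)
  K2 <- compute_grm(standardize_markers(m2))$K
  expect_equal(unname(K2), unname(K1[perm, perm]), tolerance = 1e-10)
})
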