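make_ped_map_fixture <- function(dir) {
  # 3 samples, 2 SNPs; alt (minor) alleles: snp1 = G, snp2 = T
  writeLines(c("f1 S1 0 0 1 -9 A A C T",
               "f1 S2 0 0 2 -9 A G C C",
               "f1 S3 0 0 1 -9 G G C C"),
             file.path(dir, "toy.ped"))
  writeLines(c("1 snp1 0 100", "1 snp2 0 200"), file.path(dir, "toy.map"))
  file.path(dir, "toy.ped")
}

test_that("PED/MAP fixture loads into the expected dosage matrix", {
  d <- withr::local_tempdir()
  g <- read_genotypes(make_ped_map_fixture(d), format = "ped+map")
  expect_equal(dim(g$dosages), c(3L, 2L))
  expect_equal(unname(g$dosages[, "snp1"]), c(0, 1, 2))
  expect_equal(unname(g$dosages[, "snp2"]), c(1, 0, 0))
  expect_equal(g$snps$alt, c("G", "T"))
  expect_equal(g$snps$pos, c(100L, 200L))
})

test_that("multi-allelic VCF records are skipped and counted", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t./.",
    "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0",
    "1\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1",
    "2\t100\trs5\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1"), f)
  g <- suppressMessages(read_genotypes(f, format = "vcf"))
  expect_equal(ncol(g$dosages), 4L)
  expect_equal(attr(g, "n_multiallelic_skipped"), 1L)
  expect_equal(unname(g$dosages[, "rs1"]), c(0, 1, 2))
  expect_true(is.na(g$dosages["S3", "rs2"]))
})

test_that("simulated genotypes round-trip through the dosage layout", {
  st <- shared_study()
  g <- subset_snps(st$genotypes, st$genotypes$snps$snp_id[1:50])
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_genotypes(g, prefix, format = "dosage")
  back <- read_genotypes(paste0(prefix, ".dose.tsv"), format = "dosage",
                         map = paste0(prefix, ".snps.tsv"))
  expect_identical(back$dosages, g$dosages)
  expect_equal(back$snps, g$snps, ignore_attr = TRUE)
})

test_that("allele frequencies handle missingness and monomorphism", {
  d <- matrix(c(0, 1, 2,   0, 0, 0,   2, 2, NA,  NA, NA, NA), 3, 4,
              dimnames = list(paste0("s", 1:3), NULL))
  g <- genotype_matrix(d, data.frame(snp_id = paste0("m", 1:4), chrom = "1",
                                     pos = 1:4, ref = "A", alt = "C"))
  f <- allele_frequencies(g)
  expect_equal(unname(f[1:3]), c(0.5, 0, 1))
  expect_true(is.nan(f[[4]]))
  expect_equal(attr(f, "undefined"), "m4")
})

test_that("HWE chi-square test reproduces hand-computed values", {
  expect_equal(hwe_test(25, 50, 25), 1)
  # expected counts 25/50/25 -> chi-square = 1 + 2 + 1 = 4
  expect_equal(hwe_test(30, 40, 30), 0.0455, tolerance = 1e-3)
  expect_lt(hwe_test(50, 0, 50), 1e-20)
  expect_equal(hwe_test(100, 0, 0), 1)  # monomorphic: no testable departure
  set.seed(1)
  p <- hwe_test(rpois(50, 30) + 1, rpois(50, 60), rpois(50, 30) + 1)
  expect_true(all(p > 0 & p <= 1))
})

test_that("LD pruning removes duplicated columns and keeps independent ones", {
  set.seed(7)
  n <- 120
  base <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  d <- cbind(base[, 1], base[, 1], base[, 2:6])  # columns 1 and 2 identical
  rownames(d) <- paste0("s", 1:n)
  g <- genotype_matrix(d, data.frame(snp_id = paste0("m", 1:7), chrom = "1",
                                     pos = 1:7, ref = "A", alt = "C"))
  kept <- ld_prune(g, window_snps = 7, step_snps = 1, r2_threshold = 0.1)
  expect_true(xor("m1" %in% kept, "m2" %in% kept))
  expect_true(all(paste0("m", 3:7) %in% kept))

  # independent SNPs: nothing pruned
  g2 <- genotype_matrix(matrix(rbinom(n * 30, 2, 0.3), n, 30,
                               dimnames = list(paste0("s", 1:n), NULL)),
                        data.frame(snp_id = paste0("x", 1:30), chrom = "1",
                                   pos = 1:30, ref = "A", alt = "C"))
  expect_equal(length(ld_prune(g2, 30, 5, 0.2)), 30L)
})

test_that("pruning at standard parameters bounds within-window r2 and is idempotent", {
  # one chromosome with block LD from Markov haplotype copying; enough
  # samples that chance r2 > 0.1 between unlinked markers is negligible
  ped <- founders_only_pedigree(400)
  set.seed(11)
  freqs <- runif(5000, 0.1, 0.5)
  g <- gene_drop(ped, freqs, seed = 11, ld_rho = 0.9)
  g$snps$chrom <- "1"
  g$snps$pos <- seq_len(5000)
  g <- genotype_matrix(g$dosages, g$snps)

  kept <- ld_prune(g, window_snps = 2000, step_snps = 10, r2_threshold = 0.1)
  expect_lt(length(kept), 5000L)
  idx <- match(kept, g$snps$snp_id)
  # post-hoc oracle: sampled windows contain no retained pair with r2 > 0.1
  set.seed(12)
  for (start in sample(seq(1, 3001, by = 10), 25)) {
    w <- idx[idx >= start & idx < start + 2000]
    if (length(w) < 2) next
    r2 <- cor(g$dosages[, w])^2
    expect_lte(max(r2[upper.tri(r2)]), 0.1 + 1e-12)
  }
  gk <- subset_snps(g, kept)
  expect_equal(ld_prune(gk, 2000, 10, 0.1), kept)
})

test_that("qc_snps reports its exclusion counts", {
  st <- shared_study()
  g <- subset_snps(st$genotypes, st$genotypes$snps$snp_id[1:500])
  gq <- qc_snps(g, hwe_p = 0.05, window_snps = 50, step_snps = 5,
                r2_threshold = 0.1)
  cnt <- attr(gq, "qc_counts")
  expect_equal(unname(cnt["input"]), 500)
  expect_equal(unname(cnt["input"] - cnt["hwe_removed"] - cnt["ld_removed"]),
               unname(cnt["retained"]))
  expect_equal(ncol(gq$dosages), unname(cnt["retained"]))
})
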