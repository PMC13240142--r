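pops2 <- c(s1 = "A", s2 = "B")

test_that("read_vcf maps GT strings to dosages", {
  path <- write_test_vcf(
    c("s1", "s2"),
    c(vcf_line("chr1", 100, "A", "T", 50, "QD=10", c("0/0", "0/1")),
      vcf_line("chr1", 200, "G", "C", 60, ".", c("./.", "1|1")),
      vcf_line("chr1", 300, "G", "C", 60, ".", c("./1", "1/0"))))
  gm <- read_vcf(path, pops2)
  expect_equal(unname(gm$calls[, 1]), c(0L, 1L))
  expect_equal(unname(gm$calls[, 2]), c(NA_integer_, 2L))  # missing, phased
  expect_equal(unname(gm$calls[, 3]), c(NA_integer_, 1L))  # half-call -> NA
  expect_equal(gm$sites$pos, c(100L, 200L, 300L))
  expect_equal(gm$sites$QD, c(10, NA, NA))
  expect_equal(gm$samples, c("s1", "s2"))
})

test_that("header-only VCF yields an empty matrix with header samples", {
  path <- write_test_vcf(c("s1", "s2"), character())
  gm <- read_vcf(path, pops2)
  expect_equal(nrow(gm$sites), 0L)
  expect_equal(gm$samples, c("s1", "s2"))
})

test_that("read_vcf errors are informative", {
  path <- write_test_vcf(
    c("s1", "s2"),
    c(vcf_line("chr1", 100, "A", "T", 50, ".", c("0/0", "0/1")),
      "chr1\t200\t.\tA\tT\t50\t.\t.\tGT\t0/0"))   # missing a sample column
  expect_error(read_vcf(path, pops2), "line 6")
  ok <- write_test_vcf(c("s1", "s2", "s3"),
                       vcf_line("chr1", 1, "A", "T", 50, ".",
                                c("0/0", "0/1", "0/0")))
  expect_error(read_vcf(ok, pops2), "s3")
})

test_that("multiallelic sites are retained but flagged", {
  path <- write_test_vcf(
    c("s1", "s2"),
    vcf_line("chr1", 100, "A", "T,G", 50, ".", c("1/2", "0/2")))
  gm <- read_vcf(path, pops2)
  expect_true(gm$sites$multiallelic)
  expect_equal(unname(gm$calls[, 1]), c(1L, 0L))  # only allele 1 counted
  expect_equal(nrow(apply_site_filters(gm)$sites), 0L)
})

test_that("GT and INFO parsing agrees with VariantAnnotation", {
  skip_if_not_installed("VariantAnnotation")
  set.seed(7)
  gm <- random_gm(6, 40, missing_rate = 0.1)
  gm$sites$QD <- round(runif(40, 0, 30), 2)
  path <- file.path(withr::local_tempdir(), "va.vcf")
  write_vcf(gm, path)
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  gt <- VariantAnnotation::geno(v)$GT
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  dos[!is.na(t(gt)) & t(gt) == "0/0"] <- 0L
  dos[t(gt) == "0/1"] <- 1L
  dos[t(gt) == "1/1"] <- 2L
  dos[t(gt) == "./."] <- NA_integer_
  expect_equal(unname(dos), unname(gm$calls))
  expect_equal(unlist(VariantAnnotation::info(v)$QD), gm$sites$QD,
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("hard filters drop a site iff a present annotation violates", {
  # QD = 1.9 violates (< 2.0), 2.0 and 5.0 pass; boundary FS = 60 passes
  gm <- toy_gm(matrix(c(0, 1), 2, 5), pops2)
  gm$sites$QD <- c(1.9, 2.0, 5.0, NA, NA)
  gm$sites$FS <- c(NA, NA, NA, 60.0, 60.1)
  out <- apply_hard_filters(gm)
  expect_equal(out$sites$pos, c(2L, 3L, 4L))
  # a site with no annotations at all is retained
  bare <- toy_gm(matrix(c(0, 1), 2, 1), pops2)
  expect_equal(nrow(apply_hard_filters(bare)$sites), 1L)
})

test_that("hard filters cover every annotation's inequality", {
  gm <- toy_gm(matrix(c(0, 1), 2, 7), pops2)
  gm$sites$MQ <- c(39.9, rep(NA, 6))
  gm$sites$SOR <- c(NA, 3.01, rep(NA, 5))
  gm$sites$MQRankSum <- c(NA, NA, -12.6, rep(NA, 4))
  gm$sites$ReadPosRankSum <- c(rep(NA, 3), -8.1, -8.0, NA, NA)
  gm$sites$FS <- c(rep(NA, 5), 60.5, NA)
  out <- apply_hard_filters(gm)
  expect_equal(out$sites$pos, c(5L, 7L))  # boundary -8.0 passes
})

test_that("site filters enforce MAF, call rate, QUAL and biallelic rules", {
  pops10 <- setNames(rep(c("A", "B"), 5), paste0("s", 1:10))
  # site 1: one het in 10 diploids -> MAF 0.05, retained
  # site 2: monomorphic -> dropped; site 3: QUAL 40 fails QUAL > 40
  calls <- cbind(c(1, rep(0, 9)), rep(0, 10), c(1, 1, rep(0, 8)))
  gm <- toy_gm(calls, pops10, qual = c(100, 100, 40))
  out <- apply_site_filters(gm)
  expect_equal(out$sites$pos, 1L)

  # call rate: 1 missing of 20 samples = 0.95 retained, 2 missing dropped
  pops20 <- setNames(rep("A", 20), paste0("s", 1:20))
  calls <- cbind(c(NA, 1, 1, rep(0, 17)), c(NA, NA, 1, 1, rep(0, 16)))
  gm <- toy_gm(calls, pops20)
  expect_equal(apply_site_filters(gm)$sites$pos, 1L)

  # site with zero called genotypes is dropped, not a division error
  gm <- toy_gm(matrix(NA_integer_, 2, 1), pops2)
  expect_equal(nrow(apply_site_filters(gm)$sites), 0L)

  # missing QUAL fails
  gm <- toy_gm(matrix(c(0, 1), 2, 1), pops2, qual = NA)
  expect_equal(nrow(apply_site_filters(gm)$sites), 0L)
})

test_that("write/read round trip is the identity on calls and sites", {
  set.seed(11)
  gm <- random_gm(8, 60, n_pops = 3, missing_rate = 0.15)
  gm$sites$QD <- round(runif(60, 0, 40), 3)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rt.vcf")
  write_vcf(gm, path)
  back <- read_vcf(path, gm$pop_of)
  expect_identical(back$calls, gm$calls)
  expect_equal(back$sites$pos, gm$sites$pos)
  expect_equal(back$sites$ref, gm$sites$ref)
  expect_equal(back$sites$alt, gm$sites$alt)
  expect_equal(back$sites$QD, gm$sites$QD)
  expect_identical(back$samples, gm$samples)

  # empty matrix -> valid header-only file
  empty <- subset_sites(gm, integer())
  p2 <- file.path(dir, "empty.vcf")
  write_vcf(empty, p2)
  expect_equal(nrow(read_vcf(p2, gm$pop_of)$sites), 0L)

  # missing calls encoded as ./.
  expect_true(any(grepl("\\./\\.", readLines(path))))
})

test_that("filtering is idempotent and monotone in its thresholds", {
  set.seed(13)
  gm <- random_gm(12, 80, missing_rate = 0.2)
  gm$sites$QD <- runif(80, 0, 10)
  cfg <- filter_config(maf_min = 0.1, min_call_rate = 0.8)
  once <- apply_site_filters(apply_hard_filters(gm, cfg), cfg)
  twice <- apply_site_filters(apply_hard_filters(once, cfg), cfg)
  expect_identical(once$calls, twice$calls)
  expect_equal(once$sites, twice$sites)

  for (maf in c(0, 0.05, 0.1, 0.2)) {
    n_loose <- nrow(apply_site_filters(gm, filter_config(maf_min = maf,
                                                         min_call_rate = 0))$sites)
    n_tight <- nrow(apply_site_filters(gm, filter_config(maf_min = maf + 0.05,
                                                         min_call_rate = 0))$sites)
    expect_lte(n_tight, n_loose)
  }
  for (cr in c(0, 0.5, 0.8)) {
    n_loose <- nrow(apply_site_filters(gm, filter_config(maf_min = 0,
                                                         min_call_rate = cr))$sites)
    n_tight <- nrow(apply_site_filters(gm, filter_config(maf_min = 0,
                                                         min_call_rate = cr + 0.1))$sites)
    expect_lte(n_tight, n_loose)
  }
})
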