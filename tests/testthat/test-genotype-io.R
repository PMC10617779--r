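test_that("VCF genotypes are read as ALT-allele counts", {
  path <- tempfile(fileext = ".vcf")
  # 3 samples x 4 records, hand-transcribed expectations
  writeFixtureVcf(path, c(
    "chr1\t100\tv1\tA\tG\t.\tPASS\tINFO=0.99\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tv2\tC\tT\t.\tPASS\tINFO=0.80\tGT\t0|1\t1|1\t./.",
    "chr2\t50\tv3\tG\tA\t.\tPASS\tINFO=0.95\tGT\t1/0\t0/0\t0/1",
    "chr1\t150\tv4\tT\tC\t.\tPASS\tINFO=0.30\tGT\t1/1\t0/0\t0/1"),
    samples = c("s1", "s2", "s3"))
  g <- readGenotypeVcf(path)
  expect_s4_class(g, "GenotypeMatrix")
  # sorted by (chrom, pos): v1, v4, v2, v3
  expect_identical(variantIds(g), c("v1", "v4", "v2", "v3"))
  expected <- matrix(c(0L, 1L, 2L,   # v1
                       2L, 0L, 1L,   # v4
                       1L, 2L, NA,   # v2
                       1L, 0L, 1L),  # v3
                     nrow = 3, ncol = 4,
                     dimnames = list(c("s1", "s2", "s3"), NULL))
  expect_equal(unname(genotypeCalls(g)), unname(expected))
  expect_equal(S4Vectors::mcols(variantRanges(g))$info_score,
               c(0.99, 0.30, 0.80, 0.95))
})

test_that("single-sample het call codes as 1", {
  path <- tempfile(fileext = ".vcf")
  writeFixtureVcf(path, "chr1\t10\tv1\tA\tG\t.\t.\t.\tGT\t0/1", "s1")
  expect_equal(unname(genotypeCalls(readGenotypeVcf(path))[1, 1]), 1L)
})

test_that("low genotype posteriors are masked to missing, values never changed", {
  path <- tempfile(fileext = ".vcf")
  writeFixtureVcf(path, c(
    "chr1\t10\tv1\tA\tG\t.\t.\t.\tGT:GP\t0/1:0.6,0.3,0.1\t0/1:0.02,0.97,0.01",
    "chr1\t20\tv2\tA\tG\t.\t.\t.\tGT:GP\t1/1:0.0,0.04,0.96\t0/0:0.95,0.05,0.0"),
    samples = c("s1", "s2"), gpHeader = TRUE)
  masked <- readGenotypeVcf(path, minPosterior = 0.95)
  unmasked <- readGenotypeVcf(path, minPosterior = NULL)
  expect_true(is.na(genotypeCalls(masked)["s1", "v1"]))
  expect_equal(genotypeCalls(masked)["s2", "v1"], 1L)
  expect_equal(genotypeCalls(masked)["s1", "v2"], 2L)
  expect_equal(genotypeCalls(masked)["s2", "v2"], 0L)
  # masking only introduces NAs; every retained call equals the unmasked one
  keep <- !is.na(genotypeCalls(masked))
  expect_identical(genotypeCalls(masked)[keep], genotypeCalls(unmasked)[keep])
})

test_that("multiallelic records are rejected with the record named", {
  path <- tempfile(fileext = ".vcf")
  writeFixtureVcf(path, c(
    "chr1\t10\tv1\tA\tG\t.\t.\t.\tGT\t0/1",
    "chr1\t20\tvMulti\tA\tG,T\t.\t.\t.\tGT\t1/2"), "s1")
  expect_error(readGenotypeVcf(path), "multiallelic.*vMulti")
})

test_that("HWE exact test matches trivial and symmetric cases", {
  expect_equal(hweExactTest(50, 0, 0), 1)
  expect_equal(hweExactTest(0, 0, 50), 1)
  expect_equal(hweExactTest(3, 5, 2), oracleHwe(3, 5, 2))
  expect_equal(hweExactTest(0, 10, 0), oracleHwe(0, 10, 0))
  # symmetric in which allele is called ALT
  expect_equal(hweExactTest(3, 5, 2), hweExactTest(2, 5, 3))
  expect_error(hweExactTest(-1, 2, 3), "non-negative")
  expect_error(hweExactTest(0, 0, 0), "at least one")
})

test_that("HWE exact test equals enumeration oracle on a small grid", {
  for (n in c(5L, 12L)) {
    for (n0 in 0:n) for (n1 in 0:(n - n0)) {
      n2 <- n - n0 - n1
      expect_equal(hweExactTest(n0, n1, n2), oracleHwe(n0, n1, n2),
                   tolerance = 1e-12,
                   info = sprintf("(%d,%d,%d)", n0, n1, n2))
    }
  }
})

test_that("QC filters remove engineered violations in fixed order", {
  set.seed(4)
  n <- 60L  # 1 ALT allele in 120 -> MAF 0.0083 < 0.01
  good <- function() sample(0:2, n, replace = TRUE, prob = c(.45, .4, .15))
  calls <- cbind(
    v_ok1 = good(), v_ok2 = good(),
    v_info = good(),                       # info 0.2 -> info filter
    v_miss = c(rep(NA, 4), good()[-(1:4)]),# 10% missing -> missing filter
    v_mono = rep(0L, n),                   # monomorphic
    v_rare = c(1L, rep(0L, n - 1)),        # MAF 1/80 < 0.01
    v_hwe = rep(c(0L, 2L), n / 2),         # no hets -> HWE blowup
    v_mhc = good())                        # inside MHC interval
  ids <- colnames(calls)
  g <- makeGenotypeMatrix(calls,
                          chrom = c(rep("chr1", 7), "chr6"),
                          pos = c(100L * 1:7, 30000000L), ids = ids)
  cfg <- qcConfig()
  # engineer the info score after construction keeps ids aligned
  gInfo <- variantRanges(g)
  S4Vectors::mcols(gInfo)$info_score <-
    ifelse(S4Vectors::mcols(gInfo)$variant_id == "v_info", 0.2, 0.99)
  g <- GenotypeMatrix(genotypeCalls(g), gInfo)
  res <- applyQC(g, cfg)
  rep <- res$report
  expect_equal(rep$removed[rep$filter == "info_score"], 1L)
  expect_equal(rep$removed[rep$filter == "missing_rate"], 1L)
  expect_equal(rep$removed[rep$filter == "monomorphic"], 1L)
  expect_equal(rep$removed[rep$filter == "maf"], 1L)
  expect_equal(rep$removed[rep$filter == "hwe"], 1L)
  expect_equal(rep$removed[rep$filter == "mhc"], 1L)
  expect_setequal(variantIds(res$genotypes), c("v_ok1", "v_ok2"))
  expect_equal(attr(rep, "n_input"), 8L)
  expect_equal(attr(rep, "n_surviving"), 2L)
})

test_that("all-passing input is returned unchanged with an all-zero report", {
  set.seed(5)
  calls <- matrix(sample(0:2, 200, replace = TRUE, prob = c(.4, .4, .2)),
                  nrow = 20)
  g <- makeGenotypeMatrix(calls)
  res <- applyQC(g, qcConfig())
  expect_equal(res$report$removed, rep(0L, 6))
  expect_identical(genotypeCalls(res$genotypes), genotypeCalls(g))
})

test_that("QC is idempotent and MHC exclusion is a closed 1-based interval", {
  set.seed(6)
  calls <- matrix(sample(0:2, 30 * 6, replace = TRUE), nrow = 30)
  g <- makeGenotypeMatrix(
    calls, chrom = rep("chr6", 6),
    pos = c(28866527L, 28866528L, 30000000L, 33775446L, 33775447L, 40000000L),
    ids = sprintf("m%d", 1:6))
  res1 <- applyQC(g, qcConfig())
  # exactly the in-interval variants go; boundary positions included
  expect_setequal(setdiff(variantIds(g), variantIds(res1$genotypes)),
                  c("m2", "m3", "m4"))
  res2 <- applyQC(res1$genotypes, qcConfig())
  expect_identical(genotypeCalls(res2$genotypes),
                   genotypeCalls(res1$genotypes))
  expect_equal(sum(res2$report$removed), 0L)
})

test_that("HWE sample restriction uses the requested subset", {
  # recipients in equilibrium, donors wildly out -> variant kept only
  # when HWE is restricted to recipients
  set.seed(7)
  donors <- rep(c(0L, 2L), 20)                # no hets
  recips <- stats::rbinom(40, 2, 0.5)
  calls <- cbind(v1 = c(donors, recips),
                 v2 = stats::rbinom(80, 2, 0.4))
  rownames(calls) <- c(sprintf("d%03d", 1:40), sprintf("r%03d", 1:40))
  g <- makeGenotypeMatrix(calls, ids = c("v1", "v2"))
  cohort <- makePairCohort(40)
  pooled <- applyQC(g, qcConfig(), cohort)
  restricted <- applyQC(g, qcConfig(hweSamples = "recipients"), cohort)
  expect_false("v1" %in% variantIds(pooled$genotypes))
  expect_true("v1" %in% variantIds(restricted$genotypes))
  expect_error(applyQC(g, qcConfig(hweSamples = "recipients")),
               "cohort required")
})

test_that("pair tables validate and round-trip", {
  cohort <- makePairCohort(5)
  path <- tempfile(fileext = ".tsv")
  writePairs(cohort, path)
  back <- readPairs(path)
  expect_equal(pairData(back), pairData(cohort))
  bad <- pairData(cohort)
  bad$event[2] <- 2
  badPath <- tempfile(fileext = ".tsv")
  utils::write.table(bad, badPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readPairs(badPath), "event")
  bad2 <- pairData(cohort)
  bad2$follow_time[1] <- 0
  utils::write.table(bad2, badPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readPairs(badPath), "follow_time")
  expect_error(readPairs({
    p <- tempfile()
    utils::write.table(pairData(cohort)[, -3], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p
  }), "missing required column")
})

test_that("BED regions follow the half-open convention and round-trip", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tgeneA", "chr2\t50\t80\tgeneB"), path)
  gr <- readRegions(path)
  # BED 0..100 covers 1-based positions 1..100
  expect_equal(GenomicRanges::start(gr), c(1L, 51L))
  expect_equal(GenomicRanges::end(gr), c(100L, 80L))
  expect_equal(S4Vectors::mcols(gr)$region_id, c("geneA", "geneB"))
  out <- tempfile(fileext = ".bed")
  writeRegions(gr, out)
  gr2 <- readRegions(out)
  expect_equal(GenomicRanges::start(gr2), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(gr2), GenomicRanges::end(gr))
  expect_equal(S4Vectors::mcols(gr2)$region_id,
               S4Vectors::mcols(gr)$region_id)
})
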