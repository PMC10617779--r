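test_that("variant mismatch matches allele-set containment on all 9 combos", {
  for (d in 0:2) for (r in 0:2) {
    got <- variantMismatch(d, r)
    want <- oracleMismatch(d, r)
    expect_equal(got$category, want$category,
                 info = sprintf("d=%d r=%d", d, r))
    expect_equal(got$n_introduced, want$n_introduced)
    if (want$n_introduced > 0)
      expect_equal(got$introduced_allele, want$introduced_allele)
  }
  # asymmetry witness: both single, opposite introduced alleles
  a <- variantMismatch(1, 0)
  b <- variantMismatch(0, 1)
  expect_equal(a$category, "SINGLE")
  expect_equal(b$category, "NONE")
  expect_equal(variantMismatch(1, 2)$introduced_allele, "REF")
  expect_equal(variantMismatch(1, 0)$introduced_allele, "ALT")
  # missing propagates, out-of-range errors
  expect_equal(variantMismatch(NA, 0)$category, "MISSING")
  expect_error(variantMismatch(3, 0), "out of range")
})

test_that("mismatch table applies the rule elementwise with MISSING cells", {
  calls <- rbind(d001 = c(1L, 2L, 0L, NA),
                 r001 = c(0L, 2L, 2L, 1L))
  g <- makeGenotypeMatrix(calls)
  cohort <- makePairCohort(1, donorIds = "d001", recipientIds = "r001")
  tab <- buildMismatchTable(g, cohort)
  any <- anyMismatch(tab)[1, ]
  expect_equal(unname(any), c(TRUE, FALSE, TRUE, NA))
  expect_equal(unname(doubleMismatch(tab)[1, ]), c(FALSE, FALSE, TRUE, NA))
  # double implies any wherever defined
  expect_true(all(!doubleMismatch(tab) | anyMismatch(tab), na.rm = TRUE))
  expect_error(buildMismatchTable(g, makePairCohort(1, donorIds = "nope",
                                                    recipientIds = "r001")),
               "not in genotype matrix")
})

test_that("self-pairs have no mismatches anywhere", {
  set.seed(11)
  calls <- matrix(sample(c(0:2, NA), 60, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), nrow = 3)
  rownames(calls) <- c("a", "b", "c")
  g <- makeGenotypeMatrix(calls)
  cohort <- makePairCohort(3, donorIds = c("a", "b", "c"),
                           recipientIds = c("a", "b", "c"))
  tab <- buildMismatchTable(g, cohort)
  expect_true(all(mismatchCodes(tab) == 0L, na.rm = TRUE))
})

test_that("mismatch frequency filter keeps the boundary and matches hand counts", {
  # 20 pairs; engineer per-variant mismatch counts 0,1,2,5 (of 20)
  nP <- 20L
  mk <- function(k) c(rep(1L, k), rep(0L, nP - k))   # donor gt
  calls <- rbind(
    do.call(cbind, lapply(c(0L, 1L, 2L, 5L), mk)),   # donors
    matrix(0L, nP, 4))                               # recipients all 0/0
  rownames(calls) <- c(sprintf("d%03d", 1:nP), sprintf("r%03d", 1:nP))
  # donor rows must align per pair: rebuild as pair-major
  donors <- do.call(cbind, lapply(c(0L, 1L, 2L, 5L), mk))
  recips <- matrix(0L, nP, 4)
  calls <- rbind(donors, recips)
  rownames(calls) <- c(sprintf("d%03d", 1:nP), sprintf("r%03d", 1:nP))
  g <- makeGenotypeMatrix(calls, ids = c("f0", "f1", "f2", "f5"))
  tab <- buildMismatchTable(g, makePairCohort(nP))
  res <- mismatchFrequencyFilter(tab, minFreq = 0.05)
  expect_equal(sort(res$frequencies$mismatch_freq),
               c(0, 1, 2, 5) / 20)
  # 1/20 = 0.05 sits exactly at the threshold and is kept
  expect_setequal(res$variant_ids, c("f1", "f2", "f5"))
})

test_that("region scores sum indicators with overlap and empty conventions", {
  # one pair; variants at pos 100..500 with calls S, D, N, S, D
  donors <- matrix(c(1L, 2L, 0L, 1L, 2L), 1)
  recips <- matrix(c(0L, 0L, 0L, 0L, 0L), 1)
  calls <- rbind(donors, recips)
  rownames(calls) <- c("d001", "r001")
  g <- makeGenotypeMatrix(calls, pos = c(100L, 200L, 300L, 400L, 500L))
  tab <- buildMismatchTable(g, makePairCohort(1))
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(50L, 350L, 150L, 600L),
                             c(310L, 550L, 450L, 700L)),
    region_id = c("gA", "gB", "gOverlap", "gEmpty"),
    region_class = "gene")
  # gA covers (S,D,N) -> any 2, double 1; gB covers (S,D) -> 2, 1;
  # gOverlap covers (D,N,S) -> 2, 1; gEmpty -> 0
  expect_warning(rs <- regionScore(tab, regions, mode = "any"),
                 "no variants")
  expect_equal(unname(rs$raw[1, ]), c(2, 2, 2, 0))
  expect_warning(rd <- regionScore(tab, regions, mode = "double"),
                 "no variants")
  expect_equal(unname(rd$raw[1, ]), c(1, 1, 1, 0))
  # overlapping regions each count shared variants: region totals exceed
  # the genome-wide raw (4 mismatched variants in all)
  expect_equal(sum(rs$raw[1, ]), 6)
  expect_equal(sum(anyMismatch(tab)[1, ], na.rm = TRUE), 4L)
})

test_that("genome-wide score normalizes by IQR and errors on zero IQR", {
  # 4 pairs with raws 10, 30, 10, 30 -> IQR 20 -> normalized 0.5, 1.5
  nP <- 4L
  nV <- 40L
  donors <- rbind(c(rep(1L, 10), rep(0L, 30)),
                  c(rep(1L, 30), rep(0L, 10)),
                  c(rep(1L, 10), rep(0L, 30)),
                  c(rep(1L, 30), rep(0L, 10)))
  recips <- matrix(0L, nP, nV)
  calls <- rbind(donors, recips)
  rownames(calls) <- c(sprintf("d%03d", 1:nP), sprintf("r%03d", 1:nP))
  g <- makeGenotypeMatrix(calls, ids = sprintf("w%02d", 1:nV))
  tab <- buildMismatchTable(g, makePairCohort(nP))
  st <- genomeWideScore(tab)
  expect_equal(unname(rawScores(st)), c(10, 30, 10, 30))
  expect_equal(st@iqr, 20)
  expect_equal(unname(normScores(st)), c(0.5, 1.5, 0.5, 1.5))
  # identical D-R genotypes -> all raws 0 -> zero IQR errors
  same <- makeGenotypeMatrix(matrix(1L, 4, 3,
                                    dimnames = list(c("d001", "d002",
                                                      "r001", "r002"),
                                                    NULL)))
  tab0 <- buildMismatchTable(same, makePairCohort(2))
  expect_true(all(rowSums(anyMismatch(tab0)) == 0))
  expect_error(genomeWideScore(tab0), "IQR")
})

test_that("adding universally mismatched variants shifts raws, keeps ranking", {
  set.seed(12)
  nP <- 6L
  donors <- matrix(sample(0:2, nP * 30, replace = TRUE), nP)
  recips <- matrix(sample(0:2, nP * 30, replace = TRUE), nP)
  callsA <- rbind(donors, recips)
  rownames(callsA) <- c(sprintf("d%03d", 1:nP), sprintf("r%03d", 1:nP))
  gA <- makeGenotypeMatrix(callsA, ids = sprintf("a%02d", 1:30))
  # add 5 variants mismatched in every pair (donor 2, recipient 0)
  callsB <- cbind(callsA, rbind(matrix(2L, nP, 5), matrix(0L, nP, 5)))
  gB <- makeGenotypeMatrix(callsB, ids = c(sprintf("a%02d", 1:30),
                                           sprintf("u%02d", 1:5)))
  cohort <- makePairCohort(nP)
  rawA <- rawScores(genomeWideScore(buildMismatchTable(gA, cohort)))
  rawB <- rawScores(genomeWideScore(buildMismatchTable(gB, cohort)))
  expect_equal(unname(rawB - rawA), rep(5, nP))
  expect_equal(order(rawA), order(rawB))
})

test_that("class scores partition the genome-wide raw score", {
  set.seed(13)
  nP <- 8L
  nV <- 50L
  donors <- matrix(sample(0:2, nP * nV, replace = TRUE), nP)
  recips <- matrix(sample(0:2, nP * nV, replace = TRUE), nP)
  calls <- rbind(donors, recips)
  rownames(calls) <- c(sprintf("d%03d", 1:nP), sprintf("r%03d", 1:nP))
  g <- makeGenotypeMatrix(calls)
  tab <- buildMismatchTable(g, makePairCohort(nP))
  classes <- data.frame(variant_id = variantIds(tab),
                        class = rep(c("exonic", "non_exonic"),
                                    length.out = nV))
  cs <- classScores(tab, classes)
  total <- rawScores(cs$scores$exonic) + rawScores(cs$scores$non_exonic)
  expect_equal(unname(total),
               unname(rawScores(genomeWideScore(tab))))
  expect_equal(dim(cs$correlation), c(2L, 2L))
  expect_error(classScores(tab, classes, which = "bogus"), "unknown class")
})

test_that("IQR normalization preserves ordering and correlations", {
  set.seed(14)
  raw <- sample(50:150, 30)
  st <- DRmismatch:::.scoreTable(raw, sprintf("p%02d", 1:30), "genome_wide",
                                 "any")
  expect_equal(order(rawScores(st)), order(normScores(st)))
  other <- rnorm(30)
  expect_equal(cor(rawScores(st), other), cor(normScores(st), other))
})

test_that("pi-hat recovers self, unrelated and parent-offspring pairs", {
  set.seed(15)
  nV <- 6000L
  p <- runif(nV, 0.1, 0.9)
  drawHap <- function() as.integer(runif(nV) < p)
  gtSelf <- drawHap() + drawHap()
  expect_gt(suppressWarnings(estimatePibd(gtSelf, gtSelf, p)), 0.95)
  gtA <- drawHap() + drawHap()
  gtB <- drawHap() + drawHap()
  expect_lt(abs(estimatePibd(gtA, gtB, p)), 0.05)
  # parent-offspring: child inherits one parental haplotype
  parentH1 <- drawHap()
  parent <- parentH1 + drawHap()
  child <- parentH1 + drawHap()
  expect_lt(abs(estimatePibd(parent, child, p) - 0.5), 0.05)
  # low-information warning
  expect_warning(estimatePibd(gtA[1:50], gtB[1:50], p[1:50]),
                 "fewer than 100")
})
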