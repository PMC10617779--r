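test_that("r2 is 1 for identical loci and ~0 for independent loci", {
  set.seed(21)
  a <- rbinom(400, 2, 0.35)
  res <- pairwiseR2(a, a)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  expect_equal(sum(res$hapFreqs), 1, tolerance = 1e-9)
  big <- pairwiseR2(rbinom(10000, 2, 0.4), rbinom(10000, 2, 0.6))
  expect_lt(big$r2, 0.01)
  expect_error(pairwiseR2(rep(1L, 50), rbinom(50, 2, 0.5)), "monomorphic")
})

test_that("EM r2 matches the phased closed form when phase is unambiguous", {
  set.seed(22)
  for (rep in 1:10) {
    # draw correlated haplotypes, then keep only individuals that are
    # not double heterozygotes so phase is forced
    n <- 500L
    hapFreq <- c(AB = 0.45, Ab = 0.1, aB = 0.05, ab = 0.4)
    draw <- sample(1:4, 4 * n, replace = TRUE, prob = hapFreq)
    hap <- cbind(draw %in% c(1, 2), draw %in% c(1, 3)) * 1L
    h1 <- hap[seq(1, 4 * n, 2), ]
    h2 <- hap[seq(2, 4 * n, 2), ]
    gA <- h1[, 1] + h2[, 1]
    gB <- h1[, 2] + h2[, 2]
    keep <- !(gA == 1L & gB == 1L)
    haps <- rbind(h1[keep, ], h2[keep, ])
    expect_equal(pairwiseR2(gA[keep], gB[keep])$r2,
                 oracleR2FromHaps(haps), tolerance = 1e-6)
  }
})

test_that("blocks are recovered and recombinants dropped", {
  set.seed(23)
  n <- 400L
  k <- 12L
  hapFreq <- 0.3
  h1 <- runif(n) < hapFreq
  h2 <- runif(n) < hapFreq
  # perfect-LD members with mixed allele orientation
  orient <- c(TRUE, FALSE)[rep_len(1:2, k)]
  calls <- sapply(seq_len(k), function(j) {
    x <- (h1 + h2)
    if (orient[j]) as.integer(x) else 2L - as.integer(x)
  })
  # independent tag + a recombinant member at degraded r2
  tag <- rbinom(n, 2, 0.5)
  recomb <- as.integer(h1 + h2)
  flip <- sample(n, round(0.12 * n))
  recomb[flip] <- rbinom(length(flip), 2, hapFreq)
  calls <- cbind(calls, recomb, tag)
  rownames(calls) <- sprintf("s%04d", seq_len(n))
  ids <- c(sprintf("m%02d", 1:k), "recomb", "tagv")
  g <- makeGenotypeMatrix(calls, ids = ids)
  r2rec <- pairwiseR2(calls[, 1], recomb)$r2
  expect_lt(r2rec, 0.95)
  expect_gt(r2rec, 0.5)
  blk <- buildBlock(g, c(sprintf("m%02d", 1:k), "recomb"),
                    r2In = 0.99, tagVariant = "tagv", r2Out = 0.5)
  expect_setequal(blockMembers(blk), sprintf("m%02d", 1:k))
  expect_false("recomb" %in% blockMembers(blk))
  # orientation: minor haplotype frequency below 0.5 and dosages match truth
  expect_lt(blk@minorHapFreq, 0.5)
  expect_equal(unname(blockDosage(blk)), as.integer(h1 + h2))
  expect_equal(unname(blk@discordance[!is.na(blockDosage(blk))]),
               rep(0, n))
  # a retained member linked to the tag triggers the exclusion error
  tagLinked <- tag
  flip2 <- sample(n, 10)
  tagLinked[flip2] <- rbinom(10, 2, 0.5)
  g2 <- makeGenotypeMatrix(cbind(calls, taglinked = tagLinked),
                           ids = c(ids, "taglinked"))
  expect_error(buildBlock(g2, "taglinked", r2In = 0.99,
                          tagVariant = "tagv", r2Out = 0.5),
               "linked to tag.*taglinked")
  # degenerate single-seed block
  one <- buildBlock(g, "m01")
  expect_equal(blockMembers(one), "m01")
})

test_that("haplotype dosage follows strict majority with tie and missing rules", {
  k <- 30L
  mkBlock <- function(calls) {
    rownames(calls) <- sprintf("s%03d", seq_len(nrow(calls)))
    g <- makeGenotypeMatrix(calls, ids = sprintf("m%02d", seq_len(k)))
    blk <- new("HaplotypeBlock", members = sprintf("m%02d", seq_len(k)),
               minorAllele = rep("ALT", k), dosage = integer(0),
               discordance = numeric(0),
               r2 = diag(1, k), tagVariant = "", minorHapFreq = 0.3)
    haplotypeDosage(blk, g)
  }
  # all homozygous minor
  resHom <- mkBlock(matrix(2L, 1, k))
  expect_equal(unname(resHom$dosage), 2L)
  expect_equal(unname(resHom$discordance), 0)
  # 29 members say 1, one says 0
  res29 <- mkBlock(matrix(c(0L, rep(1L, k - 1)), 1, k))
  expect_equal(unname(res29$dosage), 1L)
  expect_equal(unname(res29$discordance), 1 / 30, tolerance = 1e-12)
  # perfect 15/15 tie -> missing
  resTie <- mkBlock(matrix(rep(c(0L, 1L), each = 15), 1, k))
  expect_true(is.na(resTie$dosage))
  # >50% missing -> missing even with unanimous rest
  resMiss <- mkBlock(matrix(c(rep(NA_integer_, 16), rep(2L, 14)), 1, k))
  expect_true(is.na(resMiss$dosage))
  # exactly 50% missing is still callable
  resHalf <- mkBlock(matrix(c(rep(NA_integer_, 15), rep(2L, 15)), 1, k))
  expect_equal(unname(resHalf$dosage), 2L)
})

test_that("haplotype mismatch treats the block as one biallelic locus", {
  expect_equal(haplotypeMismatch(1, 0),
               data.frame(n_alien = 1L, direction = "minor"))
  expect_equal(haplotypeMismatch(0, 2),
               data.frame(n_alien = 2L, direction = "major"))
  for (d in 0:2)
    expect_equal(haplotypeMismatch(d, 1)$n_alien, 0L)
  # reduces exactly to variant mismatch over the full grid
  for (d in 0:2) for (r in 0:2) {
    hm <- haplotypeMismatch(d, r)
    vm <- variantMismatch(d, r)
    expect_equal(hm$n_alien, vm$n_introduced)
  }
})

test_that("tag risk mismatch requires hom-non-risk recipient and risk-carrying donor", {
  expect_true(tagRiskMismatch(1, 0))    # A/G donor into G/G recipient
  expect_false(tagRiskMismatch(0, 0))   # G/G donor
  for (d in 0:2) expect_false(tagRiskMismatch(d, 1))
  for (d in 0:2) expect_false(tagRiskMismatch(d, 2))
  expect_true(tagRiskMismatch(2, 0))
  # REF-risk orientation mirrors the logic
  expect_true(tagRiskMismatch(1, 2, riskAllele = "REF"))
  expect_false(tagRiskMismatch(2, 2, riskAllele = "REF"))
  expect_true(is.na(tagRiskMismatch(NA, 0)))
})

test_that("direction classes partition the exhaustive grid with tag precedence", {
  grid <- expand.grid(dd = 0:2, rd = 0:2, dt = 0:2, rt = 0:2)
  cls <- classifyDirection(grid$dd, grid$rd, grid$dt, grid$rt)
  expect_false(anyNA(cls))
  expect_equal(length(cls), nrow(grid))   # exactly one class per combo
  tagRisk <- grid$rt == 0 & grid$dt >= 1
  expect_true(all(cls[tagRisk] == "TAG_RISK"))
  expect_true(all(cls[!tagRisk] != "TAG_RISK"))
  noTag <- !tagRisk
  expect_true(all(cls[noTag & grid$rd == 0 & grid$dd >= 1] ==
                    "MINOR_INTRODUCING"))
  expect_true(all(cls[noTag & grid$rd == 2 & grid$dd <= 1] ==
                    "MAJOR_INTRODUCING"))
  expect_true(all(cls[noTag & (grid$rd == 1 | grid$dd == grid$rd)] ==
                    "OTHER"))
  # tag precedence holds even with a minor-introducing haplotype mismatch
  expect_equal(as.character(classifyDirection(2, 0, 1, 0)), "TAG_RISK")
  expect_true(is.na(classifyDirection(NA, 0, 1, 0)))
})
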