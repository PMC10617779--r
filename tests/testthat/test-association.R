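test_that("Cox fit matches the grid-search partial-likelihood oracle", {
  # fixed 8-subject dataset, one binary covariate, no ties
  time <- c(2, 5, 7, 9, 12, 14, 17, 20)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 1, 0, 1, 0, 1, 0, 0)
  fit <- fitCox(time, event, data.frame(x = x))
  expect_equal(coefTable(fit)$beta, oracleCoxBeta(time, event, x),
               tolerance = 1e-6)
  # randomized micro-datasets (property): n <= 10, one covariate, no ties
  set.seed(31)
  for (i in 1:12) {
    n <- sample(5:10, 1)
    t <- sample(100, n)  # distinct -> tie-free
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) < 2) ev[1:2] <- 1L
    xx <- rnorm(n)
    fit <- fitCox(t, ev, data.frame(x = xx))
    if (fit@converged)
      expect_equal(coefTable(fit)$beta, oracleCoxBeta(t, ev, xx),
                   tolerance = 1e-6, info = paste("rep", i))
  }
})

test_that("identical groups give beta ~0 and HR/CI contract holds", {
  set.seed(32)
  time <- rep(c(3, 6, 9, 12, 15, 18, 21, 24), 2)
  event <- rep(c(1, 0, 1, 1, 0, 1, 0, 1), 2)
  grp <- rep(0:1, each = 8)
  fit <- fitCox(time, event, data.frame(g = grp))
  co <- coefTable(fit)
  expect_lt(abs(co$beta), 1e-6)
  expect_gt(co$p, 0.99)
  expect_equal(co$hr, exp(co$beta))
  expect_equal(co$lower95, exp(co$beta - 1.96 * co$se))
  expect_equal(co$upper95, exp(co$beta + 1.96 * co$se))
  expect_error(fitCox(time, rep(0, 16), data.frame(g = grp)),
               "at least one event")
})

test_that("stratified fit with a single stratum equals the unstratified fit", {
  set.seed(33)
  n <- 60
  x <- rnorm(n)
  time <- rexp(n, exp(0.4 * x))
  event <- rbinom(n, 1, 0.8)
  plain <- fitCox(time, event, data.frame(x = x))
  strat <- fitCox(time, event, data.frame(x = x),
                  strata = rep("only", n))
  expect_equal(coefTable(plain)$beta, coefTable(strat)$beta,
               tolerance = 1e-8)
})

test_that("Kaplan-Meier and log-rank match hand computation", {
  # 6 subjects, 2 groups; hand-worked risk table
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 1, 1)
  grp <- c("A", "B", "A", "B", "A", "B")
  res <- kmLogrank(time, event, grp)
  # observed events: A = 3, B = 2
  expect_equal(unname(res$observed), c(3, 2))
  # expected under H0, event times 1,2,3,5,6:
  # t=1: 3/6; t=2: 2/5; t=3: 2/4; t=5: 1/2; t=6: 0/1  (group A share)
  expA <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 2 + 0
  expect_equal(unname(res$expected)[1], expA, tolerance = 1e-9)
  expect_equal(sum(res$observed), sum(res$expected), tolerance = 1e-9)
  expect_equal(res$df, 1L)
  expect_error(kmLogrank(time, event, rep("A", 6)), "two groups")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(34)
  t <- sort(sample(1000, 30))
  res <- kmLogrank(c(t, t + 1), rep(1, 60), rep(c("A", "B"), each = 30))
  a <- res$curves[res$curves$group == "A", ]
  expect_equal(a$surv, 1 - seq_len(30) / 30)
})

test_that("two-group log-rank equals the Cox score test at beta 0", {
  set.seed(35)
  for (i in 1:8) {
    n <- 40
    x <- rbinom(n, 1, 0.5)
    time <- sample(10000, n)          # tie-free
    event <- rbinom(n, 1, 0.7)
    if (length(unique(x[event == 1])) < 2) next
    lr <- kmLogrank(time, event, x)
    expect_equal(lr$chisq, oracleCoxScoreStat(time, event, x),
                 tolerance = 1e-6, info = paste("rep", i))
  }
})

test_that("aggregate gene score adds up and complements the genome", {
  set.seed(36)
  nP <- 10L
  nV <- 30L
  donors <- matrix(sample(0:2, nP * nV, replace = TRUE), nP)
  recips <- matrix(sample(0:2, nP * nV, replace = TRUE), nP)
  calls <- rbind(donors, recips)
  rownames(calls) <- c(sprintf("d%03d", 1:nP), sprintf("r%03d", 1:nP))
  g <- makeGenotypeMatrix(calls, pos = 100L * seq_len(nV))
  cohort <- makePairCohort(nP)
  tab <- buildMismatchTable(g, cohort)
  # three disjoint genes tiling all variants
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1L, 1001L, 2001L), c(1000L, 2000L, 3000L)),
    region_id = c("gA", "gB", "gC"), region_class = "gene")
  one <- aggregateGeneScore("gA", tab, regions)
  rsAll <- regionScore(tab, regions)
  expect_equal(unname(rawScores(one$aggregate)),
               unname(rsAll$raw[, "gA"]))
  all3 <- aggregateGeneScore(c("gA", "gB", "gC"), tab, regions)
  expect_equal(unname(rawScores(all3$aggregate)),
               unname(rowSums(rsAll$raw)))
  # genes tile every variant: aggregate + complement == genome-wide raw
  gw <- genomeWideScore(tab)
  expect_equal(unname(rawScores(all3$aggregate) +
                        rawScores(all3$complement)),
               unname(rawScores(gw)))
  expect_equal(unname(rawScores(all3$complement)), rep(0, nP))
  expect_error(aggregateGeneScore("nope", tab, regions), "not in annotation")
})

test_that("gene screen is deterministic and flags thresholds correctly", {
  set.seed(37)
  sim <- simulateCohort(cohortConfig(nPairs = 120L, nVariants = 1231L,
                                     nGenes = 40L, seed = 91L))
  tab <- buildMismatchTable(sim$genotypes, sim$cohort)
  gw <- genomeWideScore(tab)
  scr1 <- geneScreen(tab, sim$regions, sim$cohort, gw, threshold = 0.05)
  scr2 <- geneScreen(tab, sim$regions[rev(seq_along(sim$regions))],
                     sim$cohort, gw, threshold = 0.05)
  r1 <- screenResults(scr1)
  r2 <- screenResults(scr2)
  r2 <- r2[order(match(r2$unit, r1$unit), r2$scenario), ]
  r1 <- r1[order(match(r1$unit, r1$unit), r1$scenario), ]
  expect_equal(r1$p, r2$p)            # permuting gene order changes nothing
  # threshold 0 -> empty intersection
  expect_length(intersectionHits(scr1, threshold = 0), 0)
  # intersection flag is exactly "p <= threshold in every scenario"
  hits <- intersectionHits(scr1)
  byUnit <- tapply(r1$p <= 0.05, r1$unit, all)
  expect_setequal(hits, names(byUnit)[byUnit %in% TRUE])
})

test_that("dosage trend fits a numeric exposure and rejects degenerate input", {
  set.seed(38)
  n <- 150L
  dos <- sample(0:2, n, replace = TRUE, prob = c(.5, .35, .15))
  time <- rexp(n, 0.002 * exp(0.5 * dos)) + 1
  cohort <- makePairCohort(n, time = pmin(time, 2000),
                           event = as.integer(time < 2000))
  res <- dosageTrend(dos, cohort)
  expect_s4_class(res$fit, "CoxFit")
  expect_gt(coefTable(res$fit)$beta, 0)
  expect_equal(res$km$df, length(unique(dos)) - 1L)
  expect_error(dosageTrend(rep(0L, n), cohort), "single level")
})

test_that("variant screen runs four scenarios and excludes the tag from itself", {
  sim <- simulateCohort(cohortConfig(nPairs = 200L, nVariants = 231L,
                                     nGenes = 8L, seed = 39L))
  tab <- buildMismatchTable(sim$genotypes, sim$cohort)
  p <- pairData(sim$cohort)
  tagRisk <- tagRiskMismatch(sim$truth$donorTag, sim$truth$recipientTag)
  vs <- variantScreen(c(sim$truth$blockMembers, "tagSNP"), tab,
                      sim$cohort, tagRisk, tagVariant = "tagSNP")
  r <- screenResults(vs)
  expect_false("tagSNP" %in% r$unit)
  expect_setequal(unique(r$scenario),
                  c("adjusted/all", "adjusted/subset",
                    "stratified/all", "stratified/subset"))
  # the stratified model drops exactly the tag-risk pairs
  nStrat <- unique(r$n[r$scenario == "stratified/all" & r$converged])
  expect_equal(nStrat, nrow(p) - sum(tagRisk))
  nAdj <- unique(r$n[r$scenario == "adjusted/all" & r$converged])
  expect_equal(nAdj, nrow(p))
  # perfect-LD members share identical mismatch profiles, hence p-values
  pa <- r$p[r$scenario == "adjusted/all"]
  expect_lt(diff(range(pa)), 1e-8)
})
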