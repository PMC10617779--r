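# Independent oracles and small fixture builders shared across tests.
# Each oracle deliberately takes a different computational path from the
# implementation it checks.

# ---- allele-multiset containment oracle for variant mismatch ----
# Donor/recipient genotypes as allele multisets; a mismatch is any donor
# allele (with multiplicity of distinct type) absent from the recipient.
oracleMismatch <- function(d, r) {
  alleles <- function(g) c(rep("REF", 2 - g), rep("ALT", g))
  da <- alleles(d)
  ra <- alleles(r)
  alien <- setdiff(unique(da), unique(ra))
  nIntro <- sum(da %in% alien)
  list(category = c("NONE", "SINGLE", "DOUBLE")[nIntro + 1],
       n_introduced = nIntro,
       introduced_allele = if (nIntro == 0) "none" else alien)
}

# ---- HWE exact-test oracle by full enumeration with plain factorials ----
# Valid for n <= 50 (factorial(100) is representable in doubles).
oracleHwe <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n2 + n1
  nB <- 2 * n0 + n1
  hs <- seq.int(min(nA, nB) %% 2, min(nA, nB), by = 2)
  pr <- vapply(hs, function(h) {
    a <- (nA - h) / 2
    b <- (nB - h) / 2
    factorial(n) / (factorial(a) * factorial(h) * factorial(b)) *
      2^h * factorial(nA) * factorial(nB) / factorial(2 * n)
  }, numeric(1))
  obs <- pr[match(n1, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# ---- grid-search partial-likelihood oracle for one-covariate Cox ----
# Tie-free data; explicit Breslow/Efron-free partial likelihood (no ties
# means all tie methods coincide). Coarse grid then golden-section
# refinement on the written-out log partial likelihood.
oracleCoxBeta <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event == 1]))
  logpl <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  grid <- seq(-8, 8, by = 0.05)
  b0 <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  stats::optimize(logpl, c(b0 - 0.1, b0 + 0.1), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Score test of H0: beta = 0 for a one-covariate Cox model on tie-free
# data (classically identical to the two-group log-rank statistic).
oracleCoxScoreStat <- function(time, event, x) {
  U <- 0
  I <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    xr <- x[risk]
    U <- U + x[i] - mean(xr)
    I <- I + mean(xr^2) - mean(xr)^2
  }
  U^2 / I
}

# ---- two-locus LD closed form from known phased haplotypes ----
# haps: 2n x 2 matrix of 0/1 alleles (rows = haplotypes)
oracleR2FromHaps <- function(haps) {
  pA <- mean(haps[, 1])
  pB <- mean(haps[, 2])
  fAB <- mean(haps[, 1] == 1 & haps[, 2] == 1)
  d <- fAB - pA * pB
  d^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Hudson-style FST between two populations from their true allele
# frequencies (ratio of averages).
oracleFst <- function(p1, p2) {
  mean((p1 - p2)^2 - 0) / mean(p1 * (1 - p2) + p2 * (1 - p1))
}

# ---- small fixture builders ----

makeGenotypeMatrix <- function(calls, chrom = NULL, pos = NULL,
                               ids = NULL) {
  nv <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", nv)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(nv))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("s%03d", seq_len(nrow(calls)))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                               variant_id = ids,
                               ref = rep("A", nv), alt = rep("G", nv))
  GenotypeMatrix(calls, gr)
}

makePairCohort <- function(n, donorIds = sprintf("d%03d", seq_len(n)),
                           recipientIds = sprintf("r%03d", seq_len(n)),
                           time = NULL, event = NULL, ancestry = "EUR") {
  if (is.null(time)) time <- seq_len(n) * 100
  if (is.null(event)) event <- rep(c(1L, 0L), length.out = n)
  PairCohort(data.frame(
    donor_id = donorIds, recipient_id = recipientIds,
    follow_time = time, event = event,
    hla_mismatch = rep(2, n), donor_status = rep("living", n),
    induction = rep("depleting", n),
    donor_ancestry = rep_len(ancestry, n),
    recipient_ancestry = rep_len(ancestry, n)))
}

# Write a small VCF by hand for reader tests.
writeFixtureVcf <- function(path, records, samples, gpHeader = FALSE) {
  fmt <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"info\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">")
  if (gpHeader)
    fmt <- c(fmt,
             "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"gp\">")
  fmt <- c(fmt, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  writeLines(c(fmt, records), path)
  path
}
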