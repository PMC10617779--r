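#' @include accessors.R
NULL

#' Configure the synthetic transplant cohort generator
#'
#' Builds a \linkS4class{CohortConfig}. The defaults emulate the
#' structure of a prospective kidney-transplant genomics cohort: 385
#' donor-recipient pairs, a ~13\% death-censored graft-loss event rate
#' over a 1,824-day administrative horizon, a European-majority ancestry
#' mix with Balding-Nichols divergence F = 0.1, a living-related donor
#' fraction giving expected pairwise IBD 0.25 or 0.5, a planted 30-SNP
#' near-perfect-LD haplotype block whose minor-haplotype frequency
#' varies by ancestry, and an unlinked tag SNP whose ALT allele is the
#' risk allele.
#'
#' @param nPairs number of donor-recipient pairs.
#' @param nVariants total variant count (background + block members +
#'   tag).
#' @param nGenes number of annotated gene regions (the last one spans
#'   the block locus).
#' @param ancestry list(labels, props, fst).
#' @param relatedness list(props): proportions of pairs at expected IBD
#'   fraction 0, 0.25 and 0.5.
#' @param block list(nSnps, minorHapFreq (named by ancestry or scalar),
#'   recombFraction, r2In, r2Out).
#' @param tag list(riskAlleleFreq named by ancestry or scalar).
#' @param hazard list(betaGw, betaGene, betaMinor, betaTag, eventRate,
#'   horizon): log-hazard-ratio per unit of the centered normalized
#'   genome-wide score, per alien allele introduced within the
#'   designated causal gene (a double mismatch introduces two), and for
#'   the minor-introducing and tag-risk direction classes; target event
#'   rate; administrative censoring horizon in days.
#' @param eqtl list(effect, noiseSd, nSamples, nGenes, moduleSize,
#'   moduleR): additive expression effect per minor haplotype allele
#'   (log2 units), residual SD, expression cohort size, transcriptome
#'   size, and the planted coexpression module (size and correlation to
#'   the target gene).
#' @param seed master seed; all generator randomness flows from it.
#' @return a validated \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(nPairs = 385L, nVariants = 5000L, nGenes = 250L,
                         ancestry = list(labels = c("EUR", "AFR", "EAS"),
                                         props = c(0.7, 0.2, 0.1),
                                         fst = 0.1),
                         relatedness = list(props = c(0.7, 0.2, 0.1)),
                         block = list(nSnps = 30L,
                                      minorHapFreq = c(EUR = 0.37,
                                                       AFR = 0.15,
                                                       EAS = 0.62),
                                      recombFraction = 0,
                                      r2In = 0.99, r2Out = 0.5),
                         tag = list(riskAlleleFreq = c(EUR = 0.62,
                                                       AFR = 0.57,
                                                       EAS = 0.9)),
                         hazard = list(betaGw = log(1.46), betaGene = 0,
                                       betaMinor = log(2), betaTag = log(2),
                                       eventRate = 0.13, horizon = 1824),
                         eqtl = list(effect = 0.5, noiseSd = 1,
                                     nSamples = 91L, nGenes = 1000L,
                                     moduleSize = 50L, moduleR = 0.8),
                         seed = 1L) {
  defaults <- formals(cohortConfig)
  fill <- function(given, name) {
    def <- eval(defaults[[name]])
    for (k in setdiff(names(def), names(given))) given[[k]] <- def[[k]]
    given
  }
  new("CohortConfig", nPairs = as.integer(nPairs),
      nVariants = as.integer(nVariants), nGenes = as.integer(nGenes),
      ancestry = fill(ancestry, "ancestry"),
      relatedness = fill(relatedness, "relatedness"),
      block = fill(block, "block"), tag = fill(tag, "tag"),
      hazard = fill(hazard, "hazard"), eqtl = fill(eqtl, "eqtl"),
      seed = as.integer(seed))
}

.perAncestry <- function(x, labels) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(x, length(labels)), labels))
  if (!all(labels %in% names(x)))
    stop("per-ancestry parameter must be named for: ",
         paste(labels, collapse = ", "))
  x[labels]
}

#' Simulate ancestry-structured allele frequencies
#'
#' Draws an ancestral ALT frequency per variant from Uniform(0.05,
#' 0.95) and per-ancestry frequencies from the Balding-Nichols model:
#' Beta(p(1-F)/F, (1-p)(1-F)/F), whose expectation is p and whose
#' divergence between populations has expected FST approximately F.
#' F = 0 degenerates to identical frequencies in every ancestry.
#'
#' @param config a \linkS4class{CohortConfig}; only the ancestry spec
#'   and variant count are used.
#' @param nVariants number of variants to draw (defaults to the
#'   config's background variant count).
#' @return list with \code{p0} (ancestral frequencies) and \code{freq}
#'   (ancestries x variants matrix, rows named by ancestry label).
#' @export
simulateFrequencies <- function(config, nVariants = NULL) {
  a <- config@ancestry
  if (is.null(nVariants))
    nVariants <- config@nVariants - config@block$nSnps - 1L
  p0 <- stats::runif(nVariants, 0.05, 0.95)
  f <- a$fst
  freq <- matrix(NA_real_, length(a$labels), nVariants,
                 dimnames = list(a$labels, NULL))
  for (i in seq_along(a$labels)) {
    freq[i, ] <- if (f == 0) p0 else
      stats::rbeta(nVariants, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  }
  freq[freq < 1e-4] <- 1e-4
  freq[freq > 1 - 1e-4] <- 1 - 1e-4
  list(p0 = p0, freq = freq)
}

# Draw one pair's four haplotypes over (background, block-as-one-locus,
# tag) and apply locus-level IBD copying from donor to recipient.
# Returns ALT-space haplotype vectors plus block/tag truth.
.drawPair <- function(bgFreqD, bgFreqR, blkFreqD, blkFreqR,
                      tagFreqD, tagFreqR, ibdExpected, nSnps, orientAlt,
                      recombFraction) {
  nB <- length(bgFreqD)
  dH <- list(stats::runif(nB) < bgFreqD, stats::runif(nB) < bgFreqD)
  rH <- list(stats::runif(nB) < bgFreqR, stats::runif(nB) < bgFreqR)
  dBlk <- stats::runif(2) < blkFreqD
  rBlk <- stats::runif(2) < blkFreqR
  dTag <- stats::runif(2) < tagFreqD
  rTag <- stats::runif(2) < tagFreqR
  ibdBg <- 0L
  ibdBlk <- 0L
  ibdTag <- 0L
  if (ibdExpected > 0) {
    for (h in 1:2) {
      mask <- stats::runif(nB) < ibdExpected
      rH[[h]][mask] <- dH[[h]][mask]
      ibdBg <- ibdBg + sum(mask)
      if (stats::runif(1) < ibdExpected) {        # block is one locus
        rBlk[h] <- dBlk[h]
        ibdBlk <- ibdBlk + 1L
      }
      if (stats::runif(1) < ibdExpected) {
        rTag[h] <- dTag[h]
        ibdTag <- ibdTag + 1L
      }
    }
  }
  # member alleles from the block-haplotype pool; optional recombinants
  memberAlleles <- function(blkPair, blkFreq) {
    m <- rbind(ifelse(orientAlt, blkPair[1], 1 - blkPair[1]),
               ifelse(orientAlt, blkPair[2], 1 - blkPair[2]))
    if (recombFraction > 0) {
      rec <- matrix(stats::runif(2 * nSnps) < recombFraction, 2, nSnps)
      indep <- matrix(stats::runif(2 * nSnps) < blkFreq, 2, nSnps)
      indep <- sweep(indep, 2, orientAlt, function(s, o) ifelse(o, s, 1 - s))
      m[rec] <- indep[rec]
    }
    m
  }
  dM <- memberAlleles(dBlk, blkFreqD)
  rM <- memberAlleles(rBlk, blkFreqR)
  nTot <- nB + nSnps + 1L
  ibdFraction <- (ibdBg + ibdBlk * nSnps + ibdTag) / (2 * nTot)
  list(donor = c(dH[[1]] + dH[[2]], dM[1, ] + dM[2, ], sum(dTag)),
       recipient = c(rH[[1]] + rH[[2]], rM[1, ] + rM[2, ], sum(rTag)),
       donorBlockDosage = sum(dBlk), recipientBlockDosage = sum(rBlk),
       donorTag = sum(dTag), recipientTag = sum(rTag),
       ibdFraction = ibdFraction)
}

#' Simulate donor and recipient genotypes for one pair
#'
#' Draws the four haplotypes of a donor-recipient pair over background
#' variants, the planted haplotype block and the tag SNP, sharing loci
#' identity-by-descent at the pair's expected IBD fraction (each locus
#' independently, per haplotype; the block is inherited as a single
#' locus so its internal LD survives relatedness). Block member alleles
#' come intact from a two-haplotype pool, so within-block r-squared is
#' ~1 up to the configured recombinant fraction; the tag SNP is drawn
#' independently of the block pool.
#'
#' @param freq per-ancestry background frequency matrix from
#'   [simulateFrequencies()].
#' @param donorAncestry,recipientAncestry ancestry labels (rows of
#'   \code{freq}).
#' @param ibdExpected expected IBD fraction (0, 0.25, 0.5).
#' @param config a \linkS4class{CohortConfig} (block/tag specs).
#' @param orientAlt logical per block member: TRUE when the minor
#'   haplotype carries the ALT allele (drawn once per cohort).
#' @return list with donor/recipient ALT-count genotype vectors
#'   (background, block members, tag — in that order), true block
#'   dosages, tag genotypes, and the realized IBD fraction.
#' @export
simulatePairGenotypes <- function(freq, donorAncestry, recipientAncestry,
                                  ibdExpected, config, orientAlt) {
  blkF <- .perAncestry(config@block$minorHapFreq, rownames(freq))
  tagF <- .perAncestry(config@tag$riskAlleleFreq, rownames(freq))
  .drawPair(freq[donorAncestry, ], freq[recipientAncestry, ],
            blkF[donorAncestry], blkF[recipientAncestry],
            tagF[donorAncestry], tagF[recipientAncestry],
            ibdExpected, config@block$nSnps, orientAlt,
            config@block$recombFraction)
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with rate
#' \eqn{\lambda_0 \exp(\eta)} where \eqn{\eta} is the supplied linear
#' predictor; censoring is the minimum of the administrative horizon
#' and a Uniform(0, 2 x horizon) time. The baseline rate
#' \eqn{\lambda_0} is calibrated by bisection so the expected event
#' rate matches the target within 0.1 percentage points.
#'
#' @param eta linear predictor per pair (log hazard ratios already
#'   multiplied in; centered by the caller).
#' @param eventRate target expected event proportion in (0,1).
#' @param horizon administrative censoring horizon (days).
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return list with \code{time}, \code{event} (0/1), \code{lambda0},
#'   and \code{expectedRate} (the calibrated expectation).
#' @export
simulateSurvival <- function(eta, eventRate = 0.13, horizon = 1824,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(eta)
  cens <- pmin(horizon, stats::runif(n, 0, 2 * horizon))
  rel <- exp(eta)
  expRate <- function(l0) mean(1 - exp(-l0 * rel * cens))
  lo <- 1e-12
  hi <- 1
  while (expRate(hi) < eventRate && hi < 1e12) hi <- hi * 10
  if (expRate(hi) < eventRate)
    stop("target event rate unattainable within the follow-up horizon")
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (expRate(mid) < eventRate) lo <- mid else hi <- mid
    if (abs(expRate(mid) - eventRate) < 1e-5) break
  }
  lambda0 <- sqrt(lo * hi)
  t <- stats::rexp(n) / (lambda0 * rel)
  list(time = pmin(t, cens), event = as.integer(t <= cens),
       lambda0 = lambda0, expectedRate = expRate(lambda0))
}

#' Simulate a cis-regulated expression matrix
#'
#' The target gene follows an additive cis-eQTL model: intercept 5 +
#' effect x dosage + small age and sex effects + Gaussian noise, on the
#' log2(TPM + 1) scale. A planted coexpression module of
#' \code{moduleSize} genes is generated at correlation \code{moduleR}
#' to the target; remaining genes are independent noise around the same
#' baseline. Values are truncated at 0 (the scale's floor).
#'
#' @param dosage minor-allele dosage per sample in {0,1,2}.
#' @param eqtl list(effect, noiseSd, nGenes, moduleSize, moduleR).
#' @param covariates optional data.frame with columns \code{age} and
#'   \code{sex}; generated when NULL.
#' @param seed optional seed; NULL continues the current stream.
#' @return list with \code{expr} (genes x samples, target gene
#'   "TARGET", module genes "mod_*", noise genes "null_*"),
#'   \code{covariates}, \code{targetGene}, \code{moduleGenes}.
#' @export
simulateExpression <- function(dosage, eqtl, covariates = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(dosage)
  if (is.null(covariates))
    covariates <- data.frame(
      age = round(stats::rnorm(n, 45, 12)),
      sex = sample(c("F", "M"), n, replace = TRUE))
  target <- 5 + eqtl$effect * dosage +
    0.01 * (covariates$age - 45) + 0.2 * (covariates$sex == "M") +
    stats::rnorm(n, 0, eqtl$noiseSd)
  nMod <- eqtl$moduleSize
  nNull <- max(0L, eqtl$nGenes - nMod - 1L)
  z <- as.vector(scale(target))
  r <- eqtl$moduleR
  modM <- matrix(stats::rnorm(nMod * n, 0, sqrt(1 - r^2)), nMod, n,
                 byrow = TRUE)
  modM <- 5 + sweep(modM, 2, r * z, "+")
  nullM <- matrix(stats::rnorm(nNull * n, 5, 1), nNull, n)
  expr <- rbind(matrix(target, 1, n), modM, nullM)
  rownames(expr) <- c("TARGET",
                      sprintf("mod_%03d", seq_len(nMod)),
                      sprintf("null_%04d", seq_len(nNull)))
  colnames(expr) <- names(dosage)
  expr <- pmax(expr, 0)
  list(expr = expr, covariates = covariates, targetGene = "TARGET",
       moduleGenes = sprintf("mod_%03d", seq_len(nMod)))
}

#' Simulate a complete synthetic transplant cohort
#'
#' Generates, from a single seed, every input of the analysis pipeline:
#' paired donor/recipient genotypes with ancestry structure, kinship
#' and a planted causal haplotype block plus tag SNP; the pair table
#' with clinical covariates and survival outcomes from a
#' proportional-hazards model on the pair's own mismatch scores and
#' direction class; gene annotation tiling the background variants; a
#' variant functional-class table; and a cis-regulated expression
#' matrix. The ground truth of every planted parameter is returned for
#' closed-loop recovery tests.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return list with \code{genotypes} (\linkS4class{GenotypeMatrix}),
#'   \code{cohort} (\linkS4class{PairCohort}), \code{regions}
#'   (\code{GRanges}), \code{classes} (data.frame), \code{frequencies}
#'   (per-ancestry background ALT frequencies), \code{expression}, and
#'   \code{truth} (per-pair realized IBD, true block dosages and
#'   direction classes, planted ids and effect sizes).
#' @export
simulateCohort <- function(config) {
  set.seed(config@seed)
  nP <- config@nPairs
  k <- config@block$nSnps
  nB <- config@nVariants - k - 1L
  if (nB < config@nGenes)
    stop("nVariants too small for nGenes")
  a <- config@ancestry

  fr <- simulateFrequencies(config, nB)
  orientAlt <- stats::runif(k) < 0.5

  relLevels <- c(0, 0.25, 0.5)
  relClass <- sample(relLevels, nP, replace = TRUE,
                     prob = config@relatedness$props)
  recipAnc <- sample(a$labels, nP, replace = TRUE, prob = a$props)
  indepAnc <- sample(a$labels, nP, replace = TRUE, prob = a$props)
  donorAnc <- ifelse(relClass > 0, recipAnc, indepAnc)
  # related donors are living; some unrelated donors are living too
  livingUnrel <- stats::runif(nP) < 0.3
  donorStatus <- ifelse(relClass > 0 | livingUnrel, "living", "deceased")

  nV <- config@nVariants
  donorCalls <- matrix(NA_integer_, nP, nV)
  recipCalls <- matrix(NA_integer_, nP, nV)
  ibdFraction <- numeric(nP)
  donorDosage <- integer(nP)
  recipDosage <- integer(nP)
  donorTag <- integer(nP)
  recipTag <- integer(nP)
  for (i in seq_len(nP)) {
    g <- simulatePairGenotypes(fr$freq, donorAnc[i], recipAnc[i],
                               relClass[i], config, orientAlt)
    donorCalls[i, ] <- as.integer(g$donor)
    recipCalls[i, ] <- as.integer(g$recipient)
    ibdFraction[i] <- g$ibdFraction
    donorDosage[i] <- g$donorBlockDosage
    recipDosage[i] <- g$recipientBlockDosage
    donorTag[i] <- g$donorTag
    recipTag[i] <- g$recipientTag
  }

  vids <- c(sprintf("v%05d", seq_len(nB)),
            sprintf("blk%02d", seq_len(k)), "tagSNP")
  chrom <- c(rep("chr1", nB), rep("chr2", k + 1L))
  pos <- c(2000L * seq_len(nB), 50000L + 200L * seq_len(k), 10000L)
  variants <- GRanges(factor(chrom, levels = c("chr1", "chr2")),
                      IRanges(pos, width = 1L),
                      variant_id = vids,
                      ref = rep("A", nV), alt = rep("G", nV),
                      info_score = round(stats::runif(nV, 0.9, 1), 3))

  donorIds <- sprintf("D%04d", seq_len(nP))
  recipIds <- sprintf("R%04d", seq_len(nP))
  calls <- rbind(donorCalls, recipCalls)
  rownames(calls) <- c(donorIds, recipIds)
  genotypes <- GenotypeMatrix(calls, variants)

  # gene annotation: nGenes - 1 genes tile the background variants on
  # chr1; the last gene spans the tag + block locus on chr2
  nGeneBg <- config@nGenes - 1L
  grp <- as.integer(cut(seq_len(nB), nGeneBg, labels = FALSE))
  startPos <- tapply(2000L * seq_len(nB), grp, min) - 500L
  endPos <- tapply(2000L * seq_len(nB), grp, max) + 500L
  geneIds <- sprintf("g%04d", seq_len(nGeneBg))
  regions <- GRanges(
    factor(c(rep("chr1", nGeneBg), "chr2"), levels = c("chr1", "chr2")),
    IRanges(c(startPos, 9500L), c(endPos, 50000L + 200L * k + 500L)),
    region_id = c(geneIds, "G_BLOCK"),
    region_class = "gene")
  causalGene <- geneIds[ceiling(nGeneBg / 2)]

  classes <- data.frame(
    variant_id = vids,
    class = sample(c("exonic", "non_exonic"), nV, replace = TRUE,
                   prob = c(0.15, 0.85)),
    stringsAsFactors = FALSE)
  classes$transmembrane_nonsyn <-
    as.integer(classes$class == "exonic" & stats::runif(nV) < 0.3)

  # pair-level mismatch scores drive the hazard (closed loop with the
  # package's own mismatch rule)
  vorder <- order(variants)
  D <- donorCalls[, vorder, drop = FALSE]
  R <- recipCalls[, vorder, drop = FALSE]
  codes <- ifelse(R == 1L, 0L, ifelse(R == 0L, D, -(2L - D)))
  anyInd <- codes != 0L
  gwRaw <- rowSums(anyInd)
  gwIqr <- .iqr(gwRaw)
  gwNorm <- if (gwIqr > 0) gwRaw / gwIqr else gwRaw
  sortedIds <- vids[vorder]
  causalVids <- vids[seq_len(nB)][grp == match(causalGene, geneIds)]
  causalCols <- which(sortedIds %in% causalVids)
  # the causal gene's hazard loads on the alien-allele count (a double
  # mismatch introduces two alien alleles, i.e. twice the antigenic dose)
  geneRaw <- rowSums(abs(codes[, causalCols, drop = FALSE]))

  direction <- classifyDirection(donorDosage, recipDosage,
                                 donorTag, recipTag, riskAllele = "ALT")
  h <- config@hazard
  eta <- h$betaGw * (gwNorm - mean(gwNorm)) +
    h$betaGene * (geneRaw - mean(geneRaw)) +
    h$betaMinor * (direction == "MINOR_INTRODUCING") +
    h$betaTag * (direction == "TAG_RISK")
  surv <- simulateSurvival(eta, h$eventRate, h$horizon)

  pairs <- data.frame(
    pair_id = sprintf("P%04d", seq_len(nP)),
    donor_id = donorIds, recipient_id = recipIds,
    follow_time = pmax(0.1, round(surv$time, 1)), event = surv$event,
    hla_mismatch = pmin(stats::rpois(nP, 3), 6L),
    donor_status = donorStatus,
    induction = sample(c("depleting", "nondepleting"), nP, replace = TRUE),
    donor_ancestry = donorAnc, recipient_ancestry = recipAnc,
    stringsAsFactors = FALSE)
  cohort <- PairCohort(pairs)

  e <- config@eqtl
  nE <- min(e$nSamples, nP)
  exprDosage <- stats::setNames(recipDosage[seq_len(nE)],
                                recipIds[seq_len(nE)])
  exprCov <- data.frame(
    age = round(stats::rnorm(nE, 45, 12)),
    sex = sample(c("F", "M"), nE, replace = TRUE),
    ancestry = recipAnc[seq_len(nE)])
  expression <- simulateExpression(exprDosage, e, covariates = exprCov)

  truth <- list(
    relClass = relClass, ibdFraction = ibdFraction,
    donorDosage = donorDosage, recipientDosage = recipDosage,
    donorTag = donorTag, recipientTag = recipTag,
    direction = direction,
    blockMembers = sprintf("blk%02d", seq_len(k)),
    blockMinorAllele = ifelse(orientAlt, "ALT", "REF"),
    tagVariant = "tagSNP", riskAllele = "ALT",
    causalGene = causalGene, eta = eta, lambda0 = surv$lambda0,
    gwRaw = gwRaw, gwNorm = gwNorm, causalGeneRaw = geneRaw,
    betas = h, eqtl = e,
    expressionDosage = exprDosage)

  list(genotypes = genotypes, cohort = cohort, regions = regions,
       classes = classes, frequencies = fr, expression = expression,
       truth = truth)
}

.gtStrings <- c("0/0", "0/1", "1/1")

#' Emit a synthetic cohort to pipeline input files
#'
#' Writes the full set of pipeline inputs — genotypes as VCF 4.2 (GT
#' field, biallelic SNVs, INFO imputation score), the pair table as
#' TSV, gene annotation as BED, the variant functional-class table, the
#' expression matrix and its covariates, and the ground-truth tables
#' used only by recovery tests. Output is byte-identical across runs
#' with the same config (no timestamps, fixed formatting).
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of file paths; the in-memory cohort
#'   is attached as attribute \code{"cohort"}.
#' @export
emitCohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateCohort(config)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    pairs = file.path(dir, "pairs.tsv"),
    regions = file.path(dir, "regions.bed"),
    classes = file.path(dir, "classes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    expression_covariates = file.path(dir, "expression_covariates.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_block = file.path(dir, "truth_block.tsv"),
    config = file.path(dir, "cohort_config.yaml"))

  g <- sim$genotypes
  v <- variantRanges(g)
  cl <- genotypeCalls(g)
  gt <- matrix(.gtStrings[cl + 1L], nrow(cl), ncol(cl))
  gt[is.na(cl)] <- "./."
  body <- paste(as.character(seqnames(v)), start(v),
                mcols(v)$variant_id, mcols(v)$ref, mcols(v)$alt,
                ".", "PASS",
                sprintf("INFO=%.3f", mcols(v)$info_score), "GT",
                apply(t(gt), 1, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sampleIds(g)), collapse = "\t"))
  writeLines(c(header, body), paths$vcf)

  writePairs(sim$cohort, paths$pairs)
  writeRegions(sim$regions, paths$regions)
  utils::write.table(sim$classes, paths$classes, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  expr <- sim$expression$expr
  utils::write.table(
    data.frame(gene = rownames(expr), round(expr, 6),
               check.names = FALSE),
    paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    cbind(data.frame(sample_id = colnames(expr)),
          sim$expression$covariates),
    paths$expression_covariates, sep = "\t", quote = FALSE,
    row.names = FALSE)

  tr <- sim$truth
  utils::write.table(
    data.frame(pair_id = pairIds(sim$cohort),
               rel_class = tr$relClass,
               ibd_fraction = round(tr$ibdFraction, 6),
               donor_dosage = tr$donorDosage,
               recipient_dosage = tr$recipientDosage,
               donor_tag = tr$donorTag, recipient_tag = tr$recipientTag,
               direction = as.character(tr$direction),
               gw_raw = tr$gwRaw,
               causal_gene_raw = tr$causalGeneRaw),
    paths$truth_pairs, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(variant_id = tr$blockMembers,
               minor_allele = tr$blockMinorAllele),
    paths$truth_block, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(cohortConfigAsList(config), paths$config)
  attr(paths, "cohort") <- sim
  invisible(paths)
}

#' Serialize / restore a CohortConfig
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return a plain list (YAML-serializable).
#' @export
cohortConfigAsList <- function(config) {
  # yaml drops names on atomic vectors; store named vectors as maps
  mapify <- function(x) {
    if (is.list(x)) lapply(x, mapify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  mapify(list(nPairs = config@nPairs, nVariants = config@nVariants,
              nGenes = config@nGenes, ancestry = config@ancestry,
              relatedness = config@relatedness, block = config@block,
              tag = config@tag, hazard = config@hazard,
              eqtl = config@eqtl, seed = config@seed))
}

#' @rdname cohortConfigAsList
#' @param x a list as produced by [cohortConfigAsList()] (e.g. read
#'   back from YAML); missing entries take the defaults.
#' @export
cohortConfigFromList <- function(x) {
  args <- x[intersect(names(x), names(formals(cohortConfig)))]
  for (nm in c("ancestry", "relatedness", "block", "tag", "hazard", "eqtl"))
    if (!is.null(args[[nm]]))
      args[[nm]] <- lapply(args[[nm]], function(e)
        if (is.list(e)) unlist(e) else e)
  do.call(cohortConfig, args)
}
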