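#' @include accessors.R
NULL

# Signed mismatch code from donor/recipient ALT counts; see MismatchTable.
# A mismatch exists iff the donor carries an allele absent from the
# recipient; a heterozygous recipient carries both alleles, so never
# receives an alien allele.
.mismatchCode <- function(donor, recipient) {
  ok <- is.na(donor) | donor %in% 0:2
  if (!all(ok)) stop("donor genotype out of range {0,1,2,NA}")
  ok <- is.na(recipient) | recipient %in% 0:2
  if (!all(ok)) stop("recipient genotype out of range {0,1,2,NA}")
  code <- ifelse(recipient == 1L, 0L,
                 ifelse(recipient == 0L, as.integer(donor),
                        -(2L - as.integer(donor))))
  code[is.na(donor) | is.na(recipient)] <- NA_integer_
  code
}

#' Variant-level donor-recipient mismatch call
#'
#' Classifies a donor/recipient genotype pair at one biallelic variant.
#' A mismatch is a donor carrying an allele not present in the
#' recipient; the category counts the "alien" allele copies the donor
#' would introduce: SINGLE (1 copy), DOUBLE (2 copies), NONE, or
#' MISSING when either genotype is missing. A heterozygous recipient
#' carries both alleles, so the call is always NONE.
#'
#' @param donor,recipient ALT-allele counts in {0,1,2} or NA; vectors
#'   are recycled to equal length.
#' @return data.frame with columns \code{category} (NONE / SINGLE /
#'   DOUBLE / MISSING), \code{n_introduced} (0/1/2) and
#'   \code{introduced_allele} ("REF"/"ALT"/"none").
#' @examples
#' variantMismatch(1, 0)  # SINGLE, ALT introduced
#' variantMismatch(0, 2)  # DOUBLE, REF introduced
#' variantMismatch(2, 1)  # NONE
#' @export
variantMismatch <- function(donor, recipient) {
  n <- max(length(donor), length(recipient))
  donor <- rep_len(donor, n)
  recipient <- rep_len(recipient, n)
  code <- .mismatchCode(donor, recipient)
  category <- ifelse(is.na(code), "MISSING",
                     c("NONE", "SINGLE", "DOUBLE")[abs(code) + 1L])
  data.frame(
    category = category,
    n_introduced = ifelse(is.na(code), NA_integer_, abs(code)),
    introduced_allele = ifelse(is.na(code), NA_character_,
                               ifelse(code > 0L, "ALT",
                                      ifelse(code < 0L, "REF", "none"))),
    stringsAsFactors = FALSE)
}

#' Build the per-pair, per-variant mismatch table
#'
#' Applies the variant-level mismatch rule elementwise over all pairs
#' and variants of a genotype matrix; missing genotypes propagate to
#' MISSING calls.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param cohort a \linkS4class{PairCohort}; every donor and recipient
#'   id must be a sample of \code{x}.
#' @return a \linkS4class{MismatchTable} (pairs x variants).
#' @export
buildMismatchTable <- function(x, cohort) {
  p <- pairData(cohort)
  ids <- sampleIds(x)
  missing <- setdiff(c(p$donor_id, p$recipient_id), ids)
  if (length(missing))
    stop("sample id(s) not in genotype matrix: ",
         paste(utils::head(missing, 10), collapse = ", "))
  cl <- genotypeCalls(x)
  D <- cl[match(p$donor_id, ids), , drop = FALSE]
  R <- cl[match(p$recipient_id, ids), , drop = FALSE]
  codes <- ifelse(R == 1L, 0L, ifelse(R == 0L, D, -(2L - D)))
  codes[is.na(D) | is.na(R)] <- NA_integer_
  dimnames(codes) <- list(p$pair_id, variantIds(x))
  new("MismatchTable", codes = codes, variants = variantRanges(x),
      pairIds = p$pair_id)
}

#' Filter variants by mismatch frequency
#'
#' The gene- and variant-level screens are restricted to variants whose
#' any-mismatch frequency across pairs (with non-missing calls) is at
#' least \code{minFreq}; variants mismatched in fewer pairs are treated
#' as too rare to score.
#'
#' @param table a \linkS4class{MismatchTable}.
#' @param minFreq frequency threshold in [0,1] (default 0.05). A variant
#'   at exactly the threshold is kept.
#' @return list with \code{variant_ids} (kept) and \code{frequencies}
#'   (data.frame variant_id, mismatch_freq, n_informative for all
#'   variants).
#' @export
mismatchFrequencyFilter <- function(table, minFreq = 0.05) {
  if (minFreq < 0 || minFreq > 1) stop("minFreq must be in [0,1]")
  any <- anyMismatch(table)
  freq <- colMeans(any, na.rm = TRUE)
  freq[is.nan(freq)] <- 0
  nInf <- colSums(!is.na(any))
  tab <- data.frame(variant_id = variantIds(table),
                    mismatch_freq = unname(freq),
                    n_informative = unname(nInf),
                    stringsAsFactors = FALSE)
  list(variant_ids = tab$variant_id[tab$mismatch_freq >= minFreq],
       frequencies = tab)
}

.iqr <- function(x, type = 7) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = type,
                       names = FALSE)
  q[2] - q[1]
}

.indicatorMatrix <- function(table, mode = c("any", "double")) {
  mode <- match.arg(mode)
  if (mode == "any") anyMismatch(table) else doubleMismatch(table)
}

.scoreTable <- function(raw, pairIds, scale, mode, iqrType = 7,
                        errorOnZeroIqr = FALSE) {
  iqr <- .iqr(raw, type = iqrType)
  if (iqr <= 0) {
    if (errorOnZeroIqr)
      stop("IQR of raw ", scale, " scores is zero; normalization is ",
           "undefined. Check that pairs are genetically distinct, or ",
           "work with raw scores.")
    normalized <- rep(NA_real_, length(raw))
    iqr <- NA_real_
  } else {
    normalized <- raw / iqr
  }
  new("ScoreTable",
      scores = data.frame(pair_id = pairIds, raw = raw,
                          normalized = normalized,
                          stringsAsFactors = FALSE),
      scale = scale, mode = mode, iqr = iqr)
}

# pairs x regions raw score matrix via sparse variant-region membership;
# variants in overlapping regions count in each region.
.regionRawMatrix <- function(table, regions, mode = "any") {
  ind <- .indicatorMatrix(table, mode)
  ind[is.na(ind)] <- FALSE
  hits <- GenomicRanges::findOverlaps(variantRanges(table), regions,
                                      ignore.strand = TRUE)
  M <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                            j = S4Vectors::subjectHits(hits),
                            x = 1,
                            dims = c(ncol(ind), length(regions)))
  raw <- as.matrix(ind %*% M)
  dimnames(raw) <- list(pairIds(table), mcols(regions)$region_id)
  raw
}

#' Gene/region-level mismatch scores
#'
#' For each annotated region, sums the chosen mismatch indicator (0 for
#' absence, 1 for presence) over the variants whose position falls in
#' the region, per pair; missing calls are skipped. Variants inside
#' overlapping regions count in every region containing them. Each
#' region score is also IQR-normalized across pairs; regions with zero
#' IQR (including regions with no mapped variants, which raise a
#' warning) get NA normalized scores.
#'
#' @param table a \linkS4class{MismatchTable}.
#' @param regions \code{GRanges} with a \code{region_id} column.
#' @param mode "any" (default) or "double" mismatch indicator.
#' @param iqrType quantile type for the IQR (default 7,
#'   linear interpolation).
#' @return list with \code{raw} (pairs x regions integer matrix),
#'   \code{normalized} (same shape, NA where IQR is 0), \code{iqr}
#'   (named per-region vector), and \code{mode}.
#' @export
regionScore <- function(table, regions, mode = c("any", "double"),
                        iqrType = 7) {
  mode <- match.arg(mode)
  if (length(regions) == 0L) stop("regions must be non-empty")
  raw <- .regionRawMatrix(table, regions, mode)
  empty <- colSums(raw) == 0 &
    S4Vectors::countQueryHits(GenomicRanges::findOverlaps(
      regions, variantRanges(table), ignore.strand = TRUE)) == 0
  if (any(empty))
    warning(sum(empty), " region(s) contain no variants: ",
            paste(utils::head(colnames(raw)[empty], 5), collapse = ", "))
  iqr <- apply(raw, 2, .iqr, type = iqrType)
  normalized <- sweep(raw, 2, ifelse(iqr > 0, iqr, NA_real_), "/")
  list(raw = raw, normalized = normalized, iqr = iqr, mode = mode)
}

#' Extract one region's ScoreTable from regionScore() output
#' @param regionScores result of [regionScore()].
#' @param regionId region to extract.
#' @return a \linkS4class{ScoreTable}.
#' @export
asScoreTable <- function(regionScores, regionId) {
  if (!regionId %in% colnames(regionScores$raw))
    stop("unknown region: ", regionId)
  raw <- regionScores$raw[, regionId]
  .scoreTable(unname(raw), names(raw), paste0("gene:", regionId),
              regionScores$mode)
}

#' Genome-wide mismatch score
#'
#' Sums the variant-level any-mismatch indicator (0 match, 1 mismatch)
#' over all variants outside the exclusion regions, per pair, and
#' normalizes the raw counts by their interquartile range across pairs.
#' No mismatch-frequency filter is applied at this scale: the genome-wide
#' score uses every QC-passing variant, while the gene- and
#' variant-level screens use the frequency-filtered subset.
#'
#' @param table a \linkS4class{MismatchTable} (built from QC-passing
#'   variants; the MHC is normally already excluded by QC).
#' @param exclude optional \code{GRanges} of regions to exclude.
#' @param mode "any" (default) or "double".
#' @param rescaleMissing if TRUE, rescale each pair's raw score by
#'   n_total / n_nonmissing to compensate for missing calls (off by
#'   default; missing calls are simply skipped).
#' @param iqrType quantile type for the IQR (default 7).
#' @return a \linkS4class{ScoreTable} with scale "genome_wide". Errors
#'   if the IQR of raw scores is zero.
#' @export
genomeWideScore <- function(table, exclude = NULL, mode = "any",
                            rescaleMissing = FALSE, iqrType = 7) {
  ind <- .indicatorMatrix(table, mode)
  if (!is.null(exclude) && length(exclude)) {
    drop <- IRanges::overlapsAny(variantRanges(table), exclude,
                                 ignore.strand = TRUE)
    ind <- ind[, !drop, drop = FALSE]
  }
  raw <- rowSums(ind, na.rm = TRUE)
  if (rescaleMissing) {
    nonmiss <- rowSums(!is.na(ind))
    raw <- raw * ncol(ind) / pmax(nonmiss, 1L)
  }
  .scoreTable(unname(raw), pairIds(table), "genome_wide", mode,
              iqrType = iqrType, errorOnZeroIqr = TRUE)
}

#' Mismatch scores by variant functional class
#'
#' Computes the genome-wide-style score restricted to each functional
#' class of variants (e.g. exonic vs non-exonic vs transmembrane
#' nonsynonymous), plus the pairwise Pearson correlations between the
#' class raw scores.
#'
#' @param table a \linkS4class{MismatchTable}.
#' @param classes data.frame with columns \code{variant_id} and
#'   \code{class}; every class label used must appear here.
#' @param which class labels to score (default: all labels present).
#' @param mode "any" or "double".
#' @return list with \code{scores} (named list of
#'   \linkS4class{ScoreTable}; degenerate classes with zero IQR get NA
#'   normalized scores and a warning) and \code{correlation} (class
#'   correlation matrix of raw scores).
#' @export
classScores <- function(table, classes, which = NULL, mode = "any") {
  if (is.null(which)) which <- sort(unique(classes$class))
  unknown <- setdiff(which, unique(classes$class))
  if (length(unknown))
    stop("unknown class label(s): ", paste(unknown, collapse = ", "))
  ind <- .indicatorMatrix(table, mode)
  vids <- variantIds(table)
  scores <- list()
  rawMat <- NULL
  for (cls in which) {
    sel <- vids %in% classes$variant_id[classes$class == cls]
    raw <- rowSums(ind[, sel, drop = FALSE], na.rm = TRUE)
    if (sum(sel) == 0L)
      warning("class '", cls, "' matches no variants")
    scores[[cls]] <- .scoreTable(unname(raw), pairIds(table),
                                 paste0("class:", cls), mode)
    rawMat <- cbind(rawMat, raw)
  }
  colnames(rawMat) <- which
  corr <- if (length(which) > 1L) stats::cor(rawMat) else
    matrix(1, 1, 1, dimnames = list(which, which))
  list(scores = scores, correlation = corr)
}

#' Method-of-moments identity-by-descent estimate for one pair
#'
#' Estimates pi-hat = P(IBD=1)/2 + P(IBD=2) for a pair of individuals
#' from their genotypes and cohort ALT-allele frequencies, by the
#' classical method of moments on identity-by-state counts. Restricted
#' to common variants (MAF >= \code{minMaf}) with both genotypes
#' non-missing; the estimate is truncated to [0,1].
#'
#' @param gtI,gtJ aligned ALT-count genotype vectors for the two
#'   individuals.
#' @param alleleFreqs per-variant ALT frequency in (0,1), aligned with
#'   the genotype vectors.
#' @param minMaf MAF restriction (default 0.05).
#' @return pi-hat in [0,1], with attributes \code{k0}, \code{k1},
#'   \code{k2} (IBD-state proportions), \code{n_sites}, and
#'   \code{low_information} (TRUE, with a warning, when fewer than 100
#'   informative sites were available).
#' @export
estimatePibd <- function(gtI, gtJ, alleleFreqs, minMaf = 0.05) {
  stopifnot(length(gtI) == length(gtJ),
            length(alleleFreqs) == length(gtI))
  use <- !is.na(gtI) & !is.na(gtJ) &
    pmin(alleleFreqs, 1 - alleleFreqs) >= minMaf &
    alleleFreqs > 0 & alleleFreqs < 1
  p <- alleleFreqs[use]
  q <- 1 - p
  a <- gtI[use]
  b <- gtJ[use]
  nSites <- length(a)
  low <- nSites < 100L
  if (low) warning("fewer than 100 informative sites; pi-hat unreliable")
  # IBS state per site: 0 = opposite homozygotes, 2 = identical genotypes
  ibs <- ifelse(abs(a - b) == 2L, 0L, ifelse(a == b, 2L, 1L))
  nIbs <- tabulate(ibs + 1L, nbins = 3L)
  # expected IBS-state probabilities given IBD state, summed over sites
  e0g0 <- sum(2 * p^2 * q^2)
  e1g0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2g0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1g1 <- sum(2 * p * q)
  e2g1 <- sum(p^2 + q^2)
  k0 <- nIbs[1] / e0g0
  k1 <- (nIbs[2] - k0 * e1g0) / e1g1
  k2 <- (nIbs[3] - k0 * e2g0 - k1 * e2g1) / nSites
  k <- pmax(c(k0, k1, k2), 0)
  k <- k / sum(k)
  pihat <- min(1, max(0, k[2] / 2 + k[3]))
  attributes(pihat) <- list(k0 = k[1], k1 = k[2], k2 = k[3],
                            n_sites = nSites, low_information = low)
  pihat
}

#' Write a ScoreTable as TSV
#' @param score a \linkS4class{ScoreTable}.
#' @param path output path.
#' @export
writeScoreTable <- function(score, path) {
  utils::write.table(scoreData(score), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
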