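#' @include accessors.R
NULL

#' Two-locus linkage disequilibrium from unphased genotypes
#'
#' Estimates the four two-locus haplotype frequencies by EM from
#' unphased diploid genotypes (only double heterozygotes are
#' phase-ambiguous) and derives r-squared = D^2 / (pA qA pB qB). The EM
#' iterates until the largest haplotype-frequency change is below 1e-10
#' or 1000 iterations.
#'
#' @param gtA,gtB aligned ALT-count genotype vectors; pairwise-complete
#'   samples are used.
#' @return list with \code{r2}, \code{d} (the disequilibrium
#'   coefficient for the ALT/ALT haplotype), \code{hapFreqs} (named
#'   frequencies of AB, Ab, aB, ab where A/B denote ALT at each locus),
#'   \code{n} (samples used), and \code{iterations}.
#' @examples
#' a <- c(0, 1, 2, 1, 0, 2)
#' pairwiseR2(a, a)$r2   # identical loci: 1
#' @export
pairwiseR2 <- function(gtA, gtB) {
  stopifnot(length(gtA) == length(gtB))
  use <- !is.na(gtA) & !is.na(gtB)
  a <- gtA[use]
  b <- gtB[use]
  n <- length(a)
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    stop("LD undefined: monomorphic locus among pairwise-complete samples")
  # haplotype counts are fixed for every genotype pair except the double
  # heterozygote; h indexed AB, Ab, aB, ab (A/B = ALT at locus 1/2)
  dh <- a == 1L & b == 1L
  nDh <- sum(dh)
  au <- a[!dh]; bu <- b[!dh]
  cnt <- c(sum(pmax(au + bu - 2L, 0L)),   # AB
           sum(pmax(au - bu, 0L)),        # Ab
           sum(pmax(bu - au, 0L)),        # aB
           sum(pmax(2L - au - bu, 0L)))   # ab
  f <- rep(0.25, 4)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    den <- f[1] * f[4] + f[2] * f[3]
    w <- if (den > 0) f[1] * f[4] / den else 0.5
    newCnt <- cnt + nDh * c(w, 1 - w, 1 - w, w)
    fNew <- newCnt / (2 * n)
    if (max(abs(fNew - f)) < 1e-10 || iter >= 1000L) {
      f <- fNew
      break
    }
    f <- fNew
  }
  names(f) <- c("AB", "Ab", "aB", "ab")
  pA <- f[1] + f[2]
  pB <- f[1] + f[3]
  d <- f[1] - pA * pB
  r2 <- unname(d^2 / (pA * (1 - pA) * pB * (1 - pB)))
  list(r2 = r2, d = unname(d), hapFreqs = f, n = n, iterations = iter)
}

.r2Matrix <- function(cl, ids) {
  k <- ncol(cl)
  m <- diag(1, k)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      m[i, j] <- m[j, i] <- pairwiseR2(cl[, i], cl[, j])$r2
    }
  }
  m
}

#' Build an LD-defined haplotype block
#'
#' From a set of candidate (seed) variants, retains the maximal subset
#' whose pairwise r-squared all meet \code{r2In}, by greedy removal:
#' while any pair falls below the threshold, the member with the fewest
#' partners at or above the threshold is dropped (ties broken by genomic
#' position, earliest kept). Every retained member must have r-squared
#' below \code{r2Out} with the tag variant, or the function errors
#' listing the offenders — the block is by construction a haplotype
#' distinct from the tag SNP's.
#'
#' The minor haplotype is the orientation with cohort frequency below
#' 0.5 (ties resolved toward the ALT-bearing haplotype of the first
#' member); each member records which of its alleles rides on it.
#'
#' @param x a \linkS4class{GenotypeMatrix} (post-QC).
#' @param seedVariants candidate variant ids present in \code{x}.
#' @param r2In within-block r-squared threshold (default 0.99).
#' @param tagVariant optional id of the tag SNP the block must be
#'   unlinked from.
#' @param r2Out maximum allowed r-squared to the tag (default 0.5).
#' @return a \linkS4class{HaplotypeBlock} with per-sample dosages.
#' @export
buildBlock <- function(x, seedVariants, r2In = 0.99, tagVariant = NULL,
                       r2Out = 0.5) {
  vids <- variantIds(x)
  missing <- setdiff(seedVariants, vids)
  if (length(missing))
    stop("seed variant(s) absent (removed by QC?): ",
         paste(missing, collapse = ", "))
  seeds <- vids[vids %in% seedVariants]  # genomic order
  cl <- genotypeCalls(x)[, seeds, drop = FALSE]
  if (length(seeds) > 1L) {
    r2 <- .r2Matrix(cl, seeds)
    keep <- seeds
    while (length(keep) > 1L) {
      sub <- r2[keep, keep, drop = FALSE]
      off <- sub[upper.tri(sub)]
      if (all(off >= r2In)) break
      conn <- rowSums(sub >= r2In) - 1L
      worst <- which(conn == min(conn))
      drop <- keep[worst[length(worst)]]  # ties: latest position removed
      keep <- setdiff(keep, drop)
    }
  } else {
    r2 <- matrix(1, 1, 1, dimnames = list(seeds, seeds))
    keep <- seeds
  }
  cl <- cl[, keep, drop = FALSE]

  if (!is.null(tagVariant)) {
    if (!tagVariant %in% vids)
      stop("tag variant not found: ", tagVariant)
    tagGt <- genotypeCalls(x)[, tagVariant]
    tagR2 <- vapply(keep, function(v) pairwiseR2(cl[, v], tagGt)$r2,
                    numeric(1))
    bad <- keep[tagR2 >= r2Out]
    if (length(bad))
      stop("block member(s) linked to tag variant (r2 >= ", r2Out, "): ",
           paste(bad, collapse = ", "))
  }

  # orient members onto a common haplotype using the sign of D vs the
  # first member, then pick the rarer orientation as the minor haplotype
  # (ties resolved toward the first member's ALT allele)
  ref <- keep[1L]
  altWithRefAlt <- vapply(keep, function(v) {
    if (v == ref) return(TRUE)
    pairwiseR2(cl[, ref], cl[, v])$d >= 0
  }, logical(1))
  aligned <- stats::setNames(ifelse(altWithRefAlt, "ALT", "REF"), keep)
  alignedCounts <- .minorCountMatrix(cl, aligned)
  hapFreq <- mean(colMeans(alignedCounts, na.rm = TRUE) / 2)
  if (hapFreq > 0.5) {
    minorAllele <- stats::setNames(ifelse(aligned == "ALT", "REF", "ALT"),
                                   keep)
    minorHapFreq <- 1 - hapFreq
    minorCounts <- 2L - alignedCounts
  } else {
    minorAllele <- aligned
    minorHapFreq <- hapFreq
    minorCounts <- alignedCounts
  }

  dos <- .majorityDosage(minorCounts)
  new("HaplotypeBlock", members = keep, minorAllele = unname(minorAllele),
      dosage = dos$dosage, discordance = dos$discordance,
      r2 = r2[keep, keep, drop = FALSE],
      tagVariant = if (is.null(tagVariant)) "" else tagVariant,
      minorHapFreq = minorHapFreq)
}

# samples x members matrix of minor-haplotype allele counts
.minorCountMatrix <- function(cl, minorAllele) {
  flip <- minorAllele[colnames(cl)] == "REF"
  counts <- cl
  counts[, flip] <- 2L - counts[, flip, drop = FALSE]
  counts
}

.majorityDosage <- function(counts) {
  k <- ncol(counts)
  v0 <- rowSums(counts == 0L, na.rm = TRUE)
  v1 <- rowSums(counts == 1L, na.rm = TRUE)
  v2 <- rowSums(counts == 2L, na.rm = TRUE)
  nm <- v0 + v1 + v2
  votes <- cbind(v0, v1, v2)
  maj <- votes[cbind(seq_len(nrow(votes)),
                     max.col(votes, ties.method = "first"))]
  callable <- nm >= k / 2 & maj > nm / 2
  dosage <- as.integer(ifelse(callable,
                              max.col(votes, ties.method = "first") - 1L,
                              NA_integer_))
  discordance <- ifelse(callable, (nm - maj) / nm, NA_real_)
  names(dosage) <- names(discordance) <- rownames(counts)
  list(dosage = dosage, discordance = discordance)
}

#' Per-sample haplotype dosage by majority vote
#'
#' Calls each sample's minor-haplotype allele dosage in {0,1,2} as the
#' strict majority of the minor-allele counts across the block's
#' non-missing member SNPs. A sample with more than half of the members
#' missing, or with no strict majority (e.g. a perfect tie), is called
#' MISSING (NA). The discordance rate is the fraction of non-missing
#' members disagreeing with the call.
#'
#' @param block a \linkS4class{HaplotypeBlock}.
#' @param x a \linkS4class{GenotypeMatrix} containing the block members
#'   (defaults to the dosages stored at build time when NULL).
#' @return list with \code{dosage} (named integer, NA = missing) and
#'   \code{discordance} (named numeric).
#' @export
haplotypeDosage <- function(block, x = NULL) {
  if (is.null(x))
    return(list(dosage = block@dosage, discordance = block@discordance))
  cl <- genotypeCalls(x)[, blockMembers(block), drop = FALSE]
  minorAllele <- stats::setNames(block@minorAllele, blockMembers(block))
  .majorityDosage(.minorCountMatrix(cl, minorAllele))
}

#' Haplotype mismatch dosage and direction
#'
#' Treats the haplotype block as a single biallelic locus (minor vs
#' major haplotype allele) and applies the variant-level containment
#' rule to the donor and recipient dosages: the result is the number of
#' "alien" haplotype alleles the donor introduces (0, 1, 2) and which
#' allele is introduced. A block of one member reduces exactly to the
#' variant-level mismatch call.
#'
#' @param donorDosage,recipientDosage minor-haplotype dosages in
#'   {0,1,2}; vectors are recycled.
#' @return data.frame with columns \code{n_alien} and \code{direction}
#'   ("minor", "major", or "none").
#' @examples
#' haplotypeMismatch(1, 0)  # one minor allele introduced
#' haplotypeMismatch(0, 2)  # two major alleles introduced
#' @export
haplotypeMismatch <- function(donorDosage, recipientDosage) {
  n <- max(length(donorDosage), length(recipientDosage))
  d <- rep_len(donorDosage, n)
  r <- rep_len(recipientDosage, n)
  code <- .mismatchCode(d, r)
  data.frame(
    n_alien = abs(code),
    direction = ifelse(is.na(code), NA_character_,
                       ifelse(code > 0L, "minor",
                              ifelse(code < 0L, "major", "none"))),
    stringsAsFactors = FALSE)
}

#' Tag-SNP risk mismatch
#'
#' TRUE iff the recipient is homozygous for the non-risk allele and the
#' donor carries at least one risk allele (the rs893403-style pattern:
#' risk allele introduced by the donor into a recipient homozygous for
#' the other allele).
#'
#' @param donorGt,recipientGt ALT-count genotypes; vectors recycled.
#' @param riskAllele "ALT" (default) or "REF": which allele is the risk
#'   allele.
#' @return logical vector (NA where a genotype is missing).
#' @export
tagRiskMismatch <- function(donorGt, recipientGt, riskAllele = c("ALT", "REF")) {
  riskAllele <- match.arg(riskAllele)
  n <- max(length(donorGt), length(recipientGt))
  d <- rep_len(donorGt, n)
  r <- rep_len(recipientGt, n)
  dRisk <- if (riskAllele == "ALT") d else 2L - d
  rRisk <- if (riskAllele == "ALT") r else 2L - r
  rRisk == 0L & dRisk >= 1L
}

#' Classify pair-level mismatch directionality
#'
#' Assigns each donor-recipient pair to exactly one direction class:
#' \describe{
#'   \item{TAG_RISK}{tag-SNP risk mismatch present — takes precedence
#'     regardless of the haplotype mismatch status, so that the tag-risk
#'     group is analyzed apart;}
#'   \item{MINOR_INTRODUCING}{donor introduces the minor haplotype
#'     allele to a recipient homozygous for the major allele;}
#'   \item{MAJOR_INTRODUCING}{donor introduces the major haplotype
#'     allele to a recipient homozygous for the minor allele;}
#'   \item{OTHER}{no tag-risk mismatch and no haplotype mismatch.}
#' }
#'
#' @param donorDosage,recipientDosage minor-haplotype dosages {0,1,2}.
#' @param donorTagGt,recipientTagGt tag-SNP ALT-count genotypes.
#' @param riskAllele tag risk allele, "ALT" (default) or "REF".
#' @return factor with levels TAG_RISK, MINOR_INTRODUCING,
#'   MAJOR_INTRODUCING, OTHER; NA where any input is missing (such pairs
#'   are excluded from direction analyses).
#' @export
classifyDirection <- function(donorDosage, recipientDosage,
                              donorTagGt, recipientTagGt,
                              riskAllele = c("ALT", "REF")) {
  riskAllele <- match.arg(riskAllele)
  n <- max(length(donorDosage), length(recipientDosage),
           length(donorTagGt), length(recipientTagGt))
  dd <- rep_len(donorDosage, n)
  rd <- rep_len(recipientDosage, n)
  tagRisk <- tagRiskMismatch(rep_len(donorTagGt, n),
                             rep_len(recipientTagGt, n), riskAllele)
  hm <- haplotypeMismatch(dd, rd)
  lab <- ifelse(is.na(tagRisk) | is.na(hm$direction), NA_character_,
         ifelse(tagRisk, "TAG_RISK",
         ifelse(hm$direction == "minor", "MINOR_INTRODUCING",
         ifelse(hm$direction == "major", "MAJOR_INTRODUCING", "OTHER"))))
  factor(lab, levels = c("TAG_RISK", "MINOR_INTRODUCING",
                         "MAJOR_INTRODUCING", "OTHER"))
}

#' Write a haplotype block definition as TSV
#' @param block a \linkS4class{HaplotypeBlock}.
#' @param path output path.
#' @export
writeBlock <- function(block, path) {
  utils::write.table(
    data.frame(variant_id = blockMembers(block),
               minor_allele = block@minorAllele),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
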