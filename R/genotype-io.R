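#' @include accessors.R
NULL

#' Quality-control configuration
#'
#' Builds a \linkS4class{QCConfig} holding the thresholds of the imputed
#' genotype QC: imputation INFO score, per-variant missing rate, minor
#' allele frequency, Hardy-Weinberg exact-test p-value, the MHC exclusion
#' interval (hg19 chr6:28866528-33775446 by default), the genotype
#' posterior used for masking at read time, and the mismatch-frequency
#' threshold used by the gene- and variant-level screens.
#'
#' @param maxMissingRate,minMaf,minHweP,minInfo,minPosterior,minMismatchFreq
#'   numeric thresholds; see \linkS4class{QCConfig}.
#' @param mhcChrom,mhcStart,mhcEnd MHC interval (1-based inclusive).
#' @param hweSamples sample set the HWE test is computed on: "all"
#'   (default), "recipients", or "recipients_living_donors".
#' @return a validated \linkS4class{QCConfig}.
#' @export
qcConfig <- function(maxMissingRate = 0.05, minMaf = 0.01, minHweP = 1e-6,
                     minInfo = 0.4, minPosterior = 0.95,
                     mhcChrom = "chr6", mhcStart = 28866528,
                     mhcEnd = 33775446, minMismatchFreq = 0.05,
                     hweSamples = "all") {
  new("QCConfig", maxMissingRate = maxMissingRate, minMaf = minMaf,
      minHweP = minHweP, minInfo = minInfo, minPosterior = minPosterior,
      mhcChrom = mhcChrom, mhcStart = mhcStart, mhcEnd = mhcEnd,
      minMismatchFreq = minMismatchFreq, hweSamples = hweSamples)
}

.gt_lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                "0" = 0L, "1" = 1L,
                "./." = NA_integer_, "." = NA_integer_, "./1" = NA_integer_,
                "1/." = NA_integer_, "./0" = NA_integer_, "0/." = NA_integer_)

#' Read a VCF into a GenotypeMatrix
#'
#' Reads a VCF 4.x file of biallelic variants into a
#' \linkS4class{GenotypeMatrix}, coding genotypes as ALT-allele counts.
#' Multiallelic records are rejected (split them upstream, e.g. with
#' \code{bcftools norm}). If the file carries a GP (genotype posterior)
#' FORMAT field and \code{minPosterior} is given, genotypes whose maximum
#' posterior is below the threshold are set to missing; masking never
#' alters a retained genotype's value, only its missingness.
#'
#' An INFO key named \code{INFO}, \code{R2} or \code{DR2} (imputation
#' quality) is stored per variant as \code{info_score} when present.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param minPosterior posterior-probability masking threshold in [0,1],
#'   or NULL to skip masking even when GP is present.
#' @return a \linkS4class{GenotypeMatrix} with variants sorted by
#'   (chromosome, position).
#' @export
readGenotypeVcf <- function(path, minPosterior = NULL) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e)
      stop("failed to parse VCF '", path, "': ", conditionMessage(e),
           call. = FALSE))
  rr <- SummarizedExperiment::rowRanges(vcf)
  nalt <- lengths(rr$ALT)
  if (any(nalt != 1L)) {
    bad <- utils::head(names(rr)[nalt != 1L], 10L)
    stop("multiallelic record(s) not supported; split upstream: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  gtChar <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtChar)) stop("VCF has no GT field", call. = FALSE)
  gtChar <- gsub("|", "/", gtChar, fixed = TRUE)
  known <- gtChar %in% names(.gt_lookup)
  if (!all(known))
    stop("unsupported genotype string(s): ",
         paste(unique(gtChar[!known]), collapse = ", "), call. = FALSE)
  calls <- matrix(.gt_lookup[gtChar], nrow = nrow(gtChar),
                  dimnames = dimnames(gtChar))
  gp <- VariantAnnotation::geno(vcf)$GP
  if (!is.null(gp) && !is.null(minPosterior)) {
    maxgp <- apply(gp, c(1, 2), function(v) suppressWarnings(max(unlist(v))))
    calls[!is.na(maxgp) & maxgp < minPosterior] <- NA_integer_
  }
  ids <- names(rr)
  if (is.null(ids) || anyDuplicated(ids) || any(ids %in% c(".", "")))
    ids <- paste0(as.character(seqnames(rr)), ":", start(rr), "_",
                  as.character(rr$REF), "/",
                  vapply(rr$ALT, function(a) as.character(a[[1]]), ""))
  infoKeys <- intersect(c("INFO", "R2", "DR2"),
                        names(VariantAnnotation::info(vcf)))
  infoScore <- if (length(infoKeys))
    as.numeric(VariantAnnotation::info(vcf)[[infoKeys[1L]]])
  else rep(NA_real_, length(rr))
  gr <- GRanges(seqnames(rr), IRanges(start(rr), end(rr)),
                variant_id = ids,
                ref = as.character(rr$REF),
                alt = vapply(rr$ALT, function(a) as.character(a[[1]]), ""),
                info_score = infoScore)
  GenotypeMatrix(t(calls), gr)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of Hardy-Weinberg equilibrium from genotype
#' counts: conditional on the observed allele counts, the p-value is the
#' sum of probabilities of all heterozygote configurations no more
#' probable than the observed one.
#'
#' @param nHomRef,nHet,nHomAlt non-negative genotype counts.
#' @return exact p-value in (0, 1]; 1 for monomorphic input.
#' @examples
#' hweExactTest(50, 0, 0)   # monomorphic: 1
#' hweExactTest(0, 10, 0)   # all-heterozygote excess
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  counts <- c(nHomRef, nHet, nHomAlt)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("genotype counts must be non-negative")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  nAlt <- 2 * nHomAlt + nHet
  rare <- min(nAlt, 2 * n - nAlt)
  if (rare == 0) return(1)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  # P(h hets | allele counts) via log-factorials, normalized over hs
  logp <- hs * log(2) + lfactorial(n) -
    lfactorial((rare - hs) / 2) - lfactorial(hs) -
    lfactorial((2 * n - rare - hs) / 2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(nHet, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Apply variant quality control
#'
#' Filters a \linkS4class{GenotypeMatrix} by, in fixed order: imputation
#' INFO score, per-variant missing rate, monomorphism, minor allele
#' frequency, Hardy-Weinberg exact test, and MHC-interval exclusion.
#' Each removed variant is attributed to the first filter it fails, so
#' the report is deterministic and its counts reconcile
#' (input = surviving + sum(removed)).
#'
#' The HWE test is computed over all samples by default; pass a
#' \linkS4class{PairCohort} and set \code{hweSamples} in the config to
#' restrict it to recipients (optionally plus living donors).
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param config a \linkS4class{QCConfig}.
#' @param cohort optional \linkS4class{PairCohort}, required only when
#'   \code{config@hweSamples != "all"}.
#' @return list with elements \code{genotypes} (filtered
#'   \linkS4class{GenotypeMatrix}) and \code{report} (data.frame with
#'   columns \code{filter}, \code{removed}, plus attributes
#'   \code{n_input} and \code{n_surviving}).
#' @export
applyQC <- function(x, config = qcConfig(), cohort = NULL) {
  v <- variantRanges(x)
  cl <- genotypeCalls(x)
  nv <- length(v)

  hweIdx <- seq_len(nrow(cl))
  if (config@hweSamples != "all") {
    if (is.null(cohort))
      stop("cohort required when hweSamples != 'all'")
    p <- pairData(cohort)
    ids <- p$recipient_id
    if (config@hweSamples == "recipients_living_donors")
      ids <- c(ids, p$donor_id[p$donor_status == "living"])
    hweIdx <- which(rownames(cl) %in% ids)
  }

  nMiss <- colSums(is.na(cl))
  nTot <- nrow(cl)
  altFreq <- colMeans(cl, na.rm = TRUE) / 2
  altFreq[is.nan(altFreq)] <- 0

  info <- mcols(v)$info_score
  failInfo <- !is.na(info) & info < config@minInfo
  failMiss <- nMiss / nTot > config@maxMissingRate
  failMono <- altFreq == 0 | altFreq == 1
  failMaf <- pmin(altFreq, 1 - altFreq) < config@minMaf

  clH <- cl[hweIdx, , drop = FALSE]
  n0 <- colSums(clH == 0L, na.rm = TRUE)
  n1 <- colSums(clH == 1L, na.rm = TRUE)
  n2 <- colSums(clH == 2L, na.rm = TRUE)
  hweP <- vapply(seq_len(nv), function(j) {
    if (n0[j] + n1[j] + n2[j] == 0L) return(1)
    hweExactTest(n0[j], n1[j], n2[j])
  }, numeric(1))
  failHwe <- hweP < config@minHweP

  chromPlain <- sub("^chr", "", as.character(seqnames(v)))
  mhcPlain <- sub("^chr", "", config@mhcChrom)
  failMhc <- chromPlain == mhcPlain & start(v) >= config@mhcStart &
    start(v) <= config@mhcEnd

  filters <- list(info_score = failInfo, missing_rate = failMiss,
                  monomorphic = failMono, maf = failMaf,
                  hwe = failHwe, mhc = failMhc)
  keep <- rep(TRUE, nv)
  removed <- integer(length(filters))
  names(removed) <- names(filters)
  for (f in names(filters)) {
    hit <- keep & filters[[f]]
    removed[f] <- sum(hit)
    keep <- keep & !hit
  }

  report <- data.frame(filter = names(removed), removed = unname(removed),
                       stringsAsFactors = FALSE)
  attr(report, "n_input") <- nv
  attr(report, "n_surviving") <- sum(keep)
  stopifnot(nv == sum(keep) + sum(removed))
  list(genotypes = x[, which(keep)], report = report)
}

#' Read and validate a donor-recipient pair table
#'
#' Reads a TSV with one row per donor-recipient pair carrying the
#' survival outcome and adjustment covariates. Required columns:
#' \code{donor_id}, \code{recipient_id}, \code{follow_time},
#' \code{event}, \code{hla_mismatch}, \code{donor_status},
#' \code{induction}, \code{donor_ancestry}, \code{recipient_ancestry}.
#'
#' @param path TSV file with header.
#' @param genotypes optional \linkS4class{GenotypeMatrix}; when given,
#'   every donor and recipient id must be present among its samples.
#' @return a validated \linkS4class{PairCohort}.
#' @export
readPairs <- function(path, genotypes = NULL) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cohort <- PairCohort(p)
  if (!is.null(genotypes)) {
    ids <- sampleIds(genotypes)
    missing <- setdiff(c(p$donor_id, p$recipient_id), ids)
    if (length(missing))
      stop("pair sample id(s) absent from genotypes: ",
           paste(utils::head(missing, 10), collapse = ", "))
  }
  cohort
}

#' Write a pair table as TSV
#' @param cohort a \linkS4class{PairCohort}.
#' @param path output path.
#' @export
writePairs <- function(cohort, path) {
  utils::write.table(pairData(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read region annotation from BED
#'
#' Reads a BED file (0-based half-open) into a 1-based \code{GRanges}
#' with metadata columns \code{region_id} (from the BED name field) and
#' \code{region_class}. Writing with [writeRegions()] and re-reading is
#' an identity on (chrom, start, end, id).
#'
#' @param path BED file (>= 4 columns).
#' @param regionClass class label assigned to all records (default
#'   "gene").
#' @return \code{GRanges} of regions.
#' @export
readRegions <- function(path, regionClass = "gene") {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || any(is.na(gr$name)))
    stop("BED file must have a name (4th) column")
  if (anyDuplicated(gr$name))
    stop("duplicate region ids in ", path)
  mcols(gr) <- S4Vectors::DataFrame(region_id = gr$name,
                                    region_class = regionClass)
  gr
}

#' Write region annotation as BED
#' @param regions \code{GRanges} with a \code{region_id} column.
#' @param path output path.
#' @export
writeRegions <- function(regions, path) {
  out <- regions
  mcols(out) <- S4Vectors::DataFrame(name = mcols(regions)$region_id)
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read a variant functional-class table
#'
#' TSV with header and columns \code{variant_id} and \code{class}
#' (e.g. exonic / non_exonic), plus optional extra indicator columns
#' such as \code{transmembrane_nonsyn}.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readVariantClasses <- function(path) {
  cls <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "class") %in% names(cls)))
    stop("variant class table needs columns variant_id, class")
  if (anyDuplicated(cls$variant_id))
    stop("duplicate variant ids in class table")
  cls
}

#' Write a QC report as TSV
#' @param report QC report from [applyQC()].
#' @param path output path.
#' @export
writeQCReport <- function(report, path) {
  out <- rbind(report,
               data.frame(filter = c("input", "surviving"),
                          removed = c(attr(report, "n_input"),
                                      attr(report, "n_surviving"))))
  names(out) <- c("filter", "n")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
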