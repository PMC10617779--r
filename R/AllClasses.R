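#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GenotypeMatrix: samples by biallelic variants
#'
#' Container for diploid genotype calls coded as ALT-allele counts
#' (0, 1, 2; \code{NA} for missing) for a set of samples at a set of
#' biallelic variants. Variant coordinates and alleles are held as a
#' \link[GenomicRanges]{GRanges} (1-based positions, width-1 ranges for
#' SNVs) with metadata columns \code{variant_id}, \code{ref}, \code{alt}
#' and optionally \code{info_score} (imputation quality in [0,1]).
#'
#' Rows of \code{calls} are samples, columns are variants; variants are
#' kept sorted by (chromosome, position).
#'
#' @slot calls integer matrix, samples x variants, values in {0,1,2,NA}.
#' @slot variants \code{GRanges} with variant metadata, parallel to the
#'   columns of \code{calls}.
#'
#' @seealso [readGenotypeVcf()], [applyQC()], [buildMismatchTable()]
#' @export
setClass("GenotypeMatrix",
         representation(calls = "matrix", variants = "GRanges"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  cl <- object@calls
  v <- object@variants
  if (ncol(cl) != length(v))
    msg <- c(msg, "ncol(calls) must equal length(variants)")
  if (!all(c("variant_id", "ref", "alt") %in% names(mcols(v))))
    msg <- c(msg, "variants must carry variant_id, ref, alt metadata")
  bad <- cl[!is.na(cl)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
    msg <- c(msg, "calls must be in {0,1,2} or NA")
  if (anyDuplicated(mcols(v)$variant_id))
    msg <- c(msg, "variant ids must be unique")
  if (is.null(rownames(cl)) || anyDuplicated(rownames(cl)))
    msg <- c(msg, "sample ids (rownames of calls) must be unique")
  if (length(v) > 1L && S4Vectors::isSorted(v) == FALSE)
    msg <- c(msg, "variants must be sorted by (chrom, pos)")
  if (any(nchar(mcols(v)$alt) == 0L))
    msg <- c(msg, "all variants must have exactly one ALT allele")
  if (length(msg)) msg else TRUE
})

#' PairCohort: donor-recipient pairings with outcomes
#'
#' Holds the donor-recipient pairing table with the survival outcome
#' (follow-up time in days and death-censored graft loss indicator) and
#' adjustment covariates (HLA mismatch score, induction therapy, donor
#' status, ancestry labels for both members of the pair).
#'
#' @slot pairs data.frame with columns \code{pair_id}, \code{donor_id},
#'   \code{recipient_id}, \code{follow_time}, \code{event},
#'   \code{hla_mismatch}, \code{donor_status}, \code{induction},
#'   \code{donor_ancestry}, \code{recipient_ancestry}.
#' @export
setClass("PairCohort", representation(pairs = "data.frame"))

.paircohort_cols <- c("pair_id", "donor_id", "recipient_id", "follow_time",
                      "event", "hla_mismatch", "donor_status", "induction",
                      "donor_ancestry", "recipient_ancestry")

setValidity("PairCohort", function(object) {
  p <- object@pairs
  msg <- character()
  miss <- setdiff(.paircohort_cols, names(p))
  if (length(miss))
    return(paste("missing pair columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(p$pair_id)) msg <- c(msg, "pair_id must be unique")
  if (any(!is.finite(p$follow_time)) || any(p$follow_time <= 0))
    msg <- c(msg, "follow_time must be positive")
  if (!all(p$event %in% c(0, 1)))
    msg <- c(msg, "event must be 0/1")
  if (!all(p$donor_status %in% c("living", "deceased")))
    msg <- c(msg, "donor_status must be 'living' or 'deceased'")
  if (any(p$hla_mismatch < 0))
    msg <- c(msg, "hla_mismatch must be non-negative")
  if (length(msg)) msg else TRUE
})

#' QCConfig: thresholds for genotype quality control
#'
#' @slot maxMissingRate variants with missing rate strictly greater are
#'   removed (default 0.05).
#' @slot minMaf minor allele frequency threshold; variants strictly below
#'   are removed (default 0.01).
#' @slot minHweP Hardy-Weinberg exact-test p-value threshold; variants
#'   strictly below are removed (default 1e-6).
#' @slot minInfo imputation INFO score threshold (default 0.4); variants
#'   with a recorded score strictly below are removed.
#' @slot minPosterior genotype-posterior masking threshold applied at VCF
#'   read time (default 0.95).
#' @slot mhcChrom,mhcStart,mhcEnd MHC exclusion interval, 1-based
#'   inclusive (default chr6:28866528-33775446, hg19).
#' @slot minMismatchFreq mismatch-frequency threshold for the gene- and
#'   variant-level screens (default 0.05).
#' @slot hweSamples which samples HWE is computed on: "all" (default),
#'   "recipients", or "recipients_living_donors".
#' @export
setClass("QCConfig",
         representation(maxMissingRate = "numeric", minMaf = "numeric",
                        minHweP = "numeric", minInfo = "numeric",
                        minPosterior = "numeric", mhcChrom = "character",
                        mhcStart = "numeric", mhcEnd = "numeric",
                        minMismatchFreq = "numeric", hweSamples = "character"))

setValidity("QCConfig", function(object) {
  msg <- character()
  in01 <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (!in01(object@maxMissingRate)) msg <- c(msg, "maxMissingRate not in [0,1]")
  if (!in01(object@minMaf) || object@minMaf > 0.5)
    msg <- c(msg, "minMaf not in [0,0.5]")
  if (!in01(object@minHweP)) msg <- c(msg, "minHweP not in [0,1]")
  if (!in01(object@minInfo)) msg <- c(msg, "minInfo not in [0,1]")
  if (!in01(object@minPosterior)) msg <- c(msg, "minPosterior not in [0,1]")
  if (!in01(object@minMismatchFreq)) msg <- c(msg, "minMismatchFreq not in [0,1]")
  if (object@mhcStart > object@mhcEnd) msg <- c(msg, "mhcStart > mhcEnd")
  if (!object@hweSamples %in% c("all", "recipients", "recipients_living_donors"))
    msg <- c(msg, "unknown hweSamples setting")
  if (length(msg)) msg else TRUE
})

#' MismatchTable: per-pair, per-variant mismatch calls
#'
#' A donor-to-recipient mismatch occurs when the donor carries an allele
#' absent from the recipient. Calls are stored as a compact signed code
#' per (pair, variant) cell:
#' \itemize{
#'   \item 0: no mismatch;
#'   \item +1 / +2: single / double mismatch introducing the ALT allele;
#'   \item -1 / -2: single / double mismatch introducing the REF allele;
#'   \item NA: either genotype missing.
#' }
#'
#' @slot codes integer matrix, pairs x variants.
#' @slot variants \code{GRanges} parallel to the columns of \code{codes}.
#' @slot pairIds character, parallel to the rows of \code{codes}.
#' @export
setClass("MismatchTable",
         representation(codes = "matrix", variants = "GRanges",
                        pairIds = "character"))

setValidity("MismatchTable", function(object) {
  msg <- character()
  if (nrow(object@codes) != length(object@pairIds))
    msg <- c(msg, "nrow(codes) must equal length(pairIds)")
  if (ncol(object@codes) != length(object@variants))
    msg <- c(msg, "ncol(codes) must equal length(variants)")
  vals <- object@codes[!is.na(object@codes)]
  if (length(vals) && !all(vals %in% -2:2))
    msg <- c(msg, "codes must be in {-2,...,2} or NA")
  if (length(msg)) msg else TRUE
})

#' ScoreTable: raw and IQR-normalized mismatch scores
#'
#' Per-pair mismatch burden over some variant set (a gene, a functional
#' class, or the whole genome): the raw score is the sum of mismatch
#' indicators, and the normalized score is raw divided by the cohort
#' interquartile range of the raw scores.
#'
#' @slot scores data.frame with columns \code{pair_id}, \code{raw},
#'   \code{normalized}.
#' @slot scale label, e.g. "genome_wide", "gene:<id>" or "class:<name>".
#' @slot mode "any" or "double" mismatch indicator.
#' @slot iqr the cohort IQR used for normalization (NA when
#'   normalization was not possible).
#' @export
setClass("ScoreTable",
         representation(scores = "data.frame", scale = "character",
                        mode = "character", iqr = "numeric"))

setValidity("ScoreTable", function(object) {
  msg <- character()
  if (!all(c("pair_id", "raw", "normalized") %in% names(object@scores)))
    msg <- c(msg, "scores must have pair_id, raw, normalized")
  if (any(object@scores$raw < 0, na.rm = TRUE))
    msg <- c(msg, "raw scores must be non-negative")
  if (length(msg)) msg else TRUE
})

#' HaplotypeBlock: an LD-defined block treated as one biallelic locus
#'
#' An ordered set of variants in near-perfect linkage disequilibrium,
#' oriented so that each member contributes an allele to the cohort-minor
#' haplotype. Per-sample minor-haplotype dosage is called by strict
#' majority vote over the member SNPs.
#'
#' @slot members variant ids, ordered by genomic position.
#' @slot minorAllele per-member allele ("REF"/"ALT") carried by the minor
#'   haplotype.
#' @slot dosage named integer vector of per-sample minor-haplotype
#'   dosage in {0,1,2}, NA when no strict majority or too much
#'   missingness.
#' @slot discordance named numeric vector, fraction of non-missing
#'   members disagreeing with the majority call.
#' @slot r2 pairwise r-squared matrix among the retained members.
#' @slot tagVariant id of the tag SNP the block was checked against
#'   (empty when none).
#' @slot minorHapFreq estimated cohort frequency of the minor haplotype.
#' @export
setClass("HaplotypeBlock",
         representation(members = "character", minorAllele = "character",
                        dosage = "integer", discordance = "numeric",
                        r2 = "matrix", tagVariant = "character",
                        minorHapFreq = "numeric"))

setValidity("HaplotypeBlock", function(object) {
  msg <- character()
  if (length(object@members) != length(object@minorAllele))
    msg <- c(msg, "minorAllele must be parallel to members")
  if (!all(object@minorAllele %in% c("REF", "ALT")))
    msg <- c(msg, "minorAllele entries must be 'REF' or 'ALT'")
  d <- object@dosage[!is.na(object@dosage)]
  if (length(d) && !all(d %in% 0:2))
    msg <- c(msg, "dosages must be in {0,1,2} or NA")
  if (length(msg)) msg else TRUE
})

#' CoxFit: a proportional-hazards fit summary
#'
#' Thin summary of a Cox proportional-hazards model: per-covariate
#' coefficients, hazard ratios (exp(beta)), standard errors, Wald tests
#' and 95\% confidence intervals, plus fit metadata.
#'
#' @slot coefficients data.frame with columns \code{term}, \code{beta},
#'   \code{hr}, \code{se}, \code{z}, \code{p}, \code{lower95},
#'   \code{upper95}.
#' @slot n,nEvents numbers of subjects and events used.
#' @slot ties tie-handling method ("efron" or "breslow").
#' @slot converged logical convergence flag; non-converged or separated
#'   fits are flagged, never silently reported.
#' @slot loglik partial log-likelihood at the solution.
#' @export
setClass("CoxFit",
         representation(coefficients = "data.frame", n = "integer",
                        nEvents = "integer", ties = "character",
                        converged = "logical", loglik = "numeric"))

#' ScreenResult: per-unit association results across scenarios
#'
#' One row per (unit, scenario) where a unit is a gene or a variant; the
#' intersection flag marks units significant in every scenario at the
#' configured threshold.
#'
#' @slot results data.frame with columns \code{unit}, \code{scenario},
#'   \code{beta}, \code{hr}, \code{se}, \code{z}, \code{p}, \code{n},
#'   \code{n_events}, \code{converged}.
#' @slot threshold nominal p-value threshold for the intersection flag.
#' @slot scenarios scenario labels screened.
#' @export
setClass("ScreenResult",
         representation(results = "data.frame", threshold = "numeric",
                        scenarios = "character"))

#' CohortConfig: parameters of the synthetic transplant cohort generator
#'
#' Bundles every parameter of the synthetic cohort: cohort dimensions,
#' ancestry structure (Balding-Nichols divergence), donor relatedness
#' mix, the planted near-perfect-LD causal haplotype block and its
#' unlinked tag SNP, the proportional-hazards survival model, and the
#' cis-eQTL expression model. Build with [cohortConfig()].
#'
#' @slot nPairs,nVariants,nGenes cohort dimensions.
#' @slot ancestry list(labels, props, fst).
#' @slot relatedness list(props) over expected IBD fractions 0/0.25/0.5.
#' @slot block list(nSnps, minorHapFreq, recombFraction, r2In, r2Out).
#' @slot tag list(riskAlleleFreq).
#' @slot hazard list(betaGw, betaMinor, betaTag, eventRate, horizon).
#' @slot eqtl list(effect, noiseSd, nSamples, nGenes, moduleSize, moduleR).
#' @slot seed integer master seed.
#' @export
setClass("CohortConfig",
         representation(nPairs = "integer", nVariants = "integer",
                        nGenes = "integer", ancestry = "list",
                        relatedness = "list", block = "list", tag = "list",
                        hazard = "list", eqtl = "list", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  a <- object@ancestry; r <- object@relatedness
  if (abs(sum(a$props) - 1) > 1e-8) msg <- c(msg, "ancestry props must sum to 1")
  if (length(a$labels) != length(a$props))
    msg <- c(msg, "ancestry labels/props length mismatch")
  if (a$fst < 0 || a$fst >= 1) msg <- c(msg, "fst must be in [0,1)")
  if (abs(sum(r$props) - 1) > 1e-8) msg <- c(msg, "relatedness props must sum to 1")
  if (any(unlist(object@block$minorHapFreq) <= 0) ||
      any(unlist(object@block$minorHapFreq) >= 1))
    msg <- c(msg, "minor haplotype frequencies must be in (0,1)")
  h <- object@hazard
  if (h$eventRate <= 0 || h$eventRate >= 1) msg <- c(msg, "eventRate must be in (0,1)")
  if (h$horizon <= 0) msg <- c(msg, "horizon must be positive")
  if (length(msg)) msg else TRUE
})
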