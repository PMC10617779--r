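#' @include AllClasses.R
NULL

#' Genotype calls matrix
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return integer matrix (samples x variants) of ALT-allele counts.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' Variant annotation
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{MismatchTable}.
#' @return \code{GRanges} of variant records.
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' Sample identifiers
#' @param x a \linkS4class{GenotypeMatrix}.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Variant identifiers
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{MismatchTable}.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' Pair identifiers
#' @param x a \linkS4class{PairCohort} or \linkS4class{MismatchTable}.
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' Pair table with covariates and outcome
#' @param x a \linkS4class{PairCohort}.
#' @export
setGeneric("pairData", function(x) standardGeneric("pairData"))

#' Any-mismatch indicator matrix
#'
#' @param x a \linkS4class{MismatchTable}.
#' @return logical matrix (pairs x variants); TRUE where the donor
#'   introduces at least one allele the recipient lacks, NA where either
#'   genotype is missing.
#' @export
setGeneric("anyMismatch", function(x) standardGeneric("anyMismatch"))

#' Double-mismatch indicator matrix
#'
#' @param x a \linkS4class{MismatchTable}.
#' @return logical matrix (pairs x variants); TRUE where the donor
#'   introduces two alien allele copies.
#' @export
setGeneric("doubleMismatch", function(x) standardGeneric("doubleMismatch"))

#' Mismatch codes matrix
#'
#' @param x a \linkS4class{MismatchTable}.
#' @return signed integer code matrix; see \linkS4class{MismatchTable}.
#' @export
setGeneric("mismatchCodes", function(x) standardGeneric("mismatchCodes"))

#' Score table accessors
#' @param x a \linkS4class{ScoreTable}.
#' @export
setGeneric("scoreData", function(x) standardGeneric("scoreData"))

#' @rdname scoreData
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' @rdname scoreData
#' @export
setGeneric("normScores", function(x) standardGeneric("normScores"))

#' Haplotype block accessors
#' @param x a \linkS4class{HaplotypeBlock}.
#' @export
setGeneric("blockMembers", function(x) standardGeneric("blockMembers"))

#' @rdname blockMembers
#' @export
setGeneric("blockDosage", function(x) standardGeneric("blockDosage"))

#' Coefficient table of a model fit
#' @param x a \linkS4class{CoxFit}.
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' Screen result accessors
#' @param x a \linkS4class{ScreenResult}.
#' @export
setGeneric("screenResults", function(x) standardGeneric("screenResults"))

#' Units significant in every scenario
#'
#' @param x a \linkS4class{ScreenResult}.
#' @param threshold nominal p-value threshold; defaults to the threshold
#'   stored in the object.
#' @return character vector of unit ids whose p-value is at or below the
#'   threshold in every screened scenario.
#' @export
setGeneric("intersectionHits",
           function(x, threshold = NULL) standardGeneric("intersectionHits"))
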