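#' @include AllGenerics.R
NULL

# ---- GenotypeMatrix ----

#' Construct a GenotypeMatrix
#'
#' @param calls numeric/integer matrix, samples x variants, ALT-allele
#'   counts in {0,1,2} or NA; rownames are sample ids.
#' @param variants \code{GRanges} parallel to columns, with metadata
#'   columns \code{variant_id}, \code{ref}, \code{alt} and optionally
#'   \code{info_score}.
#' @return a \linkS4class{GenotypeMatrix} with variants sorted by
#'   (chromosome, position).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 50), width = 1),
#'                              variant_id = c("v2", "v1"),
#'                              ref = c("A", "C"), alt = c("G", "T"))
#' m <- matrix(c(0L, 1L, 2L, NA), 2, 2, dimnames = list(c("s1", "s2"), NULL))
#' g <- GenotypeMatrix(m, gr)
#' variantIds(g)  # sorted: v1 then v2
#' @export
GenotypeMatrix <- function(calls, variants) {
  stopifnot(is.matrix(calls), ncol(calls) == length(variants))
  storage.mode(calls) <- "integer"
  if (!"info_score" %in% names(mcols(variants)))
    mcols(variants)$info_score <- NA_real_
  o <- order(variants)
  calls <- calls[, o, drop = FALSE]
  variants <- variants[o]
  colnames(calls) <- mcols(variants)$variant_id
  new("GenotypeMatrix", calls = calls, variants = variants)
}

#' @rdname genotypeCalls
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname variantRanges
#' @export
setMethod("variantRanges", "GenotypeMatrix", function(x) x@variants)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@calls))

#' @rdname variantIds
#' @export
setMethod("variantIds", "GenotypeMatrix",
          function(x) mcols(x@variants)$variant_id)

#' @describeIn GenotypeMatrix number of variants
#' @param x a GenotypeMatrix
#' @export
setMethod("length", "GenotypeMatrix", function(x) ncol(x@calls))

#' Subset a GenotypeMatrix
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param i sample index (ids, logical, or integer)
#' @param j variant index (ids, logical, or integer)
#' @param ... ignored
#' @param drop ignored; never drops
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  if (is.character(j)) j <- match(j, variantIds(x))
  new("GenotypeMatrix", calls = x@calls[i, j, drop = FALSE],
      variants = x@variants[j])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "samples x",
      ncol(object@calls), "variants\n")
  cat("  chromosomes:",
      paste(unique(as.character(seqnames(object@variants))), collapse = ", "),
      "\n")
  cat("  missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(object@calls))), "\n")
})

# ---- PairCohort ----

#' Construct a PairCohort
#'
#' @param pairs data.frame with columns \code{donor_id},
#'   \code{recipient_id}, \code{follow_time}, \code{event},
#'   \code{hla_mismatch}, \code{donor_status}, \code{induction},
#'   \code{donor_ancestry}, \code{recipient_ancestry}; a \code{pair_id}
#'   column is added (donor:recipient) if absent.
#' @return a validated \linkS4class{PairCohort}.
#' @export
PairCohort <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!"pair_id" %in% names(pairs))
    pairs$pair_id <- paste(pairs$donor_id, pairs$recipient_id, sep = ":")
  miss <- setdiff(.paircohort_cols, names(pairs))
  if (length(miss))
    stop("pair table is missing required column(s): ",
         paste(miss, collapse = ", "))
  pairs <- pairs[, union(.paircohort_cols, names(pairs))]
  new("PairCohort", pairs = pairs)
}

#' @rdname pairData
#' @export
setMethod("pairData", "PairCohort", function(x) x@pairs)

#' @rdname pairIds
#' @export
setMethod("pairIds", "PairCohort", function(x) x@pairs$pair_id)

#' @describeIn PairCohort number of pairs
#' @param x a PairCohort
#' @export
setMethod("length", "PairCohort", function(x) nrow(x@pairs))

setMethod("show", "PairCohort", function(object) {
  p <- object@pairs
  cat("PairCohort:", nrow(p), "donor-recipient pairs\n")
  cat("  events:", sum(p$event), sprintf("(%.1f%%)", 100 * mean(p$event)), "\n")
  cat("  living donors:", sum(p$donor_status == "living"), "\n")
  cat("  median follow-up:", stats::median(p$follow_time), "days\n")
})

# ---- MismatchTable ----

#' @rdname mismatchCodes
#' @export
setMethod("mismatchCodes", "MismatchTable", function(x) x@codes)

#' @rdname anyMismatch
#' @export
setMethod("anyMismatch", "MismatchTable", function(x) x@codes != 0L)

#' @rdname doubleMismatch
#' @export
setMethod("doubleMismatch", "MismatchTable", function(x) abs(x@codes) == 2L)

#' @rdname variantRanges
#' @export
setMethod("variantRanges", "MismatchTable", function(x) x@variants)

#' @rdname variantIds
#' @export
setMethod("variantIds", "MismatchTable",
          function(x) mcols(x@variants)$variant_id)

#' @rdname pairIds
#' @export
setMethod("pairIds", "MismatchTable", function(x) x@pairIds)

setMethod("show", "MismatchTable", function(object) {
  cat("MismatchTable:", nrow(object@codes), "pairs x",
      ncol(object@codes), "variants\n")
  nm <- sum(object@codes != 0L, na.rm = TRUE)
  cat("  mismatched cells:", nm,
      sprintf("(%.2f%% of non-missing)",
              100 * nm / max(1, sum(!is.na(object@codes)))), "\n")
})

# ---- ScoreTable ----

#' @rdname scoreData
#' @export
setMethod("scoreData", "ScoreTable", function(x) x@scores)

#' @rdname scoreData
#' @export
setMethod("rawScores", "ScoreTable", function(x) {
  stats::setNames(x@scores$raw, x@scores$pair_id)
})

#' @rdname scoreData
#' @export
setMethod("normScores", "ScoreTable", function(x) {
  stats::setNames(x@scores$normalized, x@scores$pair_id)
})

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable [", object@scale, ", mode=", object@mode, "]: ",
      nrow(object@scores), " pairs\n", sep = "")
  cat("  raw median:", stats::median(object@scores$raw, na.rm = TRUE),
      " IQR:", object@iqr, "\n")
})

# ---- HaplotypeBlock ----

#' @rdname blockMembers
#' @export
setMethod("blockMembers", "HaplotypeBlock", function(x) x@members)

#' @rdname blockMembers
#' @export
setMethod("blockDosage", "HaplotypeBlock", function(x) x@dosage)

setMethod("show", "HaplotypeBlock", function(object) {
  cat("HaplotypeBlock:", length(object@members), "member variants\n")
  cat("  minor haplotype frequency:",
      sprintf("%.3f", object@minorHapFreq), "\n")
  if (nzchar(object@tagVariant))
    cat("  tag variant (excluded):", object@tagVariant, "\n")
  cat("  dosage called for", sum(!is.na(object@dosage)), "of",
      length(object@dosage), "samples\n")
})

# ---- CoxFit / ScreenResult ----

#' @rdname coefTable
#' @export
setMethod("coefTable", "CoxFit", function(x) x@coefficients)

setMethod("show", "CoxFit", function(object) {
  cat("CoxFit (", object@ties, " ties): n=", object@n, ", events=",
      object@nEvents, if (!object@converged) " [NOT CONVERGED]", "\n",
      sep = "")
  print(format(object@coefficients, digits = 3), row.names = FALSE)
})

#' @rdname screenResults
#' @export
setMethod("screenResults", "ScreenResult", function(x) x@results)

#' @rdname intersectionHits
#' @export
setMethod("intersectionHits", "ScreenResult", function(x, threshold = NULL) {
  if (is.null(threshold)) threshold <- x@threshold
  r <- x@results[x@results$converged & !is.na(x@results$p), , drop = FALSE]
  tab <- tapply(r$p <= threshold, r$unit, all)
  cnt <- tapply(r$scenario, r$unit, function(s) length(unique(s)))
  units <- names(tab)[!is.na(tab) & tab & cnt == length(x@scenarios)]
  sort(units)
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult:", length(unique(object@results$unit)), "units x",
      length(object@scenarios), "scenarios\n")
  hits <- intersectionHits(object)
  cat("  intersection hits (p <=", object@threshold, "):",
      length(hits), "\n")
})
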