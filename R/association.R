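#' @include accessors.R
NULL

#' Fit a Cox proportional-hazards model
#'
#' Thin, contract-enforcing wrapper around
#' \code{\link[survival]{coxph}}: maximizes the partial likelihood with
#' Efron tie handling by default (Breslow available), supports
#' stratification (separate baseline hazards per stratum), and reports
#' hazard ratios with Wald 95\% confidence intervals
#' \code{exp(beta +/- 1.96 se)}. Non-convergence and monotone-likelihood
#' (complete separation) problems are flagged on the returned object,
#' never silently dropped.
#'
#' @param time follow-up times (> 0).
#' @param event event indicator, 0/1.
#' @param covariates data.frame of covariates; character columns are
#'   treated as factors. Rows with missing values are dropped listwise.
#' @param strata optional stratification factor.
#' @param ties "efron" (default) or "breslow".
#' @return a \linkS4class{CoxFit}.
#' @export
fitCox <- function(time, event, covariates, strata = NULL,
                   ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (sum(event, na.rm = TRUE) < 1) stop("at least one event required")
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  if (!is.null(strata)) df$.strata <- strata
  complete <- stats::complete.cases(df)
  df <- df[complete, , drop = FALSE]
  terms <- paste0("`", names(covariates), "`", collapse = " + ")
  if (!is.null(strata)) terms <- paste(terms, "+ strata(.strata)")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", terms))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties, model = FALSE,
                    x = FALSE, y = TRUE),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  converged <- !warned && all(is.finite(beta)) && all(is.finite(se)) &&
    all(abs(beta) < 15)
  z <- beta / se
  coefs <- data.frame(
    term = names(beta), beta = unname(beta), hr = exp(unname(beta)),
    se = unname(se), z = unname(z),
    p = 2 * stats::pnorm(-abs(unname(z))),
    lower95 = exp(unname(beta) - 1.96 * unname(se)),
    upper95 = exp(unname(beta) + 1.96 * unname(se)),
    stringsAsFactors = FALSE)
  new("CoxFit", coefficients = coefs, n = as.integer(fit$n),
      nEvents = as.integer(fit$nevent), ties = ties,
      converged = converged,
      loglik = fit$loglik[length(fit$loglik)])
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group plus the k-group log-rank
#' test (chi-squared on k-1 degrees of freedom).
#'
#' @param time follow-up times.
#' @param event event indicator, 0/1.
#' @param group group labels; every level must have at least one
#'   subject.
#' @return list with \code{curves} (data.frame: group, time, n_risk,
#'   n_event, surv), \code{observed} and \code{expected} per-group event
#'   counts, \code{chisq}, \code{df}, and \code{p}.
#' @export
kmLogrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("at least two groups required")
  if (any(table(group) == 0L))
    stop("group(s) with zero subjects: ",
         paste(levels(group)[table(group) == 0L], collapse = ", "))
  df <- data.frame(time = time, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strat <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^group=", "", strat),
                       time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(sd$n)
  list(curves = curves,
       observed = stats::setNames(sd$obs, levels(group)),
       expected = stats::setNames(sd$exp, levels(group)),
       chisq = sd$chisq, df = k - 1L,
       p = stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE))
}

.screenScenarios <- function(modes, subsets) {
  out <- expand.grid(mode = modes, subset = subsets,
                     stringsAsFactors = FALSE)
  paste(out$mode, out$subset, sep = "/")
}

#' Genome-wide gene-level mismatch screen
#'
#' Screens every gene's mismatch score for association with the
#' survival outcome under four scenarios — \{any, double\} mismatch
#' \eqn{\times} \{all pairs, a configurable subset (e.g. intra-European
#' pairs)\} — each scenario a multivariable Cox model with the gene raw
#' score as exposure, adjusted for the genome-wide mismatch score and
#' the clinical covariates. Genes significant at the nominal threshold
#' in every scenario carry the intersection flag. No multiplicity
#' correction is applied at this stage; the intersection across
#' scenarios is the screening criterion.
#'
#' @param table a \linkS4class{MismatchTable} restricted to the
#'   frequency-filtered variant set (see [mismatchFrequencyFilter()]).
#' @param regions gene annotation \code{GRanges} with \code{region_id}.
#' @param cohort a \linkS4class{PairCohort}.
#' @param genomewide named list with elements \code{any} and
#'   \code{double}: genome-wide \linkS4class{ScoreTable}s used as
#'   adjustment (the any-mode table is reused when \code{double} is
#'   absent).
#' @param covariates names of adjustment columns in the pair table
#'   (default HLA mismatch, induction, donor status).
#' @param subset logical vector over pairs defining the subset
#'   scenario; defaults to intra-ancestry pairs whose donor and
#'   recipient ancestry agree with \code{subsetAncestry}.
#' @param subsetAncestry ancestry label for the default subset
#'   (default "EUR").
#' @param threshold nominal p-value for the intersection flag (default
#'   0.01).
#' @return a \linkS4class{ScreenResult}; genes with degenerate
#'   (constant) scores in a scenario are recorded with NA statistics
#'   and \code{converged = FALSE}.
#' @export
geneScreen <- function(table, regions, cohort,
                       genomewide,
                       covariates = c("hla_mismatch", "induction",
                                      "donor_status"),
                       subset = NULL, subsetAncestry = "EUR",
                       threshold = 0.01) {
  p <- pairData(cohort)
  stopifnot(identical(p$pair_id, pairIds(table)))
  if (is.null(subset))
    subset <- p$donor_ancestry == subsetAncestry &
      p$recipient_ancestry == subsetAncestry
  if (sum(subset) < 10L)
    stop("subset scenario has fewer than 10 pairs")
  if (is(genomewide, "ScoreTable"))
    genomewide <- list(any = genomewide, double = genomewide)
  if (is.null(genomewide$double)) genomewide$double <- genomewide$any

  rawBy <- list(any = .regionRawMatrix(table, regions, "any"),
                double = .regionRawMatrix(table, regions, "double"))
  geneIds <- mcols(regions)$region_id

  res <- vector("list", 4L)
  i <- 0L
  for (mode in c("any", "double")) {
    gw <- normScores(genomewide[[mode]])[p$pair_id]
    for (sub in c("all", "subset")) {
      i <- i + 1L
      sel <- if (sub == "all") rep(TRUE, nrow(p)) else subset
      scen <- paste(mode, sub, sep = "/")
      raw <- rawBy[[mode]][sel, , drop = FALSE]
      base <- cbind(data.frame(genomewide_score = gw[sel]),
                    p[sel, covariates, drop = FALSE])
      res[[i]] <- .screenUnits(raw, p$follow_time[sel], p$event[sel],
                               base, geneIds, scen)
    }
  }
  results <- do.call(rbind, res)
  new("ScreenResult", results = results, threshold = threshold,
      scenarios = .screenScenarios(c("any", "double"), c("all", "subset")))
}

# Cox screen of each column of `expo` as exposure with shared adjustments
.screenUnits <- function(expo, time, event, base, unitIds, scenario) {
  out <- lapply(seq_len(ncol(expo)), function(j) {
    x <- expo[, j]
    if (length(unique(x[!is.na(x)])) < 2L)
      return(data.frame(unit = unitIds[j], scenario = scenario,
                        beta = NA_real_, hr = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_, n = NA_integer_,
                        n_events = NA_integer_, converged = FALSE,
                        reason = "degenerate score",
                        stringsAsFactors = FALSE))
    fit <- tryCatch(
      fitCox(time, event, cbind(data.frame(score = x), base)),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(unit = unitIds[j], scenario = scenario,
                        beta = NA_real_, hr = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_, n = NA_integer_,
                        n_events = NA_integer_, converged = FALSE,
                        reason = "fit error", stringsAsFactors = FALSE))
    co <- coefTable(fit)[1L, ]
    data.frame(unit = unitIds[j], scenario = scenario, beta = co$beta,
               hr = co$hr, se = co$se, z = co$z, p = co$p,
               n = fit@n, n_events = fit@nEvents,
               converged = fit@converged, reason = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate mismatch score over a gene list
#'
#' Sums the gene-level raw mismatch scores over a candidate gene list
#' into one aggregate per pair, together with the complementary
#' "remaining genome" score (variants outside every listed gene), so
#' the disproportionate contribution of the candidate loci can be
#' tested against the rest of the genome.
#'
#' @param geneIds gene ids to aggregate.
#' @param table a \linkS4class{MismatchTable}.
#' @param regions gene annotation with \code{region_id}.
#' @param mode "any" (default) or "double".
#' @return list of two \linkS4class{ScoreTable}s: \code{aggregate} and
#'   \code{complement}.
#' @export
aggregateGeneScore <- function(geneIds, table, regions, mode = "any") {
  sel <- mcols(regions)$region_id %in% geneIds
  if (!all(geneIds %in% mcols(regions)$region_id))
    stop("gene id(s) not in annotation: ",
         paste(setdiff(geneIds, mcols(regions)$region_id), collapse = ", "))
  raw <- .regionRawMatrix(table, regions[sel], mode)
  agg <- rowSums(raw)
  ind <- .indicatorMatrix(table, mode)
  inside <- IRanges::overlapsAny(variantRanges(table), regions[sel],
                                 ignore.strand = TRUE)
  comp <- rowSums(ind[, !inside, drop = FALSE], na.rm = TRUE)
  list(aggregate = .scoreTable(unname(agg), pairIds(table),
                               "aggregate_genes", mode),
       complement = .scoreTable(unname(comp), pairIds(table),
                                "remaining_genome", mode))
}

#' Variant-level mismatch screen within a locus
#'
#' Tests each variant's any-mismatch indicator for association with the
#' outcome under four scenarios: Cox models (a) adjusted by the tag-SNP
#' risk-mismatch indicator on all pairs and (b) restricted to the
#' tag-non-risk stratum (pairs without a tag risk mismatch), each run
#' on the full cohort and on the configured subset. Variants
#' significant in all four scenarios are the candidate block seeds. The
#' tag variant itself is excluded from the screen by construction.
#'
#' @param variantIds variants to screen (tag removed automatically).
#' @param table a \linkS4class{MismatchTable} containing them.
#' @param cohort a \linkS4class{PairCohort}.
#' @param tagRisk logical per pair: tag-SNP risk mismatch present (see
#'   [tagRiskMismatch()]).
#' @param tagVariant id of the tag variant (excluded from screening).
#' @param covariates adjustment columns of the pair table.
#' @param subset logical subset definition as in [geneScreen()].
#' @param subsetAncestry default-subset ancestry label.
#' @param threshold nominal p for the intersection flag (default 0.05).
#' @return a \linkS4class{ScreenResult} with scenarios
#'   adjusted/stratified x all/subset.
#' @export
variantScreen <- function(variantIds, table, cohort, tagRisk,
                          tagVariant = NULL,
                          covariates = c("hla_mismatch", "induction",
                                         "donor_status"),
                          subset = NULL, subsetAncestry = "EUR",
                          threshold = 0.05) {
  p <- pairData(cohort)
  stopifnot(identical(p$pair_id, pairIds(table)),
            length(tagRisk) == nrow(p))
  if (!is.null(tagVariant)) variantIds <- setdiff(variantIds, tagVariant)
  ind <- anyMismatch(table)[, variantIds, drop = FALSE]
  mode(ind) <- "integer"
  if (is.null(subset))
    subset <- p$donor_ancestry == subsetAncestry &
      p$recipient_ancestry == subsetAncestry

  res <- vector("list", 4L)
  i <- 0L
  for (model in c("adjusted", "stratified")) {
    for (sub in c("all", "subset")) {
      i <- i + 1L
      sel <- if (sub == "all") rep(TRUE, nrow(p)) else subset
      if (model == "stratified") sel <- sel & !tagRisk
      scen <- paste(model, sub, sep = "/")
      base <- p[sel, covariates, drop = FALSE]
      if (model == "adjusted")
        base <- cbind(data.frame(tag_risk = as.integer(tagRisk[sel])), base)
      res[[i]] <- .screenUnits(ind[sel, , drop = FALSE],
                               p$follow_time[sel], p$event[sel],
                               base, variantIds, scen)
    }
  }
  new("ScreenResult", results = do.call(rbind, res),
      threshold = threshold,
      scenarios = c("adjusted/all", "adjusted/subset",
                    "stratified/all", "stratified/subset"))
}

#' Haplotype mismatch dosage-trend test
#'
#' Cox model with the number of alien haplotype alleles introduced by
#' the donor (0, 1, 2) as a numeric exposure — a positive coefficient
#' indicates a dosage effect — together with Kaplan-Meier curves by
#' dosage group.
#'
#' @param nAlien per-pair alien-allele dosage in {0,1,2} (see
#'   [haplotypeMismatch()]); NA pairs are dropped.
#' @param cohort a \linkS4class{PairCohort}.
#' @param covariates adjustment columns of the pair table (default
#'   none: the unadjusted dosage trend).
#' @return list with \code{fit} (a \linkS4class{CoxFit}) and \code{km}
#'   (the [kmLogrank()] result by dosage group).
#' @export
dosageTrend <- function(nAlien, cohort, covariates = character()) {
  p <- pairData(cohort)
  stopifnot(length(nAlien) == nrow(p))
  use <- !is.na(nAlien)
  if (length(unique(nAlien[use])) < 2L)
    stop("dosage has a single level; trend undefined")
  covs <- cbind(data.frame(dosage = nAlien[use]),
                p[use, covariates, drop = FALSE])
  fit <- fitCox(p$follow_time[use], p$event[use], covs)
  km <- kmLogrank(p$follow_time[use], p$event[use],
                  factor(nAlien[use], levels = sort(unique(nAlien[use]))))
  list(fit = fit, km = km)
}

#' Manhattan-plot-ready table from a screen
#'
#' @param screen a \linkS4class{ScreenResult}.
#' @param regions annotation \code{GRanges} with \code{region_id}
#'   matching the screen units (for variant screens, pass the variant
#'   ranges with \code{variant_id} renamed to \code{region_id}).
#' @return data.frame with unit, chrom, pos (region midpoint),
#'   scenario, p, neglog10_p.
#' @export
manhattanTable <- function(screen, regions) {
  r <- screenResults(screen)
  idx <- match(r$unit, mcols(regions)$region_id)
  data.frame(unit = r$unit,
             chrom = as.character(seqnames(regions))[idx],
             pos = (start(regions)[idx] + end(regions)[idx]) %/% 2,
             scenario = r$scenario, p = r$p,
             neglog10_p = -log10(r$p),
             stringsAsFactors = FALSE)
}

#' Write screen results as TSV
#' @param screen a \linkS4class{ScreenResult}.
#' @param path output path.
#' @export
writeScreenResult <- function(screen, path) {
  r <- screenResults(screen)
  hits <- intersectionHits(screen)
  r$intersection <- r$unit %in% hits
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
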