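#' @include accessors.R
NULL

#' Assemble a pipeline configuration
#'
#' Bundles everything the end-to-end pipeline needs: the synthetic
#' cohort generator config (ignored when running on user-supplied
#' files), QC thresholds, screen thresholds and covariate lists, the
#' haplotype-block thresholds, and the tag-SNP definition. The
#' configuration is validated here, before any stage runs, and is
#' serialized into the output directory for provenance.
#'
#' @param cohort a \linkS4class{CohortConfig}.
#' @param qc a \linkS4class{QCConfig}.
#' @param covariates adjustment covariate columns of the pair table.
#' @param subsetAncestry ancestry label defining the intra-ancestry
#'   subset scenario.
#' @param geneThreshold nominal p for the gene-screen intersection
#'   flag.
#' @param variantThreshold nominal p for the variant-screen
#'   intersection flag.
#' @param tagVariant tag-SNP variant id.
#' @param riskAllele tag risk allele ("ALT" or "REF").
#' @param seedGene seed gene for the coexpression analysis.
#' @param locusGene gene whose locus the variant-level screen and block
#'   construction run in; NULL (default) picks the top-ranked gene of
#'   the gene screen (smallest worst-scenario p).
#' @param blockSeeds how haplotype-block seeds are chosen:
#'   "intersection" (variants flagged in all four variant-screen
#'   scenarios, falling back to the best-ranked variants when none
#'   pass) or "topn".
#' @param maxSeeds cap on the number of block seeds.
#' @return validated pipeline configuration (a named list).
#' @export
pipelineConfig <- function(cohort = cohortConfig(), qc = qcConfig(),
                           covariates = c("hla_mismatch", "induction",
                                          "donor_status"),
                           subsetAncestry = "EUR",
                           geneThreshold = 0.01,
                           variantThreshold = 0.05,
                           tagVariant = "tagSNP", riskAllele = "ALT",
                           seedGene = "TARGET", locusGene = NULL,
                           blockSeeds = "intersection", maxSeeds = 40L) {
  stopifnot(is(cohort, "CohortConfig"), is(qc, "QCConfig"),
            geneThreshold >= 0, geneThreshold <= 1,
            variantThreshold >= 0, variantThreshold <= 1,
            riskAllele %in% c("ALT", "REF"),
            blockSeeds %in% c("intersection", "topn"))
  validObject(cohort)
  validObject(qc)
  list(cohort = cohort, qc = qc, covariates = covariates,
       subsetAncestry = subsetAncestry, geneThreshold = geneThreshold,
       variantThreshold = variantThreshold, tagVariant = tagVariant,
       riskAllele = riskAllele, seedGene = seedGene,
       locusGene = locusGene, blockSeeds = blockSeeds,
       maxSeeds = as.integer(maxSeeds))
}

.stageLog <- function(dir, stage, lines) {
  logDir <- file.path(dir, "logs")
  dir.create(logDir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(paste0("stage: ", stage), lines),
             file.path(logDir, paste0(stage, ".log")))
}

.requireFiles <- function(paths, neededBy, producedBy) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("stage '", neededBy, "' needs output of stage '", producedBy,
         "'; run it first. Missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
}

.readCohortInputs <- function(dir, qc) {
  cdir <- file.path(dir, "cohort")
  .requireFiles(file.path(cdir, c("genotypes.vcf", "pairs.tsv",
                                  "regions.bed", "classes.tsv")),
                "downstream", "simulate")
  genotypes <- readGenotypeVcf(file.path(cdir, "genotypes.vcf"),
                               minPosterior = qc@minPosterior)
  list(genotypes = genotypes,
       cohort = readPairs(file.path(cdir, "pairs.tsv"), genotypes),
       regions = readRegions(file.path(cdir, "regions.bed")),
       classes = readVariantClasses(file.path(cdir, "classes.tsv")))
}

#' Run the end-to-end mismatch pipeline
#'
#' Executes the pipeline stages in order — simulate, qc, mismatch,
#' screen, haplotype, eqtl — writing every stage's outputs, a
#' structured per-stage log (variant and pair counts, dropped units,
#' non-converged fits) and the resolved configuration into
#' \code{outDir}. Stages read only files written by earlier stages, so
#' a subset of stages can be re-run against an existing directory;
#' every run with identical config and inputs is byte-identical. No
#' stage mutates its inputs.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory.
#' @param stages stages to run, in order.
#' @return invisibly, \code{outDir}.
#' @export
runPipeline <- function(config, outDir,
                        stages = c("simulate", "qc", "mismatch", "screen",
                                   "haplotype", "eqtl")) {
  known <- c("simulate", "qc", "mismatch", "screen", "haplotype", "eqtl")
  stages <- match.arg(stages, known, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(cohortConfigAsList(config$cohort),
            list(qc = list(maxMissingRate = config$qc@maxMissingRate,
                           minMaf = config$qc@minMaf,
                           minHweP = config$qc@minHweP,
                           minInfo = config$qc@minInfo,
                           minPosterior = config$qc@minPosterior,
                           minMismatchFreq = config$qc@minMismatchFreq),
                 covariates = config$covariates,
                 subsetAncestry = config$subsetAncestry,
                 geneThreshold = config$geneThreshold,
                 variantThreshold = config$variantThreshold,
                 tagVariant = config$tagVariant,
                 riskAllele = config$riskAllele,
                 package_version =
                   as.character(utils::packageVersion("DRmismatch"))))
  yaml::write_yaml(prov, file.path(outDir, "config.yaml"))
  for (s in stages)
    switch(s,
           simulate = stageSimulate(config, outDir),
           qc = stageQc(config, outDir),
           mismatch = stageMismatch(config, outDir),
           screen = stageScreen(config, outDir),
           haplotype = stageHaplotype(config, outDir),
           eqtl = stageEqtl(config, outDir))
  invisible(outDir)
}

#' @rdname runPipeline
#' @export
stageSimulate <- function(config, outDir) {
  paths <- emitCohort(config$cohort, file.path(outDir, "cohort"))
  sim <- attr(paths, "cohort")
  .stageLog(outDir, "simulate",
            c(paste0("pairs: ", length(sim$cohort)),
              paste0("variants: ", length(sim$genotypes)),
              paste0("genes: ", length(sim$regions)),
              paste0("events: ", sum(pairData(sim$cohort)$event))))
  invisible(paths)
}

#' @rdname runPipeline
#' @export
stageQc <- function(config, outDir) {
  inp <- .readCohortInputs(outDir, config$qc)
  qcDir <- file.path(outDir, "qc")
  dir.create(qcDir, showWarnings = FALSE, recursive = TRUE)
  res <- applyQC(inp$genotypes, config$qc, inp$cohort)
  writeQCReport(res$report, file.path(qcDir, "qc_report.tsv"))
  writeLines(variantIds(res$genotypes),
             file.path(qcDir, "variants_pass.tsv"))
  .stageLog(outDir, "qc",
            c(paste0("variants_in: ", attr(res$report, "n_input")),
              paste0("variants_out: ", attr(res$report, "n_surviving")),
              paste0(res$report$filter, "_removed: ", res$report$removed)))
  invisible(res)
}

.qcGenotypes <- function(config, outDir) {
  inp <- .readCohortInputs(outDir, config$qc)
  passFile <- file.path(outDir, "qc", "variants_pass.tsv")
  .requireFiles(passFile, "mismatch/screen/haplotype", "qc")
  pass <- readLines(passFile)
  inp$genotypes <- inp$genotypes[, which(variantIds(inp$genotypes) %in% pass)]
  inp
}

#' @rdname runPipeline
#' @export
stageMismatch <- function(config, outDir) {
  inp <- .qcGenotypes(config, outDir)
  mmDir <- file.path(outDir, "mismatch")
  dir.create(mmDir, showWarnings = FALSE, recursive = TRUE)
  table <- buildMismatchTable(inp$genotypes, inp$cohort)
  gw <- genomeWideScore(table)
  writeScoreTable(gw, file.path(mmDir, "score_genomewide.tsv"))
  ff <- mismatchFrequencyFilter(table, config$qc@minMismatchFreq)
  utils::write.table(ff$frequencies,
                     file.path(mmDir, "mismatch_freq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ff$variant_ids, file.path(mmDir, "variants_screen.tsv"))
  cs <- classScores(table, inp$classes)
  classTab <- do.call(rbind, lapply(names(cs$scores), function(cl) {
    d <- scoreData(cs$scores[[cl]])
    d$class <- cl
    d
  }))
  utils::write.table(classTab, file.path(mmDir, "score_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round(cs$correlation, 6),
                     file.path(mmDir, "class_correlation.tsv"),
                     sep = "\t", quote = FALSE)
  p <- pairData(inp$cohort)
  cl <- genotypeCalls(inp$genotypes)
  freqs <- colMeans(cl, na.rm = TRUE) / 2
  ids <- sampleIds(inp$genotypes)
  pibd <- vapply(seq_len(nrow(p)), function(i) {
    suppressWarnings(estimatePibd(cl[match(p$donor_id[i], ids), ],
                                  cl[match(p$recipient_id[i], ids), ],
                                  freqs))
  }, numeric(1))
  utils::write.table(
    data.frame(pair_id = p$pair_id, pibd = round(pibd, 6)),
    file.path(mmDir, "pibd.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  .stageLog(outDir, "mismatch",
            c(paste0("variants_scored: ", length(inp$genotypes)),
              paste0("variants_screen: ", length(ff$variant_ids)),
              paste0("gw_iqr: ", round(gw@iqr, 4)),
              paste0("pibd_score_spearman: ",
                     round(stats::cor(pibd, normScores(gw),
                                      method = "spearman"), 4))))
  invisible(table)
}

#' @rdname runPipeline
#' @export
stageScreen <- function(config, outDir) {
  inp <- .qcGenotypes(config, outDir)
  scDir <- file.path(outDir, "screen")
  dir.create(scDir, showWarnings = FALSE, recursive = TRUE)
  screenFile <- file.path(outDir, "mismatch", "variants_screen.tsv")
  .requireFiles(screenFile, "screen", "mismatch")
  keep <- readLines(screenFile)
  tableAll <- buildMismatchTable(inp$genotypes, inp$cohort)
  gwAny <- genomeWideScore(tableAll, mode = "any")
  gwDouble <- genomeWideScore(tableAll, mode = "double")
  gsub <- inp$genotypes[, which(variantIds(inp$genotypes) %in% keep)]
  table <- buildMismatchTable(gsub, inp$cohort)
  screen <- geneScreen(table, inp$regions, inp$cohort,
                       list(any = gwAny, double = gwDouble),
                       covariates = config$covariates,
                       subsetAncestry = config$subsetAncestry,
                       threshold = config$geneThreshold)
  writeScreenResult(screen, file.path(scDir, "gene_screen.tsv"))
  utils::write.table(manhattanTable(screen, inp$regions),
                     file.path(scDir, "gene_manhattan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- intersectionHits(screen)
  if (length(hits)) {
    agg <- aggregateGeneScore(hits, table, inp$regions)
    both <- merge(scoreData(agg$aggregate), scoreData(agg$complement),
                  by = "pair_id", suffixes = c("_candidates", "_rest"))
    utils::write.table(both, file.path(scDir, "aggregate_score.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  r <- screenResults(screen)
  .stageLog(outDir, "screen",
            c(paste0("genes: ", length(unique(r$unit))),
              paste0("non_converged: ", sum(!r$converged)),
              paste0("intersection_hits: ", length(hits)),
              paste0("hits: ", paste(hits, collapse = ","))))
  invisible(screen)
}

.topGene <- function(screenTsv) {
  r <- utils::read.delim(screenTsv, stringsAsFactors = FALSE)
  r <- r[r$converged & !is.na(r$p), , drop = FALSE]
  worst <- tapply(r$p, r$unit, max)   # weakest scenario per gene
  names(which.min(worst))
}

#' @rdname runPipeline
#' @export
stageHaplotype <- function(config, outDir) {
  inp <- .qcGenotypes(config, outDir)
  hpDir <- file.path(outDir, "haplotype")
  dir.create(hpDir, showWarnings = FALSE, recursive = TRUE)
  screenFile <- file.path(outDir, "screen", "gene_screen.tsv")
  freqFile <- file.path(outDir, "mismatch", "variants_screen.tsv")
  .requireFiles(c(screenFile, freqFile), "haplotype", "screen")
  keep <- readLines(freqFile)
  locusGene <- if (is.null(config$locusGene)) .topGene(screenFile) else
    config$locusGene
  locus <- inp$regions[mcols(inp$regions)$region_id == locusGene]
  v <- variantRanges(inp$genotypes)
  inLocus <- IRanges::overlapsAny(v, locus, ignore.strand = TRUE)
  locusVariants <- setdiff(
    intersect(mcols(v)$variant_id[inLocus], keep), config$tagVariant)
  if (!length(locusVariants))
    stop("no screenable variants in top gene ", locusGene)

  cl <- genotypeCalls(inp$genotypes)
  p <- pairData(inp$cohort)
  ids <- sampleIds(inp$genotypes)
  if (!config$tagVariant %in% colnames(cl))
    stop("tag variant ", config$tagVariant, " not among QC-passing variants")
  tagGt <- cl[, config$tagVariant]
  tagRisk <- tagRiskMismatch(tagGt[match(p$donor_id, ids)],
                             tagGt[match(p$recipient_id, ids)],
                             config$riskAllele)
  tagRisk[is.na(tagRisk)] <- FALSE

  table <- buildMismatchTable(
    inp$genotypes[, which(colnames(cl) %in% c(locusVariants,
                                              config$tagVariant))],
    inp$cohort)
  vs <- variantScreen(locusVariants, table, inp$cohort, tagRisk,
                      tagVariant = config$tagVariant,
                      covariates = config$covariates,
                      subsetAncestry = config$subsetAncestry,
                      threshold = config$variantThreshold)
  vr <- variantRanges(inp$genotypes)
  vreg <- vr[mcols(vr)$variant_id %in% locusVariants]
  mcols(vreg)$region_id <- mcols(vreg)$variant_id
  writeScreenResult(vs, file.path(hpDir, "variant_screen.tsv"))
  utils::write.table(manhattanTable(vs, vreg),
                     file.path(hpDir, "variant_manhattan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  seeds <- intersectionHits(vs)
  usedFallback <- FALSE
  if (!length(seeds) || config$blockSeeds == "topn") {
    usedFallback <- !length(seeds)
    r <- screenResults(vs)
    r <- r[r$converged & !is.na(r$p), , drop = FALSE]
    worst <- sort(tapply(r$p, r$unit, max))
    seeds <- names(worst)[seq_len(min(config$maxSeeds, length(worst)))]
  }
  if (!length(seeds))
    stop("no block seed candidates in locus ", locusGene)
  if (length(seeds) > config$maxSeeds) seeds <- seeds[seq_len(config$maxSeeds)]
  block <- buildBlock(inp$genotypes, seeds,
                      r2In = config$cohort@block$r2In,
                      tagVariant = config$tagVariant,
                      r2Out = config$cohort@block$r2Out)
  writeBlock(block, file.path(hpDir, "block.tsv"))
  dos <- haplotypeDosage(block)
  utils::write.table(
    data.frame(sample_id = names(dos$dosage), dosage = dos$dosage,
               discordance = round(dos$discordance, 6)),
    file.path(hpDir, "dosage.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  dDos <- dos$dosage[match(p$donor_id, names(dos$dosage))]
  rDos <- dos$dosage[match(p$recipient_id, names(dos$dosage))]
  hm <- haplotypeMismatch(dDos, rDos)
  direction <- classifyDirection(dDos, rDos,
                                 tagGt[match(p$donor_id, ids)],
                                 tagGt[match(p$recipient_id, ids)],
                                 config$riskAllele)
  utils::write.table(
    data.frame(pair_id = p$pair_id, donor_dosage = dDos,
               recipient_dosage = rDos, n_alien = hm$n_alien,
               direction = as.character(direction)),
    file.path(hpDir, "direction.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  trend <- dosageTrend(hm$n_alien, inp$cohort)
  utils::write.table(coefTable(trend$fit),
                     file.path(hpDir, "dosage_trend.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(trend$km$curves,
                     file.path(hpDir, "km_dosage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  useDir <- !is.na(direction)
  if (length(unique(direction[useDir])) > 1L) {
    kmDir <- kmLogrank(p$follow_time[useDir], p$event[useDir],
                       droplevels(direction[useDir]))
    curves <- kmDir$curves
    curves$logrank_p <- kmDir$p
    utils::write.table(curves, file.path(hpDir, "km_direction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .stageLog(outDir, "haplotype",
            c(paste0("locus_gene: ", locusGene),
              paste0("locus_variants: ", length(locusVariants)),
              paste0("seed_fallback: ", usedFallback),
              paste0("block_size: ", length(blockMembers(block))),
              paste0("minor_hap_freq: ", round(block@minorHapFreq, 4)),
              paste0("pairs_missing_dosage: ",
                     sum(is.na(dDos) | is.na(rDos)))))
  invisible(block)
}

#' @rdname runPipeline
#' @export
stageEqtl <- function(config, outDir) {
  eqDir <- file.path(outDir, "eqtl")
  dir.create(eqDir, showWarnings = FALSE, recursive = TRUE)
  exprFile <- file.path(outDir, "cohort", "expression.tsv")
  covFile <- file.path(outDir, "cohort", "expression_covariates.tsv")
  dosFile <- file.path(outDir, "haplotype", "dosage.tsv")
  .requireFiles(c(exprFile, covFile), "eqtl", "simulate")
  .requireFiles(dosFile, "eqtl", "haplotype")
  exprTab <- utils::read.delim(exprFile, check.names = FALSE)
  expr <- as.matrix(exprTab[, -1, drop = FALSE])
  rownames(expr) <- exprTab$gene
  cov <- utils::read.delim(covFile, stringsAsFactors = FALSE)
  dosTab <- utils::read.delim(dosFile, stringsAsFactors = FALSE)
  dosage <- dosTab$dosage[match(colnames(expr), dosTab$sample_id)]
  scan <- eqtlScan(expr, dosage,
                   cov[, intersect(c("age", "sex", "ancestry"),
                                   names(cov)), drop = FALSE])
  scan[, c("effect", "se", "t", "p", "adj_p")] <-
    round(scan[, c("effect", "se", "t", "p", "adj_p")], 8)
  utils::write.table(scan, file.path(eqDir, "eqtl.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  co <- coexpression(expr, config$seedGene)
  co$r <- round(co$r, 6)
  co[, c("p", "adj_p")] <- signif(co[, c("p", "adj_p")], 8)
  utils::write.table(co, file.path(eqDir, "coexpression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .stageLog(outDir, "eqtl",
            c(paste0("expression_samples: ", sum(!is.na(dosage))),
              paste0("genes_tested: ", nrow(scan)),
              paste0("coexpressed_with_seed: ", nrow(co))))
  invisible(scan)
}
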