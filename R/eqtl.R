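#' @include accessors.R
NULL

.designMatrix <- function(n, dosage, covariates) {
  df <- data.frame(dosage = dosage)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    df <- cbind(df, as.data.frame(covariates))
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-seq_len(qrX$rank)]
    dep <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  X
}

#' Additive-model eQTL test for one gene
#'
#' Least-squares fit of an expression trait on an allele dosage (0, 1,
#' 2 risk or minor alleles) plus covariates; the reported effect is the
#' expression change per allele, with an ordinary t-test on the dosage
#' coefficient.
#'
#' @param expr numeric expression values (one gene across samples),
#'   conventionally log2(TPM + 1).
#' @param dosage allele dosage in {0,1,2}, at least two distinct
#'   values.
#' @param covariates optional data.frame of adjustment covariates
#'   (e.g. age, sex, ancestry).
#' @return data.frame with one row: effect, se, t, p, n.
#' @export
eqtlTest <- function(expr, dosage, covariates = NULL) {
  use <- !is.na(expr) & !is.na(dosage)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    use <- use & stats::complete.cases(covariates)
    covariates <- covariates[use, , drop = FALSE]
  }
  expr <- expr[use]
  dosage <- dosage[use]
  if (length(unique(dosage)) < 2L)
    stop("dosage must take at least two distinct values")
  X <- .designMatrix(length(expr), dosage, covariates)
  if (length(expr) <= ncol(X) + 1L)
    stop("too few samples for the design (n must exceed covariates + 2)")
  fit <- stats::lm.fit(X, expr)
  dfRes <- length(expr) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / dfRes
  XtXinv <- chol2inv(qr.R(qr(X)))
  j <- match("dosage", colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  eff <- unname(fit$coefficients[j])
  tstat <- eff / se
  p <- if (se == 0) 0 else 2 * stats::pt(-abs(tstat), dfRes)
  data.frame(effect = eff, se = se, t = tstat,
             p = ifelse(is.nan(p), 0, p), n = length(expr))
}

#' Transcriptome-wide additive eQTL scan
#'
#' Runs the additive dosage model of [eqtlTest()] for every gene of an
#' expression matrix against one allele dosage, with shared covariates,
#' and applies Benjamini-Hochberg adjustment across genes.
#'
#' @param expr genes x samples numeric matrix (rownames = gene ids),
#'   conventionally log2(TPM + 1).
#' @param dosage allele dosage per sample (length = ncol(expr)).
#' @param covariates optional data.frame of per-sample covariates.
#' @return data.frame per gene: gene, effect, se, t, p, adj_p, n,
#'   ordered as the input.
#' @export
eqtlScan <- function(expr, dosage, covariates = NULL) {
  stopifnot(is.matrix(expr), length(dosage) == ncol(expr))
  use <- !is.na(dosage)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    use <- use & stats::complete.cases(covariates)
    covariates <- covariates[use, , drop = FALSE]
  }
  E <- expr[, use, drop = FALSE]
  dosage <- dosage[use]
  if (length(unique(dosage)) < 2L)
    stop("dosage must take at least two distinct values")
  X <- .designMatrix(ncol(E), dosage, covariates)
  n <- ncol(E)
  if (n <= ncol(X) + 1L) stop("too few samples for the design")
  qrX <- qr(X)
  B <- t(qr.coef(qrX, t(E)))          # genes x coefficients
  R <- t(E) - X %*% t(B)              # residuals, samples x genes
  dfRes <- n - ncol(X)
  sigma2 <- colSums(R^2) / dfRes
  XtXinv <- chol2inv(qr.R(qrX))
  j <- match("dosage", colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  eff <- B[, j]
  tstat <- eff / se
  p <- 2 * stats::pt(-abs(tstat), dfRes)
  p[se == 0] <- 0
  data.frame(gene = rownames(expr), effect = unname(eff),
             se = unname(se), t = unname(tstat), p = unname(p),
             adj_p = bhAdjust(unname(p)), n = n,
             stringsAsFactors = FALSE)
}

#' Seed-gene coexpression analysis
#'
#' Pearson correlation of a seed gene's expression against every other
#' gene, with Benjamini-Hochberg adjustment over all tested genes; a
#' gene is called coexpressed when |r| meets the correlation threshold
#' and its adjusted p-value is at or below the significance threshold.
#' The seed itself is excluded from the output; zero-variance genes are
#' skipped with a warning.
#'
#' @param expr genes x samples matrix of log2(TPM + 1) values.
#' @param seedGene rowname of the seed gene.
#' @param rThreshold minimum |r| (default 0.6).
#' @param adjPThreshold maximum BH-adjusted p (default 0.05).
#' @param positiveOnly if TRUE, restrict to positively correlated genes.
#' @return data.frame of the coexpressed set (gene, r, p, adj_p); the
#'   full tested table is attached as attribute \code{"tested"}.
#' @export
coexpression <- function(expr, seedGene, rThreshold = 0.6,
                         adjPThreshold = 0.05, positiveOnly = FALSE) {
  stopifnot(is.matrix(expr))
  if (!seedGene %in% rownames(expr)) stop("seed gene not found: ", seedGene)
  if (ncol(expr) < 3L) stop("at least 3 samples required")
  seed <- expr[seedGene, ]
  if (stats::sd(seed) == 0) stop("seed gene has zero variance")
  others <- setdiff(rownames(expr), seedGene)
  sds <- apply(expr[others, , drop = FALSE], 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) skipped")
    others <- others[sds > 0]
  }
  n <- ncol(expr)
  r <- as.vector(stats::cor(seed, t(expr[others, , drop = FALSE])))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  tab <- data.frame(gene = others, r = r, p = p, adj_p = bhAdjust(p),
                    stringsAsFactors = FALSE)
  sel <- abs(tab$r) >= rThreshold & tab$adj_p <= adjPThreshold
  if (positiveOnly) sel <- sel & tab$r > 0
  out <- tab[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- tab
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity
#' enforcement; order-preserving and never smaller than the nominal
#' p-value.
#'
#' @param p p-values in [0,1].
#' @return adjusted p-values, same order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}
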