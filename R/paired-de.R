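# Empirical-Bayes variance moderation for gene-wise tests.
#
# Hyperparameters (d0, s0^2) are estimated by moment matching on the log
# variances: for s^2 ~ s0^2 * F(d, d0), E[log s^2] and Var[log s^2] involve
# digamma/trigamma terms, so d0 solves trigamma(d0/2) = Var(e) -
# trigamma(d/2) with e = log s^2 - digamma(d/2) + log(d/2). Posterior
# variance is the precision-weighted blend (d0*s0^2 + d*s^2) / (d0 + d).

.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2)
        y <- y + dif
        if (-dif / y < 1e-8) break
    }
    y
}

.fitVariancePrior <- function(s2, df) {
    ok <- is.finite(s2) & s2 > 0
    if (sum(ok) < 2) return(list(df.prior = 0, s2.prior = mean(s2[ok], 1)))
    e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
    evar <- var(e) - trigamma(df / 2)
    if (!is.finite(evar) || evar <= 0)
        return(list(df.prior = Inf, s2.prior = exp(mean(e))))
    d0 <- 2 * .trigammaInverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    list(df.prior = d0, s2.prior = s0)
}

.moderateVariances <- function(s2, df, priorDf = NULL) {
    if (!is.null(priorDf) && priorDf == 0)
        return(list(s2.post = s2, df.total = df, df.prior = 0,
                    s2.prior = NA_real_))
    fit <- .fitVariancePrior(s2, df)
    d0 <- if (is.null(priorDf)) fit$df.prior else priorDf
    s0 <- fit$s2.prior
    if (is.infinite(d0)) {
        s2post <- rep(s0, length(s2))
    } else {
        s2post <- (d0 * s0 + df * s2) / (d0 + df)
    }
    list(s2.post = s2post, df.total = d0 + df, df.prior = d0, s2.prior = s0)
}

.moderatedTest <- function(effect, s2, df, seFactor, priorDf = NULL) {
    mod <- .moderateVariances(s2, df, priorDf)
    se <- sqrt(mod$s2.post * seFactor)
    t <- ifelse(se == 0, ifelse(effect == 0, 0, sign(effect) * Inf),
                effect / se)
    p <- 2 * pt(-abs(t), df = mod$df.total)
    p[se == 0 & effect == 0] <- 1
    list(t = t, p = p, df.total = mod$df.total, df.prior = mod$df.prior,
         s2.prior = mod$s2.prior, s2.post = mod$s2.post)
}

.pairedMatrices <- function(pre, on, assay = "logcounts") {
    cdP <- SummarizedExperiment::colData(pre)
    cdO <- SummarizedExperiment::colData(on)
    if (is.null(cdP$patient) || is.null(cdO$patient))
        stop("both matrices need a 'patient' column in colData")
    shared <- intersect(cdP$patient, cdO$patient)
    dropped <- setdiff(union(cdP$patient, cdO$patient), shared)
    if (length(dropped))
        warning("dropping unpaired patients: ",
                paste(dropped, collapse = ", "))
    iP <- match(shared, cdP$patient)
    iO <- match(shared, cdO$patient)
    genes <- intersect(rownames(pre), rownames(on))
    mP <- as.matrix(SummarizedExperiment::assay(pre, assay))[genes, iP,
                                                             drop = FALSE]
    mO <- as.matrix(SummarizedExperiment::assay(on, assay))[genes, iO,
                                                            drop = FALSE]
    colnames(mP) <- colnames(mO) <- shared
    list(pre = mP, on = mO, patients = shared)
}

#' Per-patient log-expression changes between paired timepoints
#'
#' Aligns two expression matrices on the shared patients and returns the
#' genes x patients matrix of on-treatment minus pre-treatment log-normalized
#' expression, the primitive behind paired differential expression,
#' signature scoring and outcome-correlation rankings.
#'
#' @param pre,on [SummarizedExperiment::SummarizedExperiment]s with a
#'   \code{patient} column in \code{colData} and the chosen assay.
#' @param assay assay name, default \code{"logcounts"}.
#' @return genes x patients matrix of paired differences.
#' @export
pairedLogChanges <- function(pre, on, assay = "logcounts") {
    pm <- .pairedMatrices(pre, on, assay)
    pm$on - pm$pre
}

#' Paired pre/on-treatment differential expression with moderated statistics
#'
#' Tests, per gene, whether log-normalized expression changes between two
#' timepoints across patients, controlling for patient-specific effects by
#' working on within-patient paired differences. The test is a paired t
#' statistic with empirical-Bayes variance shrinkage toward a pooled prior
#' (posterior variance \eqn{(d_0 s_0^2 + d s^2)/(d_0 + d)}); p-values are
#' BH-adjusted across genes and the conventional significance threshold is
#' FDR < 0.1.
#'
#' @param pre,on paired expression ([SummarizedExperiment::SummarizedExperiment])
#'   with \code{patient} in \code{colData}; typically the output of
#'   [normalizeLog()] at the PreTx and on-treatment (ICI-4W) timepoints.
#' @param assay assay to test, default \code{"logcounts"}.
#' @param priorDf prior degrees of freedom \eqn{d_0}; \code{NULL} (default)
#'   estimates it from the data, \code{0} disables moderation (classic
#'   paired t).
#' @return data.frame with one row per gene: \code{logFC} (mean paired log2
#'   change), \code{t}, \code{pvalue}, \code{fdr}, \code{meanExpr}; the
#'   estimated \code{df.prior}/\code{s2.prior} are attached as attributes.
#' @export
pairedDifferentialExpression <- function(pre, on, assay = "logcounts",
                                         priorDf = NULL) {
    pm <- .pairedMatrices(pre, on, assay)
    n <- length(pm$patients)
    if (n < 3) stop("need >= 3 complete patient pairs, got ", n)
    diffs <- pm$on - pm$pre
    lfc <- rowMeans(diffs)
    s2 <- rowSums((diffs - lfc)^2) / (n - 1)
    res <- .moderatedTest(lfc, s2, df = n - 1, seFactor = 1 / n,
                          priorDf = priorDf)
    out <- data.frame(gene = rownames(diffs), logFC = lfc, t = res$t,
                      pvalue = res$p,
                      fdr = p.adjust(res$p, method = "BH"),
                      meanExpr = rowMeans((pm$on + pm$pre) / 2),
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "df.prior") <- res$df.prior
    attr(out, "s2.prior") <- res$s2.prior
    attr(out, "nPairs") <- n
    out
}

#' Gene-wise association with a continuous per-sample covariate
#'
#' Regresses each gene's log-normalized expression on a scaled and centered
#' covariate (e.g. on-treatment tumor-size change) and reports the slope
#' with the same empirical-Bayes moderated inference as the paired test.
#' Positive slopes mean higher expression with larger covariate values.
#'
#' @param se expression at one timepoint with the chosen assay.
#' @param covariate numeric, one value per sample (column).
#' @param assay assay name, default \code{"logcounts"}.
#' @param priorDf as in [pairedDifferentialExpression()].
#' @return data.frame per gene: \code{slope}, \code{t}, \code{pvalue},
#'   \code{fdr}, \code{meanExpr}.
#' @export
covariateDifferentialExpression <- function(se, covariate,
                                            assay = "logcounts",
                                            priorDf = NULL) {
    m <- as.matrix(SummarizedExperiment::assay(se, assay))
    n <- ncol(m)
    if (n < 4) stop("need >= 4 samples")
    if (length(covariate) != n)
        stop("covariate length must equal the number of samples")
    if (sd(covariate) == 0) stop("zero-variance covariate")
    x <- .zscale(covariate)
    sxx <- sum(x^2)
    yc <- m - rowMeans(m)
    beta <- drop(yc %*% x) / sxx
    resid <- yc - outer(beta, x)
    s2 <- rowSums(resid^2) / (n - 2)
    res <- .moderatedTest(beta, s2, df = n - 2, seFactor = 1 / sxx,
                          priorDf = priorDf)
    out <- data.frame(gene = rownames(m), slope = beta, t = res$t,
                      pvalue = res$p,
                      fdr = p.adjust(res$p, method = "BH"),
                      meanExpr = rowMeans(m),
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "df.prior") <- res$df.prior
    attr(out, "s2.prior") <- res$s2.prior
    out
}
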