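#' Build a cell-type reference profile from labeled single cells
#'
#' Normalizes each cell to a common library size (linear scale), averages
#' within cell type, and selects a high-variance gene panel (variance of
#' log1p-normalized expression across cells, top \code{topN}, conventionally
#' 3000). Potentially confounding gene classes -- mitochondrial, ribosomal,
#' sex-specific and TCR/BCR variable-region genes -- are removed by ID
#' pattern before selection; rare cell types below \code{minCells} and any
#' explicitly excluded types (e.g. very rare ones) are dropped. Per-type
#' mean total RNA content \eqn{s_k} (mean library size) is recorded for
#' RNA-to-cell fraction conversion.
#'
#' @param sc a [SingleCellReference-class].
#' @param topN number of most-variable genes to keep (default 3000); values
#'   at or above the gene count keep all non-confounder genes.
#' @param excludeConfounders remove confounder gene classes first?
#' @param confounderPatterns regex patterns defining confounder gene IDs.
#' @param minCells minimum cells a type needs to be retained (default 10).
#' @param excludeTypes cell types to drop by name.
#' @param targetLibSize per-cell normalization target (default 1e4).
#' @return a [ReferenceProfile-class].
#' @export
buildReference <- function(sc, topN = 3000, excludeConfounders = TRUE,
                           confounderPatterns = c(
                               "^MT-", "^MT\\.", "^RP[SL]",
                               "^TR[ABDG][VDJC]", "^IG[HKL][VDJC]",
                               "^IGH[MGAED]", "^XIST$", "^RPS4Y",
                               "^DDX3Y", "^UTY$", "^USP9Y"),
                           minCells = 10, excludeTypes = character(),
                           targetLibSize = 1e4) {
    stopifnot(is(sc, "SingleCellReference"))
    M <- SummarizedExperiment::assay(sc, "counts")
    types <- cellType(sc)
    tab <- table(types)
    small <- names(tab)[tab < minCells]
    if (length(small))
        warning("excluding cell types below ", minCells, " cells: ",
                paste(small, collapse = ", "))
    drop <- union(small, excludeTypes)
    keep <- !(types %in% drop)
    if (!any(keep)) stop("no cell type retained")
    M <- M[, keep, drop = FALSE]
    types <- types[keep]
    mal <- unique(types[isMalignant(sc)[keep]])

    lib <- Matrix::colSums(M)
    if (any(lib == 0)) stop("cells with zero counts in reference")
    norm <- M %*% Matrix::Diagonal(x = targetLibSize / lib)
    fac <- factor(types)
    ind <- Matrix::t(Matrix::fac2sparse(fac))          # cells x types
    ind <- ind %*% Matrix::Diagonal(x = 1 / as.numeric(table(fac)))
    profiles <- as.matrix(norm %*% ind)
    colnames(profiles) <- levels(fac)
    sK <- vapply(levels(fac), function(tt) mean(lib[types == tt]),
                 numeric(1))

    geneOK <- rownames(profiles)
    if (excludeConfounders && length(confounderPatterns)) {
        bad <- Reduce(`|`, lapply(confounderPatterns, grepl, x = geneOK))
        geneOK <- geneOK[!bad]
        profiles <- profiles[geneOK, , drop = FALSE]
        norm <- norm[geneOK, , drop = FALSE]
    }
    logNorm <- norm
    logNorm@x <- log1p(logNorm@x)
    mu <- Matrix::rowMeans(logNorm)
    mu2 <- Matrix::rowMeans(logNorm^2)
    v <- pmax(0, mu2 - mu^2)
    topN <- min(topN, length(geneOK))
    sel <- geneOK[order(-v, geneOK)][seq_len(topN)]
    new("ReferenceProfile", profiles = profiles,
        rnaContent = sK, selectedGenes = sort(sel),
        malignantType = mal)
}

#' Deconvolve bulk samples by non-negative least squares
#'
#' Fits each linear-normalized bulk expression vector as a non-negative
#' combination of the reference cell-type profiles over the selected gene
#' panel (Lawson-Hanson NNLS) and renormalizes the coefficients to sum to
#' one, giving per-sample RNA fractions. The fit is scale-invariant:
#' multiplying a bulk sample by a positive constant leaves its fractions
#' unchanged.
#'
#' @param bulk genes x samples matrix on a linear-normalized scale, or a
#'   [SummarizedExperiment::SummarizedExperiment] carrying the chosen assay
#'   (default \code{"normcounts"}; run [normalizeLog()] first for raw
#'   counts).
#' @param ref a [ReferenceProfile-class].
#' @param minOverlap minimum gene overlap between bulk and the selected
#'   panel (default 100).
#' @param assay assay name when \code{bulk} is a SummarizedExperiment.
#' @return a [CompositionEstimate-class] with the RNA-fraction scale filled
#'   and per-sample residual norms.
#' @export
deconvolveNNLS <- function(bulk, ref, minOverlap = 100,
                           assay = "normcounts") {
    if (is(bulk, "SummarizedExperiment")) {
        if (!assay %in% SummarizedExperiment::assayNames(bulk))
            stop("assay '", assay, "' not found; run normalizeLog() first")
        bulk <- as.matrix(SummarizedExperiment::assay(bulk, assay))
    }
    bulk <- as.matrix(bulk)
    genes <- intersect(selectedGenes(ref), rownames(bulk))
    if (length(genes) < minOverlap)
        stop("gene overlap with reference (", length(genes),
             ") below minOverlap = ", minOverlap)
    A <- referenceProfiles(ref)[genes, , drop = FALSE]
    nT <- ncol(A)
    out <- matrix(0, ncol(bulk), nT,
                  dimnames = list(colnames(bulk), colnames(A)))
    resid <- numeric(ncol(bulk))
    for (j in seq_len(ncol(bulk))) {
        b <- bulk[genes, j]
        if (all(b == 0)) stop("all-zero bulk sample: ", colnames(bulk)[j])
        fit <- pracma::lsqnonneg(A, b)
        x <- fit$x
        if (sum(x) == 0)
            stop("degenerate NNLS fit (all-zero coefficients) for sample ",
                 colnames(bulk)[j])
        out[j, ] <- x / sum(x)
        resid[j] <- sqrt(sum((A %*% x - b)^2))
    }
    new("CompositionEstimate", rnaFraction = out,
        cellFraction = matrix(numeric(0), 0, 0), residual = resid)
}

#' Convert RNA fractions to cell fractions via per-type RNA content
#'
#' Cell types differ in RNA per cell, so a type's share of transcript mass
#' overstates (large cells) or understates (small cells) its share of
#' cells. The conversion is
#' \eqn{f_{cell,k} = (f_{rna,k}/s_k) / \sum_j (f_{rna,j}/s_j)} with
#' \eqn{s_k} the mean per-cell RNA content of type k.
#'
#' @param x RNA-fraction vector (summing to 1) or a
#'   [CompositionEstimate-class].
#' @param s per-type RNA content: a named positive vector or a
#'   [ReferenceProfile-class] (its \code{rnaContent}).
#' @return cell-fraction vector, or the CompositionEstimate with its
#'   cell-fraction scale filled.
#' @examples
#' rnaToCellFraction(c(a = 0.5, b = 0.5), c(a = 2, b = 1))  # 1/3, 2/3
#' @export
setGeneric("rnaToCellFraction",
           function(x, s) standardGeneric("rnaToCellFraction"))

#' @rdname rnaToCellFraction
#' @export
setMethod("rnaToCellFraction", signature("numeric", "numeric"),
          function(x, s) {
    if (length(x) != length(s))
        stop("fraction and RNA-content vectors must have equal length")
    if (any(s <= 0 & x > 0))
        stop("non-positive RNA content for a type with positive fraction")
    w <- ifelse(x > 0, x / s, 0)
    tot <- sum(w)
    if (tot == 0) stop("zero denominator: all fractions are zero")
    w / tot
})

#' @rdname rnaToCellFraction
#' @export
setMethod("rnaToCellFraction", signature("CompositionEstimate", "numeric"),
          function(x, s) {
    fr <- rnaFraction(x)
    s <- s[colnames(fr)]
    if (anyNA(s)) stop("RNA content missing for some cell types")
    cf <- t(apply(fr, 1, rnaToCellFraction, s = s))
    dimnames(cf) <- dimnames(fr)
    methods::initialize(x, cellFraction = cf)
})

#' @rdname rnaToCellFraction
#' @export
setMethod("rnaToCellFraction",
          signature("CompositionEstimate", "ReferenceProfile"),
          function(x, s) rnaToCellFraction(x, rnaContent(s)))

#' Benchmark deconvolution methods against pseudobulk ground truth
#'
#' Runs each registered method on the panel and scores it per sample by
#' Spearman correlation across cell types and by NRMSE (RMSE divided by the
#' range of predicted values), against both the RNA-proportion and the
#' cell-proportion truth. Methods are ranked by median NRMSE, then median
#' Spearman. A method's RNA-fraction output is used for both scales unless
#' it also fills the cell-fraction scale.
#'
#' @param methods named list of functions taking the bulk object and
#'   returning a [CompositionEstimate-class].
#' @param panel output of [simulatePseudobulkPanel()] (or a list with
#'   \code{bulk} and \code{truth}).
#' @return list with \code{perSample} (method, sample, scale, spearman,
#'   nrmse, degenerate flag), \code{summary} (medians per method and
#'   scale) and \code{ranking} (methods ordered best-first on the RNA
#'   scale).
#' @export
benchmarkDeconvolution <- function(methods, panel) {
    stopifnot(length(methods) >= 1, !is.null(names(methods)))
    truth <- panel$truth
    rows <- list()
    for (nm in names(methods)) {
        est <- methods[[nm]](panel$bulk)
        predRna <- rnaFraction(est)
        predCell <- if (nrow(est@cellFraction)) est@cellFraction else predRna
        for (scale in c("rna", "cell")) {
            pred <- if (scale == "rna") predRna else predCell
            tr <- if (scale == "rna") truth$rnaFraction
                  else truth$cellFraction
            shared <- intersect(colnames(pred), colnames(tr))
            if (length(shared) < 3)
                stop("fewer than 3 shared cell types between prediction ",
                     "and truth")
            for (i in seq_len(nrow(tr))) {
                p <- pred[i, shared]; tv <- tr[i, shared]
                rng <- max(p) - min(p)
                degen <- sd(p) == 0 || rng == 0
                rho <- if (sd(p) == 0) NA_real_ else
                    suppressWarnings(cor(p, tv, method = "spearman"))
                nrmse <- if (rng == 0) NA_real_ else
                    sqrt(mean((p - tv)^2)) / rng
                rows[[length(rows) + 1L]] <- data.frame(
                    method = nm, sample = rownames(tr)[i], scale = scale,
                    spearman = rho, nrmse = nrmse, degenerate = degen,
                    stringsAsFactors = FALSE)
            }
        }
    }
    perSample <- do.call(rbind, rows)
    summ <- aggregate(cbind(spearman, nrmse) ~ method + scale,
                      data = perSample, FUN = median, na.rm = TRUE,
                      na.action = NULL)
    names(summ)[3:4] <- c("medianSpearman", "medianNRMSE")
    rnaSumm <- summ[summ$scale == "rna", ]
    ranking <- rnaSumm$method[order(rnaSumm$medianNRMSE,
                                    -rnaSumm$medianSpearman)]
    list(perSample = perSample, summary = summ, ranking = ranking)
}

#' Extract tumor monocyte content (TMC) from a composition estimate
#'
#' TMC is the monocyte fraction of a bulk tumor transcriptome (RNA-fraction
#' scale by default, the scale the spike-in experiment validates). Zero
#' fractions are floored before log10 at half the smallest nonzero fraction
#' (or a supplied \code{floor}) so median splits stay well defined.
#'
#' @param comp a [CompositionEstimate-class].
#' @param monocyteLabel composition column holding monocytes.
#' @param scale \code{"rna"} (default) or \code{"cell"}.
#' @param floor optional floor for log10 of zero fractions.
#' @return data.frame per sample: \code{tmc}, \code{log10Tmc},
#'   \code{floored}.
#' @export
extractTMC <- function(comp, monocyteLabel = "Monocyte",
                       scale = c("rna", "cell"), floor = NULL) {
    scale <- match.arg(scale)
    m <- if (scale == "rna") rnaFraction(comp) else cellFraction(comp)
    if (!monocyteLabel %in% colnames(m))
        stop("monocyte label '", monocyteLabel,
             "' not found in composition columns")
    tmc <- m[, monocyteLabel]
    if (is.null(floor)) {
        pos <- tmc[tmc > 0]
        floor <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
    }
    floored <- tmc < floor
    data.frame(sample = rownames(m), tmc = tmc,
               log10Tmc = log10(pmax(tmc, floor)), floored = floored,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchically cluster samples on a cellular compartment
#'
#' Log10-transforms the per-sample fractions of the chosen cell types
#' (floored for zeros), Z-scores each column, and clusters samples with
#' Ward minimum-variance linkage (\code{ward.D}) on Euclidean distances --
#' the procedure that isolates e.g. a monocyte-high cluster within the
#' phagocytic compartment. Constant columns are dropped with a warning.
#'
#' @param comp a [CompositionEstimate-class] or samples x types matrix.
#' @param types compartment cell types (default: all columns).
#' @param k clusters to cut (default 2).
#' @param scale \code{"rna"} or \code{"cell"} when \code{comp} is a
#'   CompositionEstimate.
#' @param floor optional log10 floor as in [extractTMC()].
#' @return list with \code{hclust}, \code{clusters} (named integer) and
#'   \code{scaled} (the clustered matrix).
#' @export
clusterCompartment <- function(comp, types = NULL, k = 2,
                               scale = c("rna", "cell"), floor = NULL) {
    scale <- match.arg(scale)
    m <- if (is(comp, "CompositionEstimate")) {
        if (scale == "rna") rnaFraction(comp) else cellFraction(comp)
    } else as.matrix(comp)
    if (!is.null(types)) {
        miss <- setdiff(types, colnames(m))
        if (length(miss)) stop("cell types not in composition: ",
                               paste(miss, collapse = ", "))
        m <- m[, types, drop = FALSE]
    }
    if (nrow(m) < 3) stop("need >= 3 samples to cluster")
    if (is.null(floor)) {
        pos <- m[m > 0]
        floor <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
    }
    lm10 <- log10(pmax(m, floor))
    sds <- apply(lm10, 2, sd)
    if (any(sds == 0)) {
        warning("dropping constant columns: ",
                paste(colnames(lm10)[sds == 0], collapse = ", "))
        lm10 <- lm10[, sds > 0, drop = FALSE]
        if (!ncol(lm10)) stop("no variable columns left")
    }
    z <- scale(lm10)
    hc <- hclust(dist(z), method = "ward.D")
    clusters <- cutree(hc, k = k)
    names(clusters) <- rownames(m)
    list(hclust = hc, clusters = clusters, scaled = z)
}

#' Validate deconvolution-assessed TMC against known spike-in fractions
#'
#' Deconvolves a monocyte spike-in series and regresses estimated TMC on
#' the known spiked fraction (with the source biopsy as a fixed effect when
#' given), reporting the slope and its p-value. A positive, significant
#' slope shows the TMC readout tracks true monocyte RNA content.
#'
#' @param spiked [SummarizedExperiment::SummarizedExperiment] with a
#'   linear-scale assay and \code{fraction} (and optionally \code{biopsy})
#'   in \code{colData}; e.g. from [simulateSpikeIn()].
#' @param ref a [ReferenceProfile-class].
#' @param monocyteLabel monocyte column name.
#' @param assay assay name (default \code{"normcounts"}).
#' @param minOverlap passed to [deconvolveNNLS()].
#' @return list with \code{slope}, \code{pvalue}, \code{fit} (the lm) and
#'   \code{tmc} (per-sample estimates).
#' @export
spikeInValidation <- function(spiked, ref, monocyteLabel = "Monocyte",
                              assay = "normcounts", minOverlap = 100) {
    cd <- SummarizedExperiment::colData(spiked)
    if (is.null(cd$fraction)) stop("colData must contain 'fraction'")
    f <- cd$fraction
    if (length(unique(f)) < 2)
        stop("need >= 2 distinct spike levels to estimate a slope")
    if (length(unique(f)) < 3)
        warning("fewer than 3 spike levels; slope estimate is fragile")
    comp <- deconvolveNNLS(spiked, ref, minOverlap = minOverlap,
                           assay = assay)
    tmc <- extractTMC(comp, monocyteLabel)$tmc
    dat <- data.frame(tmc = tmc, fraction = f)
    if (!is.null(cd$biopsy) && length(unique(cd$biopsy)) > 1) {
        dat$biopsy <- factor(cd$biopsy)
        fit <- lm(tmc ~ fraction + biopsy, data = dat)
    } else {
        fit <- lm(tmc ~ fraction, data = dat)
    }
    sm <- summary(fit)$coefficients
    list(slope = sm["fraction", "Estimate"],
         pvalue = sm["fraction", "Pr(>|t|)"],
         fit = fit,
         tmc = setNames(tmc, rownames(cd)))
}
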