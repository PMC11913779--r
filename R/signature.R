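#' Derive a top-k treatment-responsive gene signature
#'
#' Takes the genes significant at \code{fdrThreshold} from a paired
#' differential-expression result and keeps the top \code{k} by
#' significance, ordered by ascending FDR, then ascending p, then
#' descending |log fold change|, then gene ID (fully deterministic).
#' With the conventional defaults this yields a 70-gene on-treatment
#' signature dominated by T/NK and cytotoxic inflammation markers.
#'
#' @param de result of [pairedDifferentialExpression()].
#' @param k signature size (default 70). If fewer genes pass the FDR
#'   threshold, the signature is truncated with a warning.
#' @param fdrThreshold significance threshold (default 0.1).
#' @param name signature name.
#' @return a [GeneSignature-class]; direction is the sign of the log fold
#'   change and the selection statistic is the log fold change.
#' @export
deriveSignature <- function(de, k = 70, fdrThreshold = 0.1,
                            name = "INCITE-like") {
    sig <- de[de$fdr < fdrThreshold & is.finite(de$fdr), , drop = FALSE]
    if (!nrow(sig))
        stop("no genes pass FDR < ", fdrThreshold, "; cannot derive signature")
    ord <- order(sig$fdr, sig$pvalue, -abs(sig$logFC), sig$gene)
    sig <- sig[ord, , drop = FALSE]
    if (k > nrow(sig)) {
        warning("only ", nrow(sig), " genes pass FDR < ", fdrThreshold,
                "; truncating signature from k = ", k)
        k <- nrow(sig)
    }
    sig <- sig[seq_len(k), , drop = FALSE]
    new("GeneSignature", name = name, genes = sig$gene,
        direction = sign(sig$logFC), stat = sig$logFC)
}

#' Score per-patient on-treatment signature upregulation
#'
#' For each paired patient, the mean over signature genes of the
#' on-treatment minus pre-treatment log-normalized expression, divided by
#' the cohort standard deviation of that mean ("scaled, without centering"
#' -- no mean subtraction, so the sign of the change is preserved).
#'
#' @param pre,on paired expression with \code{patient} in \code{colData}.
#' @param sig a [GeneSignature-class]; signature genes missing from the
#'   matrices are dropped with a warning.
#' @param assay assay name, default \code{"logcounts"}.
#' @return named numeric score per patient.
#' @export
scoreSignatureChange <- function(pre, on, sig, assay = "logcounts") {
    changes <- pairedLogChanges(pre, on, assay)
    genes <- signatureGenes(sig)
    miss <- setdiff(genes, rownames(changes))
    if (length(miss)) {
        warning("dropping ", length(miss),
                " signature genes absent from the expression data")
        genes <- setdiff(genes, miss)
    }
    if (!length(genes)) stop("no signature genes present")
    raw <- colMeans(changes[genes, , drop = FALSE])
    s <- sd(raw)
    if (!is.finite(s) || s == 0)
        stop("degenerate cohort: zero variance of mean signature change")
    raw / s
}

#' Split patients into reactive and quiescent groups by signature score
#'
#' Splits at the cohort median score: patients at or above the median are
#' labeled \code{"reactive"}, the rest \code{"quiescent"} (ties go to
#' reactive, so random continuous scores give exactly ceiling(n/2) reactive
#' patients). The full score ordering is returned alongside the labels.
#'
#' @param scores named per-patient numeric scores (>= 2 patients).
#' @return data.frame sorted by decreasing score with columns
#'   \code{patient}, \code{score}, \code{rank}, \code{label}.
#' @export
classifyReactivity <- function(scores) {
    if (length(scores) < 2) stop("need >= 2 patients")
    if (is.null(names(scores)))
        names(scores) <- paste0("patient", seq_along(scores))
    med <- median(scores)
    if (all(scores == scores[1]))
        warning("all scores identical; every patient labeled reactive")
    lab <- ifelse(scores >= med, "reactive", "quiescent")
    ord <- order(-scores, names(scores))
    data.frame(patient = names(scores)[ord], score = scores[ord],
               rank = seq_along(scores),
               label = factor(lab[ord], levels = c("reactive", "quiescent")),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Noise-robustness of signature prefixes (compact-subset selection)
#'
#' For each prefix size k of the ranked signature, correlates the k-gene
#' change score with an outcome (e.g. tumor-size change) both as-is and
#' after adding Gaussian noise to the per-gene changes (averaged over a grid
#' of noise SDs and \code{reps} replicates). The selected compact signature
#' is the smallest k whose noise-degraded correlation retains at least
#' \code{retention} of the full-signature correlation magnitude with the
#' same sign -- the route from a 70-gene signature to a noise-robust
#' ~12-gene subset.
#'
#' @param sig a [GeneSignature-class] (ranked).
#' @param changes genes x patients matrix from [pairedLogChanges()].
#' @param outcome numeric per-patient outcome aligned to \code{changes}
#'   columns.
#' @param sizes prefix sizes to test; default 1..length(signature).
#' @param noiseSdGrid Gaussian noise SDs added to per-gene changes.
#' @param reps noise replicates per SD (warning below 10).
#' @param retention fraction of the full-signature correlation that must be
#'   retained (default 0.9).
#' @param seed optional seed for the noise draws.
#' @return list with \code{table} (size, correlation, noisyCorrelation),
#'   \code{selectedSize} and \code{fullCorrelation}.
#' @export
subsetRobustness <- function(sig, changes, outcome, sizes = NULL,
                             noiseSdGrid = c(0.25, 0.5, 1), reps = 50,
                             retention = 0.9, seed = NULL) {
    if (reps < 10) warning("reps < 10 gives unstable robustness estimates")
    genes <- intersect(signatureGenes(sig), rownames(changes))
    if (!length(genes)) stop("no signature genes present in changes")
    if (is.null(sizes)) sizes <- seq_along(genes)
    sizes <- sizes[sizes >= 1 & sizes <= length(genes)]
    if (!is.null(seed)) set.seed(seed)
    m <- changes[genes, , drop = FALSE]
    np <- ncol(m)
    fullCor <- cor(colMeans(m), outcome)
    corK <- noisyK <- numeric(length(sizes))
    for (j in seq_along(sizes)) {
        k <- sizes[j]
        sub <- m[seq_len(k), , drop = FALSE]
        corK[j] <- cor(colMeans(sub), outcome)
        acc <- 0
        for (sdv in noiseSdGrid) {
            for (r in seq_len(reps)) {
                noisy <- sub + matrix(rnorm(length(sub), 0, sdv), nrow = k)
                acc <- acc + cor(colMeans(noisy), outcome)
            }
        }
        noisyK[j] <- acc / (reps * length(noiseSdGrid))
    }
    keep <- sign(noisyK) == sign(fullCor) &
        abs(noisyK) >= retention * abs(fullCor)
    selected <- if (any(keep)) min(sizes[keep]) else NA_integer_
    list(table = data.frame(size = sizes, correlation = corK,
                            noisyCorrelation = noisyK),
         selectedSize = selected, fullCorrelation = fullCor)
}

#' Mean Z-scored expression of a gene set per sample
#'
#' Z-scores each set gene's log-normalized expression across samples and
#' averages over set genes -- a generic single-sample module score used to
#' compare external inflammatory/resistance signatures.
#'
#' @param se expression with the chosen assay.
#' @param genes character vector of set genes; missing genes are dropped
#'   with a warning, constant genes (zero SD) likewise.
#' @param assay assay name, default \code{"logcounts"}.
#' @return named numeric score per sample.
#' @export
geneSetScore <- function(se, genes, assay = "logcounts") {
    m <- as.matrix(SummarizedExperiment::assay(se, assay))
    present <- intersect(genes, rownames(m))
    if (!length(present)) stop("no gene of the set is present")
    if (length(present) < length(genes))
        warning("dropping ", length(genes) - length(present),
                " set genes absent from the expression data")
    sub <- m[present, , drop = FALSE]
    sds <- apply(sub, 1, sd)
    if (any(sds == 0)) {
        warning("dropping ", sum(sds == 0), " constant set genes")
        sub <- sub[sds > 0, , drop = FALSE]
        if (!nrow(sub)) stop("all set genes are constant across samples")
        sds <- sds[sds > 0]
    }
    z <- (sub - rowMeans(sub)) / sds
    colMeans(z)
}

#' Aggregate single cells into pseudobulk samples
#'
#' Sums raw counts over all cells of each group (sample/patient, optionally
#' restricted to one cell type first), producing pseudobulk profiles for
#' cell-type-specific outcome differential expression.
#'
#' @param sc a [SingleCellReference-class].
#' @param groupBy colData column(s) defining the groups (default
#'   \code{"patient"}).
#' @param cellType optional single cell type to restrict to before
#'   summation; patients with no cells of that type are omitted with a
#'   warning.
#' @return [SummarizedExperiment::SummarizedExperiment] of summed counts,
#'   one column per group.
#' @export
pseudobulkAggregate <- function(sc, groupBy = "patient", cellType = NULL) {
    cd <- SummarizedExperiment::colData(sc)
    miss <- setdiff(groupBy, colnames(cd))
    if (length(miss))
        stop("grouping column(s) not in colData: ",
             paste(miss, collapse = ", "))
    keep <- rep(TRUE, ncol(sc))
    if (!is.null(cellType)) {
        keep <- cd$cellType == cellType
        if (!any(keep)) stop("no cells of type ", cellType)
        lost <- setdiff(unique(interaction(as.data.frame(cd[, groupBy,
                                                            drop = FALSE]),
                                           drop = TRUE)),
                        unique(interaction(as.data.frame(cd[keep, groupBy,
                                                            drop = FALSE]),
                                           drop = TRUE)))
        if (length(lost))
            warning("omitting groups with 0 cells of type ", cellType, ": ",
                    paste(lost, collapse = ", "))
    }
    sub <- sc[, keep]
    grp <- interaction(as.data.frame(
        SummarizedExperiment::colData(sub)[, groupBy, drop = FALSE]),
        drop = TRUE, sep = "_")
    M <- SummarizedExperiment::assay(sub, "counts")
    agg <- as.matrix(M %*% Matrix::t(Matrix::fac2sparse(grp)))
    colnames(agg) <- levels(grp)
    cdSub <- as.data.frame(
        SummarizedExperiment::colData(sub)[, groupBy, drop = FALSE])
    info <- unique(cbind(group = as.character(grp), cdSub))
    info <- info[match(levels(grp), info$group), , drop = FALSE]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = agg),
        colData = S4Vectors::DataFrame(info, row.names = levels(grp)))
}
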