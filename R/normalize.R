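#' Median-of-ratios size factors
#'
#' Computes one size factor per sample as the median, over genes expressed
#' in every sample, of the ratio of the sample's count to the gene's
#' geometric mean across samples. This is the standard count normalization
#' for bulk RNA-seq; genes with any zero are excluded from the median.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return numeric size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' sizeFactorsMoR(m)   # 1/sqrt(2), sqrt(2)
#' @export
sizeFactorsMoR <- function(counts) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 2) stop("need >= 2 samples for size factors")
    if (any(counts < 0)) stop("counts must be non-negative")
    allPos <- rowSums(counts > 0) == ncol(counts)
    if (!any(allPos))
        stop("every gene contains a zero; median-of-ratios is undefined. ",
             "Filter genes or use a pseudo-reference approach.")
    logGeo <- rowMeans(log(counts[allPos, , drop = FALSE]))
    apply(counts[allPos, , drop = FALSE], 2, function(x)
        exp(median(log(x) - logGeo)))
}

#' Normalize counts and add linear and log-scale assays
#'
#' Divides counts by median-of-ratios size factors (\code{"normcounts"},
#' the linear scale used for deconvolution) and adds
#' \code{log2(normalized + 1)} (\code{"logcounts"}, the variance-stabilized
#' scale used for differential expression and signature scoring).
#'
#' @param se [SummarizedExperiment::SummarizedExperiment] with a
#'   \code{"counts"} assay (or a bare matrix).
#' @return the input with \code{"normcounts"} and \code{"logcounts"} assays
#'   added and size factors stored in \code{metadata()$sizeFactors}.
#' @export
normalizeLog <- function(se) {
    if (is.matrix(se) || is(se, "Matrix"))
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = as.matrix(se)))
    counts <- as.matrix(SummarizedExperiment::assay(se, "counts"))
    sf <- sizeFactorsMoR(counts)
    norm <- sweep(counts, 2, sf, "/")
    SummarizedExperiment::assay(se, "normcounts") <- norm
    SummarizedExperiment::assay(se, "logcounts") <- log2(norm + 1)
    S4Vectors::metadata(se)$sizeFactors <- sf
    se
}
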