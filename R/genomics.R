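#' Consensus-filter a mutation table across variant callers
#'
#' Retains variants supported by at least \code{minCallers} of the callers
#' (the conventional 2-of-3 consensus rule). The caller support of each
#' record is read from a \code{callers} column holding comma-separated
#' caller names (or a list column of character vectors).
#'
#' @param mutations data.frame with at least \code{patient}, \code{biopsy},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{callers}.
#' @param minCallers minimum supporting callers (default 2).
#' @return the filtered data.frame with an added integer \code{nCallers}
#'   column; idempotent, and monotone (non-increasing) in \code{minCallers}.
#' @examples
#' tab <- data.frame(patient = "P1", biopsy = "b1", chrom = "1",
#'                   pos = 1:3, ref = "A", alt = "T",
#'                   nonsynonymous = TRUE,
#'                   callers = c("A,B,C", "A", "B,C"))
#' consensusFilter(tab)          # keeps rows 1 and 3
#' @export
consensusFilter <- function(mutations, minCallers = 2) {
    if (!"callers" %in% names(mutations))
        stop("mutation table needs a 'callers' column")
    lst <- if (is.list(mutations$callers)) mutations$callers
           else strsplit(as.character(mutations$callers), "[,;]\\s*")
    lst <- lapply(lst, unique)
    n <- vapply(lst, length, 1L)
    if (any(n == 0)) stop("empty caller set in mutation table")
    distinct <- length(unique(unlist(lst)))
    if (minCallers > distinct)
        warning("minCallers (", minCallers, ") exceeds the ", distinct,
                " distinct callers present; result may be empty")
    out <- mutations[n >= minCallers, , drop = FALSE]
    out$nCallers <- n[n >= minCallers]
    rownames(out) <- NULL
    out
}

#' Tumor mutational burden per patient
#'
#' TMB is the number of nonsynonymous coding mutations per megabase of
#' coding space (35.6 Mb by default, the protein-coding exon total of a
#' current human annotation). TMB is computed per biopsy and averaged
#' across each patient's biopsies. Biopsies present in \code{biopsies} (or,
#' by default, in the unfiltered table) but contributing no qualifying
#' mutations count as TMB 0.
#'
#' @param mutations (consensus-filtered) mutation table with
#'   \code{patient}, \code{biopsy} and a logical \code{nonsynonymous}
#'   column flagging nonsynonymous coding variants.
#' @param codingSpaceMb coding-space size in Mb (default 35.6).
#' @param biopsies optional data.frame (\code{patient}, \code{biopsy})
#'   enumerating all sequenced biopsies, so zero-mutation biopsies count.
#' @return data.frame per patient: \code{tmb}, \code{nMutations},
#'   \code{nBiopsies}.
#' @examples
#' tab <- data.frame(patient = "P1", biopsy = "b1",
#'                   nonsynonymous = rep(TRUE, 356))
#' computeTMB(tab)$tmb   # 10
#' @export
computeTMB <- function(mutations, codingSpaceMb = 35.6, biopsies = NULL) {
    stopifnot(codingSpaceMb > 0)
    need <- c("patient", "biopsy", "nonsynonymous")
    miss <- setdiff(need, names(mutations))
    if (length(miss)) stop("mutation table lacks column(s): ",
                           paste(miss, collapse = ", "))
    if (is.null(biopsies))
        biopsies <- unique(mutations[, c("patient", "biopsy")])
    biopsies <- unique(biopsies[, c("patient", "biopsy")])
    ns <- mutations[mutations$nonsynonymous, , drop = FALSE]
    key <- paste(biopsies$patient, biopsies$biopsy, sep = "\r")
    cnt <- table(factor(paste(ns$patient, ns$biopsy, sep = "\r"),
                        levels = key))
    perBiopsy <- data.frame(patient = biopsies$patient,
                            tmb = as.numeric(cnt) / codingSpaceMb)
    out <- aggregate(tmb ~ patient, data = perBiopsy, FUN = mean)
    nm <- aggregate(nonsynonymous ~ patient, data = mutations, FUN = sum)
    names(nm)[2] <- "nMutations"
    nb <- aggregate(biopsy ~ patient, data = biopsies,
                    FUN = function(b) length(unique(b)))
    names(nb)[2] <- "nBiopsies"
    out <- merge(merge(out, nm, all.x = TRUE), nb, all.x = TRUE)
    out$nMutations[is.na(out$nMutations)] <- 0L
    out
}

#' Classify microsatellite instability from an MSI score
#'
#' A tumor is MSI if its MSIsensor-type score is at least the threshold
#' (3.5 by default; the boundary is inclusive).
#'
#' @param score non-negative MSI score(s).
#' @param threshold classification threshold (default 3.5).
#' @return logical MSI flag(s).
#' @export
classifyMSI <- function(score, threshold = 3.5) {
    if (any(score < 0, na.rm = TRUE)) stop("MSI scores must be non-negative")
    score >= threshold
}

#' Classify gene copy-number state relative to ploidy
#'
#' Amplified if copies exceed twice the ploidy-adjusted baseline; deleted
#' if more than half the baseline gene copies are lost (baseline taken as
#' the tumor ploidy); neutral otherwise. The three classes are exhaustive
#' and mutually exclusive.
#'
#' @param copies non-negative gene copy number(s).
#' @param ploidy tumor ploidy (> 0), recycled.
#' @return factor with levels amplified / neutral / deleted.
#' @examples
#' classifyCNA(c(5, 2, 0.9), ploidy = 2)
#' @export
classifyCNA <- function(copies, ploidy) {
    if (any(ploidy <= 0)) stop("ploidy must be positive")
    if (any(copies < 0)) stop("copies must be non-negative")
    amp <- copies > 2 * ploidy
    del <- (ploidy - copies) > ploidy / 2
    factor(ifelse(amp, "amplified", ifelse(del, "deleted", "neutral")),
           levels = c("amplified", "neutral", "deleted"))
}
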