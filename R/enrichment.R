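#' Rank genes by correlation of expression change with an outcome
#'
#' Computes, per gene, the Pearson correlation between on-treatment
#' expression changes and a per-patient outcome (e.g. tumor-size change),
#' and returns the genes ordered by decreasing correlation -- the ranking
#' used for outcome-anchored gene-set enrichment. Constant gene rows get
#' r = 0 with a warning; ties are broken lexicographically by gene ID.
#'
#' @param changes genes x patients matrix ([pairedLogChanges()]).
#' @param outcome numeric per-patient outcome aligned to columns.
#' @return named numeric vector of correlations, sorted decreasing.
#' @export
correlationRanking <- function(changes, outcome) {
    if (ncol(changes) < 3) stop("need >= 3 patients")
    if (length(outcome) != ncol(changes))
        stop("outcome length must equal the number of patients")
    sds <- apply(changes, 1, sd)
    r <- rep(0, nrow(changes))
    names(r) <- rownames(changes)
    if (any(sds == 0))
        warning(sum(sds == 0), " constant gene rows; correlation set to 0")
    ok <- sds > 0
    r[ok] <- suppressWarnings(
        apply(changes[ok, , drop = FALSE], 1, cor, y = outcome))
    r[order(-r, names(r))]
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, genes...).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

# Weighted Kolmogorov-Smirnov running-sum enrichment score for a set given
# by its positions in the ranked statistic vector. Hit increments are
# proportional to |stat|^weight, miss decrements are 1/(N - |S|); the ES is
# the extreme deviation of the running sum.
.gseaES <- function(stat, hitIdx, weight = 1) {
    N <- length(stat)
    m <- length(hitIdx)
    incr <- rep(-1 / (N - m), N)
    w <- abs(stat[hitIdx])^weight
    if (sum(w) == 0) w <- rep(1, m)
    incr[hitIdx] <- w / sum(w)
    running <- cumsum(incr)
    peak <- which.max(abs(running))
    list(es = running[peak], peak = peak)
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' Computes the weighted Kolmogorov-Smirnov enrichment score (ES) of each
#' set against a ranked gene list, a permutation p-value from random
#' same-size gene sets, and a normalized enrichment score (NES = ES divided
#' by the mean |ES| of same-sign null sets, following the original GSEA
#' convention of separate positive/negative null pools). When the number of
#' possible same-size sets is no larger than \code{nPerm} the null is
#' enumerated exhaustively, making the p-value exact at small scale;
#' otherwise the minimum attainable p is 1/(nPerm + 1). BH FDR is computed
#' across sets.
#'
#' @param stats named statistic vector; ranked descending internally with
#'   lexicographic tie-break.
#' @param sets named list of gene sets; sets intersecting the ranking
#'   outside [\code{minSize}, \code{maxSize}] are skipped and reported.
#' @param nPerm permutations per set (default 1000).
#' @param weight exponent on |stat| for hit increments (default 1; 0 gives
#'   the unweighted KS statistic).
#' @param minSize,maxSize set-size bounds after intersection.
#' @param seed optional seed; same seed gives identical p/NES.
#' @return data.frame per scored set: \code{pathway}, \code{size},
#'   \code{ES}, \code{NES}, \code{pvalue}, \code{fdr},
#'   \code{leadingEdge} (semicolon-separated); skipped sets are recorded in
#'   attribute \code{"skipped"}.
#' @export
prerankedGSEA <- function(stats, sets, nPerm = 1000, weight = 1,
                          minSize = 2, maxSize = 500, seed = NULL) {
    if (is.null(names(stats))) stop("stats must be named by gene")
    ord <- order(-stats, names(stats))
    stat <- stats[ord]
    genes <- names(stat)
    N <- length(stat)
    if (!is.null(seed)) set.seed(seed)
    rows <- list()
    skipped <- character()
    for (nm in names(sets)) {
        hit <- which(genes %in% sets[[nm]])
        m <- length(hit)
        if (m < minSize || m > maxSize || m >= N) {
            skipped <- c(skipped, nm)
            next
        }
        obs <- .gseaES(stat, hit, weight)
        exhaustive <- choose(N, m) <= nPerm
        nullES <- if (exhaustive) {
            apply(utils::combn(N, m), 2, function(ix)
                .gseaES(stat, ix, weight)$es)
        } else {
            vapply(seq_len(nPerm), function(i)
                .gseaES(stat, sort(sample.int(N, m)), weight)$es,
                numeric(1))
        }
        same <- sign(nullES) == sign(obs$es)
        # tolerance guards exact ES ties against last-ulp rounding
        p <- (1 + sum(abs(nullES[same]) >= abs(obs$es) - 1e-10)) /
            (1 + sum(same))
        nes <- if (any(same)) obs$es / mean(abs(nullES[same])) else NA_real_
        le <- if (obs$es >= 0) genes[hit[hit <= obs$peak]]
              else genes[hit[hit >= obs$peak]]
        rows[[nm]] <- data.frame(pathway = nm, size = m, ES = obs$es,
                                 NES = nes, pvalue = p,
                                 leadingEdge = paste(le, collapse = ";"),
                                 stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
        out <- data.frame(pathway = character(), size = integer(),
                          ES = numeric(), NES = numeric(),
                          pvalue = numeric(), fdr = numeric(),
                          leadingEdge = character())
    } else {
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out$fdr <- p.adjust(out$pvalue, method = "BH")
        out <- out[, c("pathway", "size", "ES", "NES", "pvalue", "fdr",
                       "leadingEdge")]
    }
    attr(out, "skipped") <- skipped
    out
}
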