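#' Classify immune-related radiological response (irRECIST-style)
#'
#' Assigns per-patient best-overall-response categories from percent
#' changes in target-lesion burden relative to pre-treatment: response is a
#' >= 30% reduction (irCR when the burden reaches -100%, irPR otherwise,
#' boundary inclusive); progression (irPD) is a >= 20% increase or
#' unequivocal new lesions; everything else is irSD (irNN is mapped to
#' irSD). Patients with clinical progression and no evaluable scan are
#' irPD; patients with neither scans nor a clinical-progression override
#' are not assessable (NA category, with a warning).
#'
#' @param bestChange best (most negative) percent change per patient; NA
#'   for no evaluable scan.
#' @param worstChange worst (largest) percent change per patient; defaults
#'   to \code{bestChange} when only one assessment exists.
#' @param newLesions logical, unequivocal new lesions.
#' @param clinicalProgression logical, clinical progression without scans.
#' @return list with \code{category} (factor irCR/irPR/irSD/irPD, NA = not
#'   assessable) and \code{responder} (logical).
#' @examples
#' classifyResponse(c(-100, -30, 5), worstChange = c(-100, -30, 5))
#' @export
classifyResponse <- function(bestChange, worstChange = bestChange,
                             newLesions = FALSE,
                             clinicalProgression = FALSE) {
    n <- length(bestChange)
    newLesions <- rep_len(newLesions, n)
    clinicalProgression <- rep_len(clinicalProgression, n)
    worstChange <- rep_len(worstChange, n)
    cat <- character(n)
    for (i in seq_len(n)) {
        if (is.na(bestChange[i])) {
            cat[i] <- if (clinicalProgression[i]) "irPD" else NA_character_
        } else if (bestChange[i] <= -100) {
            cat[i] <- "irCR"
        } else if (bestChange[i] <= -30) {
            cat[i] <- "irPR"
        } else if ((!is.na(worstChange[i]) && worstChange[i] >= 20) ||
                   newLesions[i]) {
            cat[i] <- "irPD"
        } else {
            cat[i] <- "irSD"
        }
    }
    if (anyNA(cat))
        warning(sum(is.na(cat)), " patient(s) not assessable ",
                "(no scans, no clinical-progression override)")
    category <- factor(cat, levels = c("irCR", "irPR", "irSD", "irPD"))
    list(category = category,
         responder = category %in% c("irCR", "irPR") & !is.na(category))
}

#' Classify clinical benefit from progression-free survival
#'
#' Clinical benefit (CB) means attaining \code{horizon} months of PFS
#' (default 12): patients progression-free at the horizon are CB, patients
#' with progression or death before it are NCB, and patients censored
#' before the horizon without progression -- or explicitly excluded, e.g.
#' for switching to alternative therapy -- are not assessable.
#'
#' @param pfsTime PFS time in months.
#' @param pfsEvent event flag (1 = progression/death, 0 = censored).
#' @param horizon CB horizon in months (default 12).
#' @param excluded logical, patients excluded from CB analyses.
#' @return factor with levels CB / NCB / not assessable.
#' @examples
#' classifyCB(c(9.3, 14, 6), c(1, 0, 0))
#' @export
classifyCB <- function(pfsTime, pfsEvent, horizon = 12, excluded = FALSE) {
    n <- length(pfsTime)
    excluded <- rep_len(excluded, n)
    lab <- ifelse(excluded, "not assessable",
           ifelse(pfsTime >= horizon, "CB",
           ifelse(pfsEvent == 1, "NCB", "not assessable")))
    factor(lab, levels = c("CB", "NCB", "not assessable"))
}

#' Pooled two-proportion z-test
#'
#' Compares two binomial proportions with the pooled-variance z statistic
#' and a two-sided normal p-value (e.g. clinical-benefit rates between a
#' monocyte-high cluster and the remaining samples).
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with \code{z}, \code{pvalue}, \code{p1}, \code{p2}.
#' @examples
#' twoProportionTest(8, 12, 5, 20)   # z ~ 2.32
#' @export
twoProportionTest <- function(x1, n1, x2, n2) {
    if (n1 < 1 || n2 < 1) stop("both groups need n >= 1")
    if (x1 > n1 || x2 > n2 || x1 < 0 || x2 < 0)
        stop("successes must lie in [0, n]")
    p1 <- x1 / n1; p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    list(z = z, pvalue = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}
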