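#' Run the full synthetic biomarker-discovery workflow
#'
#' Convenience orchestration over a simulated cohort: simulate (or reuse) a
#' single-cell reference, simulate the paired-trial cohort, normalize,
#' derive and score the on-treatment signature, build the deconvolution
#' reference, estimate composition and TMC for the pre-treatment samples,
#' and run the survival stratifications (TMC median split + log-rank,
#' multivariable TMC + TMB Cox, quadrant analysis).
#'
#' @param config a [SimConfig-class].
#' @param ref optional pre-simulated [SingleCellReference-class].
#' @param k signature size (default 70).
#' @param topN reference gene panel size (default 3000).
#' @return list with the intermediate objects: \code{ref}, \code{cohort},
#'   \code{de}, \code{signature}, \code{scores}, \code{reactivity},
#'   \code{refProfile}, \code{composition}, \code{tmc}, \code{tmcSplit},
#'   \code{logrankOS}, \code{cox}, \code{quadrant}.
#' @export
runPipeline <- function(config, ref = NULL, k = 70, topN = 3000) {
    if (is.null(ref)) ref <- simulateSingleCellReference(config)
    cohort <- simulateCohort(config, ref)
    pre <- normalizeLog(cohort$pre)
    on <- normalizeLog(cohort$on)
    de <- pairedDifferentialExpression(pre, on)
    sig <- deriveSignature(de, k = k)
    scores <- scoreSignatureChange(pre, on, sig)
    reactivity <- classifyReactivity(scores)
    refProfile <- buildReference(ref, topN = topN)
    comp <- deconvolveNNLS(pre, refProfile,
                           minOverlap = min(100, length(
                               selectedGenes(refProfile))))
    comp <- rnaToCellFraction(comp, refProfile)
    tmc <- extractTMC(comp)
    out <- cohort$outcomes
    split <- medianSplit(tmc$tmc)
    logrankOS <- logrankTest(out$osMonths, out$osEvent, split)
    cox <- coxFit(out$osMonths, out$osEvent,
                  data.frame(tmc = tmc$tmc, tmb = out$tmb),
                  log10Transform = c(tmc = TRUE, tmb = FALSE))
    quadrant <- quadrantAnalysis(out$tmb, tmc$tmc, out$osMonths,
                                 out$osEvent)
    list(ref = ref, cohort = cohort, de = de, signature = sig,
         scores = scores, reactivity = reactivity,
         refProfile = refProfile, composition = comp, tmc = tmc,
         tmcSplit = split, logrankOS = logrankOS, cox = cox,
         quadrant = quadrant)
}

#' Synthetic worked-example trial outcome table
#'
#' Loads a small synthetic per-patient outcome table for a 38-patient
#' esophageal-cancer ICI window trial cohort (three treatment arms,
#' per-patient tumor-size changes, PFS, and a phagocytic-compartment
#' cluster label for the biopsied subset). The per-patient values are
#' invented, but their aggregate bookkeeping -- arm sizes, responder and
#' clinical-benefit counts, monocyte-cluster benefit rates -- matches the
#' published aggregate outcomes of such a trial, so the table exercises the
#' [classifyResponse()] / [classifyCB()] / [twoProportionTest()] paths of a
#' real analysis. See the file's column header for the schema.
#'
#' @return data.frame, one row per patient.
#' @examples
#' tab <- syntheticTrialOutcomes()
#' resp <- classifyResponse(tab$bestChangePct, tab$worstChangePct)
#' mean(resp$responder) * 100   # pooled response rate in percent
#' @export
syntheticTrialOutcomes <- function() {
    path <- system.file("extdata", "synthetic_trial_outcomes.tsv",
                        package = "ICIwindow", mustWork = TRUE)
    read.delim(path, stringsAsFactors = FALSE)
}
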