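#' Kaplan-Meier estimate with median survival
#'
#' Product-limit survival curve with the median defined as the earliest
#' time at which S(t) drops to 0.5 or below (reported as NA, "not
#' reached", when the curve never crosses 0.5), plus an optional risk
#' table.
#'
#' @param time positive follow-up times (months).
#' @param event event flags (1 = event, 0 = censored).
#' @param riskTimes optional times at which to report numbers at risk.
#' @return list with \code{fit} (the survfit object), \code{curve}
#'   (data.frame time, nRisk, nEvent, surv), \code{median} and, when
#'   requested, \code{riskTable}.
#' @export
kmEstimate <- function(time, event, riskTimes = NULL) {
    if (any(time <= 0)) stop("survival times must be positive")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    curve <- data.frame(time = fit$time, nRisk = fit$n.risk,
                        nEvent = fit$n.event, surv = fit$surv)
    med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5])
           else NA_real_
    out <- list(fit = fit, curve = curve, median = med)
    if (!is.null(riskTimes)) {
        sm <- summary(fit, times = riskTimes, extend = TRUE)
        out$riskTable <- data.frame(time = sm$time, nRisk = sm$n.risk)
    }
    out
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank statistic over the pooled
#' event times, chi-squared with (k - 1) degrees of freedom.
#'
#' @param time,event as in [kmEstimate()].
#' @param group group labels (>= 2 non-empty groups).
#' @return list with \code{chisq}, \code{df}, \code{pvalue}.
#' @export
logrankTest <- function(time, event, group) {
    group <- droplevels(factor(group))
    if (nlevels(group) < 2) stop("need >= 2 non-empty groups")
    if (any(table(group) == 0)) stop("empty group")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    df <- length(sd$n) - 1
    list(chisq = sd$chisq, df = df,
         pvalue = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with the trial's covariate conventions
#'
#' Fits a Cox model by partial-likelihood maximization (Efron tie
#' correction by default) after optionally log10-transforming and then
#' scaling and centering each continuous covariate -- the convention used
#' for biomarkers such as log10(TMC) and TMB. Reports hazard ratios with
#' Wald 95% confidence intervals and p-values; supports univariable and
#' multivariable designs.
#'
#' @param time,event survival outcome.
#' @param covariates data.frame (or named vector for one covariate) of
#'   per-patient values.
#' @param log10Transform logical scalar or named per-covariate vector:
#'   apply log10 first.
#' @param scale scale and center covariates (default TRUE).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return data.frame per covariate: \code{term}, \code{beta}, \code{se},
#'   \code{hr}, \code{lo}, \code{hi}, \code{pvalue}.
#' @export
coxFit <- function(time, event, covariates, log10Transform = FALSE,
                   scale = TRUE, ties = c("efron", "breslow")) {
    ties <- match.arg(ties)
    if (!is.data.frame(covariates))
        covariates <- data.frame(x = covariates)
    if (sum(event) < 10)
        warning("fewer than 10 events; estimates may be unstable")
    lt <- if (length(log10Transform) == 1)
        setNames(rep(log10Transform, ncol(covariates)), names(covariates))
    else log10Transform
    X <- covariates
    for (nm in names(X)) {
        if (isTRUE(lt[[nm]])) {
            if (any(X[[nm]] <= 0))
                stop("log10 transform needs positive values for ", nm)
            X[[nm]] <- log10(X[[nm]])
        }
        if (sd(X[[nm]]) == 0) stop("constant covariate: ", nm)
        if (scale) X[[nm]] <- .zscale(X[[nm]])
    }
    dat <- cbind(data.frame(.time = time, .event = event), X)
    fit <- survival::coxph(
        survival::Surv(.time, .event) ~ ., data = dat, ties = ties)
    if (!fit$iter < fit$control$iter.max && is.na(fit$loglik[2]))
        stop("Cox fit failed to converge")
    sm <- summary(fit)
    data.frame(term = rownames(sm$coefficients),
               beta = sm$coefficients[, "coef"],
               se = sm$coefficients[, "se(coef)"],
               hr = sm$conf.int[, "exp(coef)"],
               lo = sm$conf.int[, "lower .95"],
               hi = sm$conf.int[, "upper .95"],
               pvalue = sm$coefficients[, "Pr(>|z|)"],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen cell types for association with survival
#'
#' Univariable Cox regression of survival on each cell type's
#' (log10-transformed, scaled) pre-treatment fraction, with
#' Benjamini-Hochberg correction across all tested types; significance at
#' FDR < 0.05. All-zero cell types are skipped with a warning. This is the
#' screen that singles out tumor monocyte content among the full cell-type
#' panel.
#'
#' @param comp a [CompositionEstimate-class] (samples aligned to the
#'   survival vectors).
#' @param time,event survival outcome.
#' @param scale \code{"rna"} or \code{"cell"} fraction scale.
#' @param floor optional log10 floor per [extractTMC()].
#' @return data.frame per tested type: \code{cellType}, \code{hr},
#'   \code{lo}, \code{hi}, \code{pvalue}, \code{fdr}, \code{significant};
#'   sorted by ascending FDR then p.
#' @export
screenCellTypes <- function(comp, time, event, scale = c("rna", "cell"),
                            floor = NULL) {
    scale <- match.arg(scale)
    m <- if (scale == "rna") rnaFraction(comp) else cellFraction(comp)
    if (nrow(m) != length(time))
        stop("composition and survival must cover the same patients")
    rows <- list()
    for (tt in colnames(m)) {
        v <- m[, tt]
        if (all(v == 0)) {
            warning("skipping all-zero cell type: ", tt)
            next
        }
        fl <- if (is.null(floor)) min(v[v > 0]) / 2 else floor
        x <- log10(pmax(v, fl))
        if (sd(x) == 0) {
            warning("skipping constant cell type: ", tt)
            next
        }
        cf <- suppressWarnings(coxFit(time, event, data.frame(frac = x),
                                      scale = TRUE))
        rows[[tt]] <- data.frame(cellType = tt, hr = cf$hr, lo = cf$lo,
                                 hi = cf$hi, pvalue = cf$pvalue,
                                 stringsAsFactors = FALSE)
    }
    if (!length(rows)) stop("no testable cell types")
    out <- do.call(rbind, rows)
    out$fdr <- p.adjust(out$pvalue, method = "BH")
    out$significant <- out$fdr < 0.05
    out <- out[order(out$fdr, out$pvalue), ]
    rownames(out) <- NULL
    out
}

#' Split patients at the cohort median
#'
#' Values strictly above the median are "high"; values at the median go to
#' "low" (deterministic tie rule: "high" strictly exceeds the median).
#'
#' @param values per-patient numeric.
#' @return factor with levels low / high; group sizes in attribute
#'   \code{"sizes"}.
#' @examples
#' medianSplit(c(1, 2, 3, 4))   # low low high high
#' @export
medianSplit <- function(values) {
    if (length(values) < 2) stop("need >= 2 patients")
    f <- factor(ifelse(values > median(values), "high", "low"),
                levels = c("low", "high"))
    attr(f, "sizes") <- table(f)
    f
}

#' Quadrant analysis: cross of two biomarker median splits
#'
#' Crosses the median splits of two biomarkers (canonically pre-treatment
#' TMB and TMC), labels each patient by quadrant, runs the overall
#' four-group log-rank test, and reports per-quadrant Kaplan-Meier medians,
#' highlighting the double-high group. Labels are invariant to monotone
#' transforms of either marker. Patients missing either marker are excluded
#' with a warning.
#'
#' @param tmb,tmc per-patient biomarker values.
#' @param time,event survival outcome.
#' @return list with \code{labels} (factor per retained patient),
#'   \code{logrank} ([logrankTest()] output), \code{medians} (per-quadrant
#'   KM median survival), \code{doubleHigh} (the "TMB-high/TMC-high"
#'   label) and \code{kept} (logical index of retained patients).
#' @export
quadrantAnalysis <- function(tmb, tmc, time, event) {
    ok <- complete.cases(tmb, tmc, time, event)
    if (!all(ok))
        warning("excluding ", sum(!ok), " patient(s) with missing markers")
    tmb <- tmb[ok]; tmc <- tmc[ok]; time <- time[ok]; event <- event[ok]
    sb <- medianSplit(tmb)
    sc <- medianSplit(tmc)
    lab <- factor(paste0("TMB-", sb, "/TMC-", sc),
                  levels = c("TMB-low/TMC-low", "TMB-low/TMC-high",
                             "TMB-high/TMC-low", "TMB-high/TMC-high"))
    lr <- logrankTest(time, event, lab)
    med <- vapply(levels(droplevels(lab)), function(lv) {
        kmEstimate(time[lab == lv], event[lab == lv])$median
    }, numeric(1))
    list(labels = lab, logrank = lr,
         medians = data.frame(quadrant = names(med), medianSurvival = med,
                              row.names = NULL),
         doubleHigh = "TMB-high/TMC-high", kept = ok)
}
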