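#' Construct a simulation configuration
#'
#' Builds a validated [SimConfig-class]. Defaults emulate the statistical
#' structure of a first-line ICI window-of-opportunity esophageal
#' adenocarcinoma trial cohort: ~45% responders, logit-normal tumor monocyte
#' content around 5%, log-normal tumor mutational burden with median
#' 5 mutations/Mb independent of TMC, and exponential OS/PFS with log-hazard
#' decreases of 0.97 and 0.69 per SD of scaled log10(TMC) and TMB
#' (hazard ratios ~0.38 and ~0.50) around baseline medians of 13.4 and
#' 9.1 months. See the package vignette for the rationale behind each value.
#'
#' @param nGenes,nCellTypes,nMarkersPerType,markerFold,nbDispersion
#'   single-cell count model; NB variance is \eqn{\mu + \mu^2/\theta} with
#'   \code{nbDispersion} as \eqn{\theta}.
#' @param cellsPerType,libSizeMean,libSizeLogSd,typeRnaContent reference
#'   atlas size and per-cell library-size model. \code{typeRnaContent = NULL}
#'   spreads per-type RNA content geometrically over (0.65, 1.8).
#' @param nPatients,cellsPerPseudobulk,purityRange,dirichletConc mixing model
#'   for bulk samples.
#' @param responderProb,signatureEffectMean,signatureEffectSd on-treatment
#'   T/NK signature upregulation (log2 scale).
#' @param tmcLogitMean,tmcLogitSd,tmbLogMean,tmbLogSd biomarker distributions.
#' @param hazardTMC,hazardTMB,baselineHazardOS,baselineHazardPFS,censorRate
#'   proportional-hazards survival model.
#' @param shrinkageIntercept,shrinkagePerDelta,shrinkagePerTMC,shrinkageNoiseSd
#'   tumor-size percent-change model (negative change = shrinkage).
#' @param seed integer random seed; identical configs give identical output.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 200, nCellTypes = 3, nMarkersPerType = 10,
#'                  cellsPerType = 50, seed = 7)
#' @export
simConfig <- function(nGenes = 1500L, nCellTypes = 8L,
                      nMarkersPerType = 70L, markerFold = 8,
                      nbDispersion = 2, cellsPerType = 400L,
                      libSizeMean = 2000, libSizeLogSd = 0.3,
                      typeRnaContent = NULL,
                      nPatients = 35L, cellsPerPseudobulk = 300L,
                      purityRange = c(0.2, 0.9), dirichletConc = 1,
                      responderProb = 0.45,
                      signatureEffectMean = 1, signatureEffectSd = 0.4,
                      tmcLogitMean = qlogis(0.05), tmcLogitSd = 1,
                      tmbLogMean = log(5), tmbLogSd = 0.8,
                      hazardTMC = 0.97, hazardTMB = 0.69,
                      baselineHazardOS = log(2) / 13.4,
                      baselineHazardPFS = log(2) / 9.1,
                      censorRate = 0.25,
                      shrinkageIntercept = 0, shrinkagePerDelta = 15,
                      shrinkagePerTMC = 8, shrinkageNoiseSd = 10,
                      seed = 1L) {
    new("SimConfig",
        nGenes = as.integer(nGenes), nCellTypes = as.integer(nCellTypes),
        nMarkersPerType = as.integer(nMarkersPerType),
        markerFold = markerFold, nbDispersion = nbDispersion,
        cellsPerType = as.integer(cellsPerType),
        libSizeMean = libSizeMean, libSizeLogSd = libSizeLogSd,
        typeRnaContent = if (is.null(typeRnaContent)) numeric()
                         else typeRnaContent,
        nPatients = as.integer(nPatients),
        cellsPerPseudobulk = as.integer(cellsPerPseudobulk),
        purityRange = purityRange, dirichletConc = dirichletConc,
        responderProb = responderProb,
        signatureEffectMean = signatureEffectMean,
        signatureEffectSd = signatureEffectSd,
        tmcLogitMean = tmcLogitMean, tmcLogitSd = tmcLogitSd,
        tmbLogMean = tmbLogMean, tmbLogSd = tmbLogSd,
        hazardTMC = hazardTMC, hazardTMB = hazardTMB,
        baselineHazardOS = baselineHazardOS,
        baselineHazardPFS = baselineHazardPFS,
        censorRate = censorRate,
        shrinkageIntercept = shrinkageIntercept,
        shrinkagePerDelta = shrinkagePerDelta,
        shrinkagePerTMC = shrinkagePerTMC,
        shrinkageNoiseSd = shrinkageNoiseSd,
        seed = as.integer(seed))
}

#' Cell-type names used by the simulator
#'
#' The first three types are fixed: the malignant type \code{"EAC"},
#' \code{"Monocyte"} and \code{"TNK"} (T/NK cells, carriers of the treatment
#' signature). Further types take generic tumor-microenvironment names.
#'
#' @param n number of cell types (>= 3).
#' @return character vector of length \code{n}.
#' @export
cellTypeNames <- function(n) {
    base <- c("EAC", "Monocyte", "TNK", "Bcell", "Macrophage",
              "Fibroblast", "Endothelial", "Squamous")
    if (n <= length(base)) return(base[seq_len(n)])
    c(base, paste0("Type", seq.int(length(base) + 1L, n)))
}

.rdirichlet <- function(n, alpha) {
    x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
                byrow = TRUE)
    x / rowSums(x)
}

.zscale <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) stop("cannot scale a constant covariate")
    (x - mean(x)) / s
}

.typeRnaContentFactors <- function(config) {
    if (length(config@typeRnaContent)) return(config@typeRnaContent)
    exp(seq(log(0.65), log(1.8), length.out = config@nCellTypes))
}

.typeExpressionProbs <- function(config) {
    # relative transcript abundance per type: shared log-normal baseline,
    # marker blocks boosted markerFold-fold, columns normalized to 1
    base <- exp(rnorm(config@nGenes, 0, 1.25))
    types <- cellTypeNames(config@nCellTypes)
    genes <- sprintf("G%04d", seq_len(config@nGenes))
    p <- matrix(base, nrow = config@nGenes, ncol = config@nCellTypes,
                dimnames = list(genes, types))
    m <- config@nMarkersPerType
    markers <- lapply(seq_len(config@nCellTypes), function(k)
        genes[seq.int((k - 1L) * m + 1L, k * m)])
    names(markers) <- types
    for (k in seq_len(config@nCellTypes))
        p[markers[[k]], k] <- p[markers[[k]], k] * config@markerFold
    p <- sweep(p, 2, colSums(p), "/")
    list(probs = p, markers = markers, genes = genes, types = types)
}

#' Simulate a labeled single-cell reference atlas
#'
#' Draws negative-binomial counts for \code{cellsPerType} cells of each type.
#' Each type boosts its own \code{nMarkersPerType} marker genes by
#' \code{markerFold}; per-cell library sizes are log-normal with a per-type
#' RNA-content multiplier, so cell types differ in mean total RNA (the basis
#' of the RNA-fraction vs cell-fraction distinction downstream). The type
#' \code{"EAC"} is flagged malignant.
#'
#' @param config a [SimConfig-class].
#' @return a [SingleCellReference-class]; \code{metadata()} carries the
#'   marker map, the configured type expression probabilities and the config.
#' @examples
#' ref <- simulateSingleCellReference(
#'     simConfig(nGenes = 200, nCellTypes = 3, nMarkersPerType = 10,
#'               cellsPerType = 40, seed = 1))
#' table(cellType(ref))
#' @export
simulateSingleCellReference <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    layout <- .typeExpressionProbs(config)
    rna <- .typeRnaContentFactors(config)
    nct <- config@nCellTypes
    npc <- config@cellsPerType
    counts <- vector("list", nct)
    libs <- vector("list", nct)
    for (k in seq_len(nct)) {
        lib <- rlnorm(npc, log(config@libSizeMean * rna[k]) -
                          config@libSizeLogSd^2 / 2, config@libSizeLogSd)
        mu <- outer(layout$probs[, k], lib)
        counts[[k]] <- matrix(
            rnbinom(length(mu), size = config@nbDispersion, mu = mu),
            nrow = config@nGenes)
        libs[[k]] <- lib
    }
    mat <- do.call(cbind, counts)
    rownames(mat) <- layout$genes
    colnames(mat) <- sprintf("cell%05d", seq_len(ncol(mat)))
    cd <- S4Vectors::DataFrame(
        cellType = rep(layout$types, each = npc),
        patient = sample(paste0("D", 1:6), ncol(mat), replace = TRUE),
        malignant = rep(layout$types == "EAC", each = npc),
        row.names = colnames(mat))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(mat, sparse = TRUE)),
        colData = cd)
    S4Vectors::metadata(sce) <- list(markers = layout$markers,
                                     typeProbs = layout$probs,
                                     typeRnaContent = setNames(rna,
                                                               layout$types),
                                     config = config)
    new("SingleCellReference", sce)
}

# Draw integer cell counts per type for one mixture, then sample that many
# member cells (with replacement) from the atlas. Returns the multiplicity
# weights over atlas cells plus the realized cell/RNA fraction truth.
.sampleMixture <- function(typeProb, idxByType, libSizes, nCells) {
    nPer <- drop(rmultinom(1, nCells, typeProb))
    cells <- integer(0)
    for (k in seq_along(typeProb)) {
        if (nPer[k] > 0)
            cells <- c(cells, sample(idxByType[[k]], nPer[k],
                                     replace = TRUE))
    }
    w <- tabulate(cells, nbins = length(libSizes))
    mass <- vapply(seq_along(typeProb), function(k) {
        sel <- idxByType[[k]]
        sum(w[sel] * libSizes[sel])
    }, numeric(1))
    list(weights = w, cells = cells,
         cellFraction = nPer / sum(nPer),
         rnaFraction = mass / sum(mass))
}

#' Simulate a pseudobulk benchmarking panel with known composition
#'
#' Creates bulk samples by summing single-cell counts from known numbers of
#' cells: malignant purity is drawn from \code{purityRange}, the residual
#' mass is split over non-malignant types by a Dirichlet draw, and
#' \code{cellsPerPseudobulk} cells are sampled multinomially. Both ground
#' truth scales are recorded: the cell fraction (sampled cells per type /
#' total) and the RNA fraction (counts contributed per type / total counts).
#' The default panel of 80 samples spans tumor purity, immune infiltration
#' and stromal/squamous contamination gradients.
#'
#' @param ref a [SingleCellReference-class].
#' @param nSamples number of pseudobulk samples (default 80).
#' @param config a [SimConfig-class] supplying purity range, Dirichlet
#'   concentration, cell count per sample and the seed.
#' @return list with \code{bulk} (a [SummarizedExperiment::SummarizedExperiment]
#'   of summed counts with per-sample purity in \code{colData}) and
#'   \code{truth} (matrices \code{rnaFraction}, \code{cellFraction}
#'   [samples x types] and \code{cells}, the sampled atlas cell indices per
#'   sample, from which both scales can be recomputed).
#' @export
simulatePseudobulkPanel <- function(ref, nSamples = 80L,
                                    config = S4Vectors::metadata(ref)$config) {
    stopifnot(is(ref, "SingleCellReference"), nSamples >= 1)
    validObject(config)
    set.seed(config@seed + 1L)
    types <- unique(cellType(ref))
    malTypes <- unique(cellType(ref)[isMalignant(ref)])
    if (length(malTypes) != 1L)
        stop("reference must contain exactly one malignant cell type")
    if (!length(types) || length(types) < 2L)
        stop("reference must contain a malignant and >= 1 other cell type")
    M <- SummarizedExperiment::assay(ref, "counts")
    libSizes <- Matrix::colSums(M)
    idxByType <- lapply(types, function(tt) which(cellType(ref) == tt))
    names(idxByType) <- types
    empty <- types[vapply(idxByType, length, 1L) == 0L]
    if (length(empty))
        stop("cell type absent from reference: ", paste(empty, collapse = ", "))
    nonMal <- setdiff(types, malTypes)
    purity <- runif(nSamples, config@purityRange[1], config@purityRange[2])
    W <- matrix(0, ncol(M), nSamples)
    rnaFrac <- cellFrac <- matrix(0, nSamples, length(types),
                                  dimnames = list(NULL, types))
    cellLog <- vector("list", nSamples)
    for (s in seq_len(nSamples)) {
        w <- drop(.rdirichlet(1, rep(config@dirichletConc, length(nonMal))))
        probs <- setNames(numeric(length(types)), types)
        probs[malTypes] <- purity[s]
        probs[nonMal] <- (1 - purity[s]) * w
        mix <- .sampleMixture(probs, idxByType, libSizes,
                              config@cellsPerPseudobulk)
        W[, s] <- mix$weights
        rnaFrac[s, ] <- mix$rnaFraction
        cellFrac[s, ] <- mix$cellFraction
        cellLog[[s]] <- mix$cells
    }
    bulk <- as.matrix(M %*% W)
    colnames(bulk) <- sprintf("PB%03d", seq_len(nSamples))
    rownames(rnaFrac) <- rownames(cellFrac) <- colnames(bulk)
    names(cellLog) <- colnames(bulk)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = bulk),
        colData = S4Vectors::DataFrame(purity = purity,
                                       row.names = colnames(bulk)))
    list(bulk = se,
         truth = list(rnaFraction = rnaFrac, cellFraction = cellFrac,
                      cells = cellLog))
}

#' Simulate a paired pre-/on-treatment trial cohort with ground truth
#'
#' Per patient: tumor monocyte content TMC from a logit-normal, tumor
#' mutational burden TMB from an independent log-normal, a Bernoulli
#' responder flag, and a per-patient signature upregulation
#' \eqn{\delta_i \sim N(\delta_{resp}, sd)} for responders (mean 0
#' otherwise). The pre-treatment bulk sample is a cell mixture whose
#' monocyte share equals TMC; the on-treatment sample applies the
#' \eqn{\delta_i} log2-fold boost to the T/NK marker genes. Tumor-size
#' percent change is linear in \eqn{-\delta_i} and \eqn{-z(\log_{10} TMC)}
#' plus noise; OS and PFS are exponential with hazard
#' \eqn{h_0 \exp(-a\,z(\log_{10}TMC) - b\,z(TMB))} and independent
#' exponential censoring. irRECIST and clinical-benefit labels are derived
#' through [classifyResponse()] and [classifyCB()].
#'
#' @param config a [SimConfig-class].
#' @param ref a [SingleCellReference-class]; must contain the malignant type,
#'   \code{"Monocyte"} and \code{"TNK"}.
#' @return list with \code{pre} and \code{on}
#'   ([SummarizedExperiment::SummarizedExperiment] count matrices, one sample
#'   per patient), \code{outcomes} (per-patient data.frame: tumor-size
#'   change, irRECIST category, CB label, OS/PFS time + event, TMB) and
#'   \code{truth} (responder flag, \eqn{\delta_i}, TMC, TMB, hazard rates,
#'   realized composition on both scales, and the true signature genes).
#' @export
simulateCohort <- function(config, ref) {
    stopifnot(is(config, "SimConfig"), is(ref, "SingleCellReference"))
    validObject(config)
    set.seed(config@seed + 2L)
    types <- unique(cellType(ref))
    malTypes <- unique(cellType(ref)[isMalignant(ref)])
    if (length(malTypes) != 1L)
        stop("reference must contain exactly one malignant cell type")
    for (need in c("Monocyte", "TNK"))
        if (!need %in% types)
            stop("cell type absent from reference: ", need)
    if (config@baselineHazardOS <= 0 || config@baselineHazardPFS <= 0)
        stop("non-positive baseline hazard")
    M <- SummarizedExperiment::assay(ref, "counts")
    libSizes <- Matrix::colSums(M)
    idxByType <- lapply(types, function(tt) which(cellType(ref) == tt))
    names(idxByType) <- types
    sigGenes <- S4Vectors::metadata(ref)$markers[["TNK"]]
    if (is.null(sigGenes))
        stop("reference metadata lacks the TNK marker map")

    n <- config@nPatients
    patients <- sprintf("P%03d", seq_len(n))
    tmc <- plogis(rnorm(n, config@tmcLogitMean, config@tmcLogitSd))
    tmb <- rlnorm(n, config@tmbLogMean, config@tmbLogSd)
    responder <- rbinom(n, 1, config@responderProb) == 1
    delta <- rnorm(n, ifelse(responder, config@signatureEffectMean, 0),
                   config@signatureEffectSd)
    purity <- runif(n, config@purityRange[1], config@purityRange[2])
    otherTypes <- setdiff(types, c(malTypes, "Monocyte"))

    Wpre <- Won <- matrix(0, ncol(M), n)
    rnaFrac <- cellFrac <- matrix(0, n, length(types),
                                  dimnames = list(patients, types))
    for (i in seq_len(n)) {
        probs <- setNames(numeric(length(types)), types)
        probs["Monocyte"] <- tmc[i]
        probs[malTypes] <- purity[i] * (1 - tmc[i])
        w <- drop(.rdirichlet(1, rep(config@dirichletConc,
                                     length(otherTypes))))
        probs[otherTypes] <- (1 - purity[i]) * (1 - tmc[i]) * w
        mixPre <- .sampleMixture(probs, idxByType, libSizes,
                                 config@cellsPerPseudobulk)
        mixOn <- .sampleMixture(probs, idxByType, libSizes,
                                config@cellsPerPseudobulk)
        Wpre[, i] <- mixPre$weights
        Won[, i] <- mixOn$weights
        rnaFrac[i, ] <- mixPre$rnaFraction
        cellFrac[i, ] <- mixPre$cellFraction
    }
    pre <- as.matrix(M %*% Wpre)
    on <- as.matrix(M %*% Won)
    on[sigGenes, ] <- round(sweep(on[sigGenes, , drop = FALSE], 2,
                                  2^delta, "*"))
    colnames(pre) <- paste0(patients, "_PreTx")
    colnames(on) <- paste0(patients, "_ICI4W")

    zTmc <- .zscale(log10(tmc))
    zTmb <- .zscale(tmb)
    sizeChange <- pmax(-100,
        config@shrinkageIntercept - config@shrinkagePerDelta * delta -
        config@shrinkagePerTMC * zTmc + rnorm(n, 0, config@shrinkageNoiseSd))
    rateOS <- config@baselineHazardOS *
        exp(-config@hazardTMC * zTmc - config@hazardTMB * zTmb)
    ratePFS <- config@baselineHazardPFS *
        exp(-config@hazardTMC * zTmc - config@hazardTMB * zTmb)
    if (any(!is.finite(rateOS)) || any(rateOS <= 0) || any(ratePFS <= 0))
        stop("non-positive hazards in survival simulation")
    tOS <- rexp(n, rateOS)
    tPFS <- rexp(n, ratePFS)
    cens <- if (config@censorRate > 0)
        rexp(n, config@baselineHazardOS *
                 config@censorRate / (1 - config@censorRate))
    else rep(Inf, n)
    osMonths <- pmin(tOS, cens); osEvent <- as.integer(tOS <= cens)
    pfsMonths <- pmin(tPFS, cens); pfsEvent <- as.integer(tPFS <= cens)

    resp <- classifyResponse(bestChange = sizeChange)
    cb <- classifyCB(pfsMonths, pfsEvent)
    mkSE <- function(mat, tp) SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = mat),
        colData = S4Vectors::DataFrame(patient = patients,
                                       timepoint = tp,
                                       row.names = colnames(mat)))
    list(pre = mkSE(pre, "PreTx"), on = mkSE(on, "ICI-4W"),
         outcomes = data.frame(patient = patients,
                               sizeChange = sizeChange,
                               irRECIST = resp$category,
                               responder = resp$responder,
                               cb = cb,
                               osMonths = osMonths, osEvent = osEvent,
                               pfsMonths = pfsMonths, pfsEvent = pfsEvent,
                               tmb = tmb,
                               stringsAsFactors = FALSE),
         truth = list(responder = responder, delta = delta, tmc = tmc,
                      tmb = tmb, hazardOS = rateOS, hazardPFS = ratePFS,
                      rnaFraction = rnaFrac, cellFraction = cellFrac,
                      signatureGenes = sigGenes))
}

#' Simulate a monocyte RNA spike-in series
#'
#' Blends a bulk tumor expression profile with a monocyte profile on the
#' linear scale: each output column is \eqn{(1-f)\,bulk + f\,mono'} where
#' \eqn{mono'} is the monocyte profile rescaled to the bulk total, so the
#' total RNA mass is preserved and the monocyte share of it is exactly
#' \eqn{f}. Mirrors wet-lab spike-ins at 0--8% of total RNA mass.
#'
#' @param bulkProfile,monocyteProfile named non-negative vectors on the same
#'   gene index, linear scale. Build the monocyte profile from classical and
#'   non-classical subtypes with [blendProfiles()] (10:1 by default).
#' @param fractions spike fractions, each in [0, 1).
#' @return [SummarizedExperiment::SummarizedExperiment] with a
#'   \code{"normcounts"} (linear) assay, one column per fraction, and the
#'   known fraction in \code{colData}.
#' @examples
#' b <- setNames(c(10, 5, 1), c("A", "B", "C"))
#' m <- setNames(c(0, 1, 9), c("A", "B", "C"))
#' simulateSpikeIn(b, m, c(0, 0.02, 0.04))
#' @export
simulateSpikeIn <- function(bulkProfile, monocyteProfile,
                            fractions = c(0, 0.005, 0.01, 0.02, 0.04, 0.08)) {
    if (is.null(names(bulkProfile)) ||
        !identical(names(bulkProfile), names(monocyteProfile)))
        stop("bulk and monocyte profiles must share an identical gene index")
    if (any(fractions < 0) || any(fractions >= 1))
        stop("fractions must lie in [0, 1)")
    monoScaled <- monocyteProfile * sum(bulkProfile) / sum(monocyteProfile)
    out <- vapply(fractions, function(f)
        (1 - f) * bulkProfile + f * monoScaled,
        numeric(length(bulkProfile)))
    rownames(out) <- names(bulkProfile)
    colnames(out) <- sprintf("spike_%g", fractions)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(normcounts = out),
        colData = S4Vectors::DataFrame(fraction = fractions,
                                       row.names = colnames(out)))
}

#' Blend two expression profiles by RNA mass
#'
#' Mass-weighted mixture of two linear-scale profiles at \code{ratio}:1
#' (e.g. classical:non-classical monocytes mixed 10:1), rescaled to the
#' total mass of the first profile.
#'
#' @param a,b named non-negative vectors on the same gene index.
#' @param ratio mass ratio of \code{a} to \code{b}.
#' @return blended profile with \code{sum(a)} total mass.
#' @export
blendProfiles <- function(a, b, ratio = 10) {
    if (is.null(names(a)) || !identical(names(a), names(b)))
        stop("profiles must share an identical gene index")
    stopifnot(ratio > 0)
    total <- sum(a)
    (ratio / (ratio + 1)) * a / sum(a) * total +
        (1 / (ratio + 1)) * b / sum(b) * total
}
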