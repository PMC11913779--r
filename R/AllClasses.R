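#' @import methods
#' @importFrom stats median var sd cor quantile rnorm runif rbinom rgamma
#'   rnbinom rpois rexp rmultinom plogis qlogis rlnorm pnorm pt p.adjust
#'   hclust dist cutree lm coef setNames complete.cases digamma trigamma
#'   psigamma pchisq aggregate
#' @importFrom utils head read.delim write.table combn
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Simulation configuration for synthetic ICI-window cohorts
#'
#' Holds every tunable of the synthetic-data generator: the negative-binomial
#' single-cell model (gene count, cell types, marker structure, dispersion),
#' the pseudobulk mixing model (purity range, Dirichlet concentration), the
#' treatment-response model (responder probability, per-patient signature
#' upregulation \eqn{\delta}), the biomarker distributions (logit-normal tumor
#' monocyte content, log-normal tumor mutational burden) and the proportional
#' hazards survival model. Identical configurations (including \code{seed})
#' yield bit-identical simulations.
#'
#' @slot nGenes number of genes simulated.
#' @slot nCellTypes number of cell types (>= 3; the first three are always
#'   the malignant type \code{"EAC"}, \code{"Monocyte"} and \code{"TNK"}).
#' @slot nMarkersPerType marker genes boosted per cell type.
#' @slot markerFold multiplicative expression boost of a type's markers.
#' @slot nbDispersion negative-binomial size parameter \eqn{\theta}
#'   (variance \eqn{\mu + \mu^2/\theta}).
#' @slot cellsPerType cells simulated per type in the reference atlas.
#' @slot libSizeMean,libSizeLogSd log-normal per-cell library size model.
#' @slot typeRnaContent per-type RNA content multipliers (mean library size
#'   scale); length 0 means an automatic geometric spread across types.
#' @slot nPatients patients in the simulated cohort.
#' @slot cellsPerPseudobulk cells summed into each pseudobulk/bulk sample.
#' @slot purityRange range of malignant purity for mixtures, within [0,1].
#' @slot dirichletConc Dirichlet concentration for non-malignant composition.
#' @slot responderProb Bernoulli probability a patient is a responder.
#' @slot signatureEffectMean,signatureEffectSd responder log2 upregulation
#'   \eqn{\delta_i \sim N(\delta_{resp}, sd)} of T/NK signature genes.
#' @slot tmcLogitMean,tmcLogitSd logit-normal tumor monocyte content.
#' @slot tmbLogMean,tmbLogSd log-normal tumor mutational burden (mutations/Mb).
#' @slot hazardTMC,hazardTMB log-hazard decrease per SD of log10(TMC) and TMB.
#' @slot baselineHazardOS,baselineHazardPFS exponential baseline hazards
#'   (events/month).
#' @slot censorRate approximate fraction of patients censored.
#' @slot shrinkageIntercept,shrinkagePerDelta,shrinkagePerTMC,shrinkageNoiseSd
#'   linear model for on-treatment tumor-size percent change.
#' @slot seed integer random seed.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults.
#' @export
setClass("SimConfig", representation(
    nGenes = "integer",
    nCellTypes = "integer",
    nMarkersPerType = "integer",
    markerFold = "numeric",
    nbDispersion = "numeric",
    cellsPerType = "integer",
    libSizeMean = "numeric",
    libSizeLogSd = "numeric",
    typeRnaContent = "numeric",
    nPatients = "integer",
    cellsPerPseudobulk = "integer",
    purityRange = "numeric",
    dirichletConc = "numeric",
    responderProb = "numeric",
    signatureEffectMean = "numeric",
    signatureEffectSd = "numeric",
    tmcLogitMean = "numeric",
    tmcLogitSd = "numeric",
    tmbLogMean = "numeric",
    tmbLogSd = "numeric",
    hazardTMC = "numeric",
    hazardTMB = "numeric",
    baselineHazardOS = "numeric",
    baselineHazardPFS = "numeric",
    censorRate = "numeric",
    shrinkageIntercept = "numeric",
    shrinkagePerDelta = "numeric",
    shrinkagePerTMC = "numeric",
    shrinkageNoiseSd = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    counts <- c(nGenes = object@nGenes, nCellTypes = object@nCellTypes,
                nMarkersPerType = object@nMarkersPerType,
                cellsPerType = object@cellsPerType,
                nPatients = object@nPatients,
                cellsPerPseudobulk = object@cellsPerPseudobulk)
    if (any(counts < 1L))
        msg <- c(msg, paste("all counts must be >= 1; offending:",
                            paste(names(counts)[counts < 1L], collapse = ", ")))
    if (object@nCellTypes < 3L)
        msg <- c(msg, "need >= 3 cell types (malignant, Monocyte, TNK)")
    if (object@nCellTypes * object@nMarkersPerType > object@nGenes)
        msg <- c(msg, "nCellTypes * nMarkersPerType exceeds nGenes")
    if (length(object@purityRange) != 2L ||
        any(object@purityRange < 0) || any(object@purityRange > 1) ||
        diff(object@purityRange) < 0)
        msg <- c(msg, "purityRange must be an ordered interval within [0, 1]")
    for (nm in c("markerFold", "nbDispersion", "dirichletConc",
                 "signatureEffectSd", "tmcLogitSd", "tmbLogSd",
                 "baselineHazardOS", "baselineHazardPFS")) {
        if (slot(object, nm) <= 0)
            msg <- c(msg, paste(nm, "must be positive"))
    }
    for (nm in c("censorRate", "responderProb")) {
        v <- slot(object, nm)
        if (v < 0 || v > 1) msg <- c(msg, paste(nm, "must lie in [0, 1]"))
    }
    if (length(object@typeRnaContent) &&
        (length(object@typeRnaContent) != object@nCellTypes ||
         any(object@typeRnaContent <= 0)))
        msg <- c(msg, "typeRnaContent must be positive, one value per type")
    if (length(msg)) msg else TRUE
})

#' Labeled single-cell reference atlas
#'
#' A [SingleCellExperiment::SingleCellExperiment] whose \code{colData} carries
#' the three labels every downstream stage needs: \code{cellType},
#' \code{patient} and a logical \code{malignant} flag. The \code{"counts"}
#' assay holds raw UMI-like counts.
#'
#' @export
setClass("SingleCellReference", contains = "SingleCellExperiment")

setValidity("SingleCellReference", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("cellType", "patient", "malignant")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("missing colData columns:",
                            paste(miss, collapse = ", ")))
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    if ("malignant" %in% colnames(cd) && !is.logical(cd$malignant))
        msg <- c(msg, "'malignant' must be logical")
    if (length(msg)) msg else TRUE
})

#' Ordered treatment-responsive gene signature
#'
#' An ordered gene list with per-gene direction (+1 up, -1 down on treatment)
#' and the selection statistic that ordered it (here, the moderated paired
#' log2 fold change). Houses top-k signatures such as a 70-gene ICI-induced
#' T/NK enrichment signature and its compact noise-robust subsets.
#'
#' @slot name signature name.
#' @slot genes ordered gene identifiers (most significant first).
#' @slot direction +1/-1 per gene.
#' @slot stat per-gene selection statistic.
#' @export
setClass("GeneSignature", representation(
    name = "character", genes = "character",
    direction = "numeric", stat = "numeric"))

setValidity("GeneSignature", function(object) {
    msg <- character()
    n <- length(object@genes)
    if (anyDuplicated(object@genes))
        msg <- c(msg, "genes must be unique")
    if (length(object@direction) != n || length(object@stat) != n)
        msg <- c(msg, "genes, direction and stat must have equal length")
    if (n && !all(object@direction %in% c(-1, 1)))
        msg <- c(msg, "direction must be +1 or -1")
    if (length(msg)) msg else TRUE
})

#' Cell-type reference profiles for deconvolution
#'
#' Per-type mean linear-normalized expression (genes x types), the per-type
#' mean total RNA content \eqn{s_k} (mean library size of type-k cells, used
#' to convert RNA fractions to cell fractions), the selected high-variance
#' gene panel, and the label of the malignant type.
#'
#' @slot profiles genes x cell-types matrix of mean normalized expression.
#' @slot rnaContent named per-type mean library size \eqn{s_k > 0}.
#' @slot selectedGenes genes retained for deconvolution.
#' @slot malignantType name of the malignant cell type.
#' @export
setClass("ReferenceProfile", representation(
    profiles = "matrix", rnaContent = "numeric",
    selectedGenes = "character", malignantType = "character"))

setValidity("ReferenceProfile", function(object) {
    msg <- character()
    if (!identical(names(object@rnaContent), colnames(object@profiles)))
        msg <- c(msg, "rnaContent names must match profile columns")
    if (any(object@rnaContent <= 0))
        msg <- c(msg, "rnaContent must be positive")
    if (!all(object@selectedGenes %in% rownames(object@profiles)))
        msg <- c(msg, "selectedGenes must be a subset of profile genes")
    if (length(object@malignantType) > 1L)
        msg <- c(msg, "at most one malignant type")
    if (length(msg)) msg else TRUE
})

#' Sample-level cell composition estimates
#'
#' Samples x cell-types fractions on two scales: the RNA fraction (share of
#' transcript mass attributed to each type, the direct deconvolution output)
#' and the cell fraction (share of cells, obtained via per-type RNA content).
#' Rows sum to one on each populated scale; a per-sample residual records
#' the NNLS fit error.
#'
#' @slot rnaFraction samples x types RNA-fraction matrix.
#' @slot cellFraction samples x types cell-fraction matrix (may be empty
#'   until [rnaToCellFraction()] is applied).
#' @slot residual per-sample residual norm of the fit.
#' @export
setClass("CompositionEstimate", representation(
    rnaFraction = "matrix", cellFraction = "matrix", residual = "numeric"))

setValidity("CompositionEstimate", function(object) {
    msg <- character()
    chk <- function(m, label) {
        if (!nrow(m)) return(character())
        out <- character()
        if (any(m < -1e-9))
            out <- c(out, paste(label, "has negative entries"))
        rs <- rowSums(m)
        if (any(abs(rs - 1) > 1e-6))
            out <- c(out, paste(label, "rows must sum to 1 (tol 1e-6)"))
        out
    }
    msg <- c(msg, chk(object@rnaFraction, "rnaFraction"))
    if (nrow(object@cellFraction))
        msg <- c(msg, chk(object@cellFraction, "cellFraction"))
    if (length(object@residual) &&
        length(object@residual) != nrow(object@rnaFraction))
        msg <- c(msg, "residual length must match sample count")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes,", object@nCellTypes,
        "cell types,", object@nPatients, "patients, seed", object@seed, "\n")
    cat("  markers/type:", object@nMarkersPerType,
        " fold:", object@markerFold,
        " NB size:", object@nbDispersion, "\n")
    cat("  purity: [", object@purityRange[1], ",", object@purityRange[2],
        "]  delta_resp:", object@signatureEffectMean,
        " hazards (TMC, TMB): (", object@hazardTMC, ",",
        object@hazardTMB, ")\n")
})

setMethod("show", "GeneSignature", function(object) {
    cat("GeneSignature '", object@name, "': ", length(object@genes),
        " genes (", sum(object@direction > 0), " up, ",
        sum(object@direction < 0), " down)\n", sep = "")
    if (length(object@genes))
        cat("  top:", paste(head(object@genes, 5), collapse = ", "), "\n")
})

setMethod("show", "ReferenceProfile", function(object) {
    cat("ReferenceProfile:", ncol(object@profiles), "cell types x",
        nrow(object@profiles), "genes;", length(object@selectedGenes),
        "selected genes\n")
    if (length(object@malignantType))
        cat("  malignant type:", object@malignantType, "\n")
})

setMethod("show", "CompositionEstimate", function(object) {
    cat("CompositionEstimate:", nrow(object@rnaFraction), "samples x",
        ncol(object@rnaFraction), "cell types; cell-fraction scale",
        if (nrow(object@cellFraction)) "present" else "absent", "\n")
})
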