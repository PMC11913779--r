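# Small simulation configurations and hand-built objects shared by tests.

smallConfig <- function(...) {
    args <- list(nGenes = 300L, nCellTypes = 5L, nMarkersPerType = 15L,
                 markerFold = 8, cellsPerType = 60L,
                 cellsPerPseudobulk = 150L, nPatients = 30L, seed = 42L)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(simConfig, args)
}

# hand-built SingleCellReference from an explicit count matrix
makeSCRef <- function(counts, cellType, malignant = cellType == "EAC",
                      patient = rep("D1", ncol(counts))) {
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
        colData = S4Vectors::DataFrame(cellType = cellType,
                                       patient = patient,
                                       malignant = malignant))
    new("SingleCellReference", sce)
}

# SummarizedExperiment with a patient column and a chosen assay
makeSE <- function(mat, patient = colnames(mat), assayName = "logcounts",
                   timepoint = "PreTx") {
    SummarizedExperiment::SummarizedExperiment(
        assays = setNames(list(mat), assayName),
        colData = S4Vectors::DataFrame(patient = patient,
                                       timepoint = timepoint,
                                       row.names = colnames(mat)))
}

makeComposition <- function(rna, cell = matrix(numeric(0), 0, 0),
                            residual = numeric(nrow(rna))) {
    new("CompositionEstimate", rnaFraction = rna, cellFraction = cell,
        residual = residual)
}

# independent closed-form BH step-up oracle
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    out <- numeric(m)
    out[o] <- pmin(q, 1)
    out
}
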