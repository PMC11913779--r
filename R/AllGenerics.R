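#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly:
#' cell labels of a [SingleCellReference], the gene list / directions /
#' statistics of a [GeneSignature], the profile matrix, per-type RNA content,
#' selected genes and malignant label of a [ReferenceProfile], and the two
#' fraction scales plus fit residuals of a [CompositionEstimate].
#'
#' @param x an object of the documented class.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))
#' @rdname accessors
#' @export
setGeneric("isMalignant", function(x) standardGeneric("isMalignant"))
#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
#' @rdname accessors
#' @export
setGeneric("signatureDirections",
           function(x) standardGeneric("signatureDirections"))
#' @rdname accessors
#' @export
setGeneric("signatureStats", function(x) standardGeneric("signatureStats"))
#' @rdname accessors
#' @export
setGeneric("referenceProfiles",
           function(x) standardGeneric("referenceProfiles"))
#' @rdname accessors
#' @export
setGeneric("rnaContent", function(x) standardGeneric("rnaContent"))
#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))
#' @rdname accessors
#' @export
setGeneric("malignantType", function(x) standardGeneric("malignantType"))
#' @rdname accessors
#' @export
setGeneric("rnaFraction", function(x) standardGeneric("rnaFraction"))
#' @rdname accessors
#' @export
setGeneric("cellFraction", function(x) standardGeneric("cellFraction"))
#' @rdname accessors
#' @export
setGeneric("fitResidual", function(x) standardGeneric("fitResidual"))

#' @rdname accessors
#' @export
setMethod("cellType", "SingleCellReference",
          function(x) SummarizedExperiment::colData(x)$cellType)
#' @rdname accessors
#' @export
setMethod("isMalignant", "SingleCellReference",
          function(x) SummarizedExperiment::colData(x)$malignant)
#' @rdname accessors
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("signatureDirections", "GeneSignature", function(x)
    setNames(x@direction, x@genes))
#' @rdname accessors
#' @export
setMethod("signatureStats", "GeneSignature", function(x)
    setNames(x@stat, x@genes))
#' @rdname accessors
#' @export
setMethod("referenceProfiles", "ReferenceProfile", function(x) x@profiles)
#' @rdname accessors
#' @export
setMethod("rnaContent", "ReferenceProfile", function(x) x@rnaContent)
#' @rdname accessors
#' @export
setMethod("selectedGenes", "ReferenceProfile", function(x) x@selectedGenes)
#' @rdname accessors
#' @export
setMethod("malignantType", "ReferenceProfile", function(x) x@malignantType)
#' @rdname accessors
#' @export
setMethod("rnaFraction", "CompositionEstimate", function(x) x@rnaFraction)
#' @rdname accessors
#' @export
setMethod("cellFraction", "CompositionEstimate", function(x) {
    if (!nrow(x@cellFraction))
        stop("cell-fraction scale not computed; run rnaToCellFraction()")
    x@cellFraction
})
#' @rdname accessors
#' @export
setMethod("fitResidual", "CompositionEstimate", function(x) x@residual)
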