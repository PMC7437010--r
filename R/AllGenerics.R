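#' @importFrom BiocGenerics counts
NULL

#' Accessors for barseqpop classes
#'
#' Small accessor layer so downstream code never touches slots directly:
#' \code{counts()} and \code{abundances()} return the assay matrices of a
#' \linkS4class{BarseqExperiment} (genes x samples); \code{sampleData()} its
#' per-sample metadata; \code{catalogEntries()}/\code{discardedBarcodes()}
#' the retained and ambiguous parts of a \linkS4class{BarcodeCatalog};
#' \code{ordinationPoints()}/\code{ordinationStress()}/\code{eigenvalues()}
#' the pieces of an \linkS4class{Ordination}; \code{trueAbundances()} the
#' noise-free abundance matrix of one condition of a
#' \linkS4class{SimTruth}; \code{plantedGenes()} the genes planted with a
#' non-neutral coefficient (optionally restricted to one condition).
#'
#' @param object,x an object of the documented class.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(object, ...) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(object, ...) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("catalogEntries",
    function(object, ...) standardGeneric("catalogEntries"))

#' @rdname accessors
#' @export
setGeneric("discardedBarcodes",
    function(object, ...) standardGeneric("discardedBarcodes"))

#' @rdname accessors
#' @export
setGeneric("barcodeLength",
    function(object, ...) standardGeneric("barcodeLength"))

#' @rdname accessors
#' @export
setGeneric("ordinationPoints",
    function(object, ...) standardGeneric("ordinationPoints"))

#' @rdname accessors
#' @export
setGeneric("ordinationStress",
    function(object, ...) standardGeneric("ordinationStress"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object, ...) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("trueAbundances",
    function(object, condition, ...) standardGeneric("trueAbundances"))

#' @rdname accessors
#' @export
setGeneric("plantedGenes",
    function(object, condition = NULL, ...) standardGeneric("plantedGenes"))

#' @rdname accessors
#' @export
setGeneric("selectionCoefficients",
    function(object, ...) standardGeneric("selectionCoefficients"))
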