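#' @describeIn accessors raw counts assay of a BarseqExperiment
#' @export
setMethod("counts", "BarseqExperiment", function(object, ...) {
    assay(object, "counts")
})

#' @describeIn accessors abundance assay (after \code{normalizeAbundance})
#' @export
setMethod("abundances", "BarseqExperiment", function(object, ...) {
    if (!"abundance" %in% assayNames(object))
        stop("no 'abundance' assay; run normalizeAbundance() first")
    assay(object, "abundance")
})

#' @describeIn accessors per-sample metadata as a data.frame
#' @export
setMethod("sampleData", "BarseqExperiment", function(object, ...) {
    as.data.frame(colData(object))
})

#' @describeIn accessors retained (barcode, gene) entries
#' @export
setMethod("catalogEntries", "BarcodeCatalog", function(object, ...) {
    object@entries
})

#' @describeIn accessors barcodes discarded as ambiguous
#' @export
setMethod("discardedBarcodes", "BarcodeCatalog", function(object, ...) {
    object@discarded
})

#' @describeIn accessors common barcode length
#' @export
setMethod("barcodeLength", "BarcodeCatalog", function(object, ...) {
    object@barcodeLength
})

#' @describeIn accessors sample coordinates of an ordination
#' @export
setMethod("ordinationPoints", "Ordination", function(object, ...) {
    object@points
})

#' @describeIn accessors Kruskal stress-1 of an NMDS ordination
#' @export
setMethod("ordinationStress", "Ordination", function(object, ...) {
    object@stress
})

#' @describeIn accessors eigenvalue spectrum of a PCoA ordination
#' @export
setMethod("eigenvalues", "Ordination", function(object, ...) {
    object@eigenvalues
})

#' @describeIn accessors noise-free timepoints-by-genes abundance matrix
#' @export
setMethod("trueAbundances", "SimTruth", function(object, condition, ...) {
    if (!condition %in% names(object@abundances))
        stop("unknown condition: ", condition)
    object@abundances[[condition]]
})

#' @describeIn accessors genes carrying a planted non-neutral coefficient
#' @export
setMethod("plantedGenes", "SimTruth", function(object, condition = NULL, ...) {
    pl <- object@planted
    if (!is.null(condition)) pl <- pl[pl$condition %in% condition, , drop = FALSE]
    unique(pl$gene)
})

#' @describeIn accessors genes-by-phases selection coefficient matrix
#' @export
setMethod("selectionCoefficients", "FitnessLandscape", function(object, ...) {
    object@s
})

setMethod("show", "BarcodeCatalog", function(object) {
    cat("BarcodeCatalog:", nrow(object@entries), "retained barcodes (L =",
        object@barcodeLength, "),", length(object@discarded),
        "discarded as ambiguous\n")
})

setMethod("show", "BarseqExperiment", function(object) {
    cat(sprintf("BarseqExperiment: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
    if (ncol(object)) {
        cd <- colData(object)
        cat("conditions:",
            paste(unique(as.character(cd$condition)), collapse = ", "), "\n")
        cat("time range (h):", paste(range(cd$time_h), collapse = " - "), "\n")
    }
    ft <- metadata(object)$filterT0
    if (!is.null(ft))
        cat(sprintf("t0 filter: >= %d counts in '%s'\n",
                    ft$threshold, ft$t0Sample))
})

setMethod("show", "Ordination", function(object) {
    cat(sprintf("%s ordination: %d samples, k = %d\n", object@method,
                nrow(object@points), ncol(object@points)))
    if (object@method == "NMDS") {
        cat(sprintf("stress-1 = %.5f (%d restarts%s)\n", object@stress,
                    object@details$nRestarts %||% NA_integer_,
                    if (isTRUE(object@details$converged)) ""
                    else ", NOT converged"))
    } else {
        pos <- sum(object@eigenvalues > 0)
        cat(sprintf("%d positive / %d negative eigenvalues\n", pos,
                    sum(object@eigenvalues < 0)))
    }
})

setMethod("show", "PermanovaResult", function(object) {
    cat(sprintf(
        "PERMANOVA (%s): pseudo-F = %.4g, R2 = %.4f, p = %.4g (%d perms%s)\n",
        object@term, object@pseudoF, object@R2, object@pValue,
        object@nPermutations,
        if (isTRUE(object@details$exhaustive)) ", exhaustive" else ""))
    if (!is.na(object@strata[1])) cat("strata:", object@strata[1], "\n")
})

setMethod("show", "DispersionResult", function(object) {
    cat(sprintf(
        "Beta dispersion: %d samples, %d groups; F = %.4g (classical p = %.4g, permutation p = %.4g)\n",
        length(object@distances), nlevels(object@groups),
        object@anovaF, object@anovaP, object@permP))
    print(round(object@groupMeans, 4))
})

setMethod("show", "FitnessLandscape", function(object) {
    s <- object@s
    cat(sprintf("FitnessLandscape: %d genes x %d phases, %d non-neutral coefficients\n",
                nrow(s), ncol(s), sum(s != 0)))
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@abundances), "conditions (",
        paste(names(object@abundances), collapse = ", "), ")\n")
    cat(nrow(object@planted), "planted non-neutral (gene, phase) pairs; seed",
        object@seed, "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
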