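#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<-
NULL

#' Barcode catalog mapping barcode sequences to genes
#'
#' A validated map from strain-specific DNA barcodes to gene identifiers.
#' Barcodes shared by more than one gene are unusable for quantification and
#' are kept aside in \code{discarded}; every retained barcode maps to exactly
#' one gene and all retained barcodes share a common length.
#'
#' @slot entries data.frame with columns \code{barcode} and \code{gene}, one
#'   row per retained barcode.
#' @slot discarded character vector of barcode sequences dropped because they
#'   mapped to several distinct genes.
#' @slot barcodeLength integer, common length of the retained barcodes.
#'
#' @seealso [loadCatalog()]
#' @export
setClass("BarcodeCatalog",
    representation(
        entries = "data.frame",
        discarded = "character",
        barcodeLength = "integer"
    )
)

setValidity("BarcodeCatalog", function(object) {
    e <- object@entries
    msgs <- character()
    if (!all(c("barcode", "gene") %in% colnames(e)))
        msgs <- c(msgs, "entries must have columns 'barcode' and 'gene'")
    else {
        if (anyDuplicated(e$barcode))
            msgs <- c(msgs, "a retained barcode maps to more than one gene")
        if (nrow(e) && !all(nchar(e$barcode) == object@barcodeLength))
            msgs <- c(msgs, "retained barcodes must all have length barcodeLength")
        if (any(e$barcode %in% object@discarded))
            msgs <- c(msgs, "a barcode appears both retained and discarded")
        if (nrow(e) && any(grepl("[^ACGT]", e$barcode)))
            msgs <- c(msgs, "barcodes must be over the alphabet {A,C,G,T}")
    }
    if (length(msgs)) msgs else TRUE
})

#' Bar-seq experiment container
#'
#' A \linkS4class{SummarizedExperiment} holding the samples-by-mutants count
#' data of a pooled competition experiment: genes (mutant barcodes collapsed
#' to their gene) as rows, samples as columns.  The \code{counts} assay holds
#' raw non-negative integer barcode counts; after [normalizeAbundance()] an
#' \code{abundance} assay holds pseudocounted relative abundances whose
#' columns sum to one.  Per-sample metadata live in \code{colData} with the
#' mandatory fields \code{condition} (e.g. \code{"Seed1"}, \code{"BR"},
#' \code{"CF4"}), \code{vessel} (\code{"shake_flask"} or \code{"bioreactor"})
#' and \code{time_h} (elapsed fermentation time in hours).
#'
#' @seealso [countReads()], [filterT0()], [normalizeAbundance()]
#' @export
setClass("BarseqExperiment", contains = "SummarizedExperiment")

setValidity("BarseqExperiment", function(object) {
    msgs <- character()
    cd <- colData(object)
    need <- c("condition", "vessel", "time_h")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msgs <- c(msgs, paste0("colData lacks field(s): ",
                               paste(miss, collapse = ", ")))
    if (is.null(colnames(object)) && ncol(object) > 0)
        msgs <- c(msgs, "sample (column) names are required")
    if (anyDuplicated(colnames(object)))
        msgs <- c(msgs, "sample_id (column names) must be unique")
    if (anyDuplicated(rownames(object)))
        msgs <- c(msgs, "gene (row) names must be unique")
    if ("counts" %in% assayNames(object)) {
        cts <- assay(object, "counts")
        if (length(cts) && (any(cts < 0) || any(cts != round(cts))))
            msgs <- c(msgs, "counts must be non-negative integers")
    } else msgs <- c(msgs, "a 'counts' assay is required")
    if ("time_h" %in% colnames(cd) && length(cd$time_h) &&
        any(cd$time_h < 0))
        msgs <- c(msgs, "time_h must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' Ordination of a distance matrix
#'
#' Result of [pcoa()] or [nmds()]: a samples-by-k coordinate matrix plus the
#' method-specific diagnostics (Kruskal stress-1 for NMDS, the full
#' eigenvalue spectrum for PCoA).
#'
#' @slot points numeric matrix, samples in rows, axes in columns.
#' @slot stress Kruskal stress-1 (NMDS; \code{NA} for PCoA).
#' @slot eigenvalues full eigenvalue spectrum, sorted decreasing (PCoA;
#'   empty for NMDS).
#' @slot method "PCoA" or "NMDS".
#' @slot details list of diagnostics: per-restart stress, the accepted stress
#'   trace of the winning restart, convergence flag, seed, restart count.
#' @export
setClass("Ordination",
    representation(
        points = "matrix",
        stress = "numeric",
        eigenvalues = "numeric",
        method = "character",
        details = "list"
    )
)

setValidity("Ordination", function(object) {
    msgs <- character()
    if (!object@method %in% c("PCoA", "NMDS"))
        msgs <- c(msgs, "method must be 'PCoA' or 'NMDS'")
    if (object@method == "NMDS" && !is.na(object@stress) && object@stress < 0)
        msgs <- c(msgs, "stress must be non-negative")
    if (length(object@eigenvalues) > 1 &&
        is.unsorted(rev(object@eigenvalues)))
        msgs <- c(msgs, "eigenvalues must be sorted decreasing")
    if (length(msgs)) msgs else TRUE
})

#' Distance-based permutational ANOVA result
#'
#' @slot term name of the tested grouping factor.
#' @slot pseudoF observed pseudo-F statistic.
#' @slot R2 fraction of distance-based variance explained by the term.
#' @slot pValue permutation p-value.
#' @slot nPermutations number of permutations used (number of distinct
#'   arrangements when the test enumerated them exhaustively).
#' @slot strata name or values of the restriction stratum, \code{NA} if none.
#' @slot details list: SS decomposition, exhaustive flag, permuted F values,
#'   optionally the permuted label matrix.
#' @export
setClass("PermanovaResult",
    representation(
        term = "character",
        pseudoF = "numeric",
        R2 = "numeric",
        pValue = "numeric",
        nPermutations = "integer",
        strata = "character",
        details = "list"
    )
)

setValidity("PermanovaResult", function(object) {
    msgs <- character()
    if (!is.na(object@R2) && (object@R2 < 0 || object@R2 > 1))
        msgs <- c(msgs, "R2 must lie in [0, 1]")
    if (!is.na(object@pValue) &&
        (object@pValue <= 0 || object@pValue > 1))
        msgs <- c(msgs, "p-value must lie in (0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' Beta-dispersion (homogeneity of multivariate dispersion) result
#'
#' Distances of each sample to its group centroid in principal-coordinate
#' space, with a classical one-way ANOVA F across groups, a permutation
#' p-value, and pairwise permutation comparisons adjusted by
#' Benjamini-Hochberg.
#'
#' @slot distances per-sample distance to the group centroid (named).
#' @slot groups factor of group membership, same order as distances.
#' @slot groupMeans mean distance per group.
#' @slot anovaF classical one-way ANOVA F on the distances.
#' @slot anovaP classical F-distribution p-value.
#' @slot permP permutation p-value for the global test.
#' @slot pairwise data.frame: groupA, groupB, observed F, permutation p,
#'   BH-adjusted q.
#' @slot details list: eigenvalues, number of imaginary axes, excluded
#'   singleton groups, seed.
#' @export
setClass("DispersionResult",
    representation(
        distances = "numeric",
        groups = "factor",
        groupMeans = "numeric",
        anovaF = "numeric",
        anovaP = "numeric",
        permP = "numeric",
        pairwise = "data.frame",
        details = "list"
    )
)

setValidity("DispersionResult", function(object) {
    if (length(object@distances) &&
        any(object@distances < -1e-12))
        "distances to centroid must be non-negative"
    else TRUE
})

#' Per-mutant, per-phase selection coefficients
#'
#' The fitness landscape of a simulated pooled competition: a genes-by-phases
#' matrix of per-generation selection coefficients \eqn{s} (0 = neutral,
#' negative = deleterious in that phase; per generation the abundance of a
#' mutant is multiplied by \eqn{1+s} before renormalization).
#'
#' @slot s numeric matrix, genes in rows, phases in columns; finite.
#' @export
setClass("FitnessLandscape", representation(s = "matrix"))

setValidity("FitnessLandscape", function(object) {
    msgs <- character()
    if (length(object@s)) {
        if (any(!is.finite(object@s)))
            msgs <- c(msgs, "selection coefficients must be finite")
        if (is.null(rownames(object@s)) || is.null(colnames(object@s)))
            msgs <- c(msgs, "s must have gene rownames and phase colnames")
        else if (anyDuplicated(colnames(object@s)))
            msgs <- c(msgs, "phase ids must be unique")
    }
    if (length(msgs)) msgs else TRUE
})

#' Ground truth of a simulated pooled competition
#'
#' True (noise-free) relative abundances per condition and timepoint, the
#' planted deleterious (gene, phase) pairs, and the schedule and landscape
#' that produced them.  [sampleReads()] layers multinomial sequencing noise
#' on top of this truth; recovery tests compare pipeline calls against
#' \code{planted}.
#'
#' @slot abundances named list (one element per condition) of
#'   timepoints-by-genes abundance matrices; every row sums to 1.
#' @slot times named list of numeric sampling times (hours) per condition.
#' @slot planted data.frame: gene, phase, condition, s for every planted
#'   non-neutral coefficient.
#' @slot landscape the \linkS4class{FitnessLandscape} used.
#' @slot schedule the process schedule data.frame used.
#' @slot seed integer seed the trajectory was generated under.
#' @export
setClass("SimTruth",
    representation(
        abundances = "list",
        times = "list",
        planted = "data.frame",
        landscape = "FitnessLandscape",
        schedule = "data.frame",
        seed = "integer"
    )
)

setValidity("SimTruth", function(object) {
    msgs <- character()
    if (!identical(names(object@abundances), names(object@times)))
        msgs <- c(msgs, "abundances and times must cover the same conditions")
    for (cond in names(object@abundances)) {
        ab <- object@abundances[[cond]]
        if (nrow(ab) != length(object@times[[cond]])) {
            msgs <- c(msgs, sprintf("condition %s: row/time mismatch", cond))
            next
        }
        if (length(ab) && any(abs(rowSums(ab) - 1) > 1e-8))
            msgs <- c(msgs, sprintf(
                "condition %s: abundance rows must sum to 1", cond))
    }
    if (length(msgs)) msgs else TRUE
})
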