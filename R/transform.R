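#' Discard genes poorly represented in the starting pool
#'
#' Restricts the table to genes with at least \code{threshold} counts in the
#' designated t0 (starting pool) sample.  Every sample keeps the same
#' restricted gene universe, which all downstream statistics then share;
#' genes absent from a later sample stay in the table with count 0 rather
#' than being dropped, so "not detected" remains an observable state.
#' The operation is idempotent and never modifies its input.
#'
#' @param x a \linkS4class{BarseqExperiment}.
#' @param t0Sample sample id of the starting pool.
#' @param threshold minimum t0 count for a gene to be retained (default 10).
#' @return a \linkS4class{BarseqExperiment} restricted to the retained genes;
#'   the filter settings are recorded in \code{metadata(x)$filterT0}.
#' @export
filterT0 <- function(x, t0Sample, threshold = 10L) {
    stopifnot(is(x, "BarseqExperiment"))
    if (!t0Sample %in% colnames(x))
        stop("unknown t0 sample: ", t0Sample)
    keep <- counts(x)[, t0Sample] >= threshold
    out <- x[keep, ]
    metadata(out)$filterT0 <- list(t0Sample = t0Sample,
                                   threshold = as.integer(threshold))
    out
}

#' Pseudocount-normalize counts to relative abundances
#'
#' Adds a pseudocount to every raw count and divides by the per-sample total
#' of the adjusted counts, so every sample is a proper composition:
#' \deqn{a_{gs} = (c_{gs} + p) / \sum_{g'} (c_{g's} + p).}
#' The pseudocount (default 10) guarantees strictly positive abundances and
#' sidesteps division by zero for undetected mutants.  Dividing by the
#' adjusted rather than the raw total makes each sample sum to exactly 1,
#' the form Bray-Curtis and the other compositional statistics expect.
#'
#' @param x a \linkS4class{BarseqExperiment} with at least one gene.
#' @param pseudocount non-negative count added to every cell (default 10).
#' @return \code{x} with an added \code{abundance} assay; the pseudocount is
#'   recorded in \code{metadata(x)$pseudocount}.
#' @export
normalizeAbundance <- function(x, pseudocount = 10L) {
    stopifnot(is(x, "BarseqExperiment"))
    if (nrow(x) == 0L) stop("nothing to normalize: empty gene set")
    if (ncol(x) == 0L) stop("nothing to normalize: no samples")
    adj <- counts(x) + pseudocount
    ab <- sweep(adj, 2L, colSums(adj), "/")
    assay(x, "abundance") <- ab
    metadata(x)$pseudocount <- pseudocount
    x
}
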