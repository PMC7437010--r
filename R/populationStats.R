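#' Detection profile of one sample
#'
#' A mutant counts as detected in a sample when its raw barcode count reaches
#' the threshold (inclusive; default 10, the usual "at least 10 counts"
#' convention).  Richness here is simply the number of detected mutants.
#'
#' @param x a \linkS4class{BarseqExperiment}.
#' @param sampleId sample to profile.
#' @param threshold minimum count for detection (default 10).
#' @return list with \code{sample_id}, \code{threshold}, \code{n_detected},
#'   \code{n_not_detected} and the character vector \code{detected_genes}.
#' @export
detectionProfile <- function(x, sampleId, threshold = 10L) {
    stopifnot(is(x, "BarseqExperiment"))
    if (!sampleId %in% colnames(x)) stop("unknown sample: ", sampleId)
    det <- counts(x)[, sampleId] >= threshold
    list(sample_id = sampleId, threshold = as.integer(threshold),
         n_detected = sum(det), n_not_detected = sum(!det),
         detected_genes = rownames(x)[det])
}

#' Diversity-loss windows along a condition's time course
#'
#' For each consecutive pair of timepoints of one condition, counts the
#' mutants detected at the earlier but not the later timepoint ("lost") and,
#' symmetrically, those gained, at each detection threshold.  Loss means a
#' detection-state transition, not permanent extinction: a mutant hovering
#' around the threshold can be lost in one window and gained back in the
#' next.  The window of maximal loss per threshold localizes abrupt
#' diversity collapse (ties go to the earliest window).
#'
#' @param x a \linkS4class{BarseqExperiment}.
#' @param condition condition whose time course is scanned (needs >= 2
#'   timepoints).
#' @param thresholds detection thresholds to scan; the default
#'   \code{c(1, 5, 10, 20)} reads the conventional "> 0, 5, 10 or 20" count
#'   cutoffs as minimum-count thresholds.
#' @return list with \code{windows}, a data.frame (condition, threshold,
#'   t_start_h, t_end_h, n_lost, n_gained, fraction_lost), and
#'   \code{maxLoss}, the per-threshold argmax row of that table.
#' @export
lossWindows <- function(x, condition, thresholds = c(1L, 5L, 10L, 20L)) {
    stopifnot(is(x, "BarseqExperiment"))
    sd <- sampleData(x)
    sel <- sd[sd$condition == condition, , drop = FALSE]
    sel <- sel[order(sel$time_h), , drop = FALSE]
    if (nrow(sel) < 2L)
        stop("condition '", condition, "' has fewer than 2 timepoints")
    rows <- list()
    for (th in thresholds) {
        det <- lapply(rownames(sel), function(s)
            detectionProfile(x, s, th)$detected_genes)
        for (i in seq_len(nrow(sel) - 1L)) {
            lost <- setdiff(det[[i]], det[[i + 1L]])
            gained <- setdiff(det[[i + 1L]], det[[i]])
            rows[[length(rows) + 1L]] <- data.frame(
                condition = condition, threshold = th,
                t_start_h = sel$time_h[i], t_end_h = sel$time_h[i + 1L],
                n_lost = length(lost), n_gained = length(gained),
                fraction_lost = if (length(det[[i]]))
                    length(lost) / length(det[[i]]) else 0)
        }
    }
    windows <- do.call(rbind, rows)
    maxLoss <- do.call(rbind, lapply(split(windows, windows$threshold),
        function(w) w[which.max(w$n_lost), ]))  # which.max takes the earliest tie
    maxLoss <- maxLoss[order(maxLoss$threshold), ]
    rownames(maxLoss) <- NULL
    list(windows = windows, maxLoss = maxLoss)
}

#' Pairwise Pearson correlation of samples
#'
#' Correlates samples on their RAW barcode counts over the shared
#' (post-filter) gene universe — the convention for seed-train and
#' between-condition similarity heatmaps.  Depth differences add noise to
#' raw-count correlations; set \code{useAbundance = TRUE} to correlate
#' pseudocounted relative abundances instead.
#'
#' @param x a \linkS4class{BarseqExperiment} with >= 2 samples and >= 2
#'   genes.
#' @param useAbundance correlate the abundance assay instead of raw counts.
#' @return symmetric samples-by-samples matrix of Pearson r; rows/columns of
#'   zero-variance samples are \code{NA} (with a warning).
#' @export
pearsonMatrix <- function(x, useAbundance = FALSE) {
    stopifnot(is(x, "BarseqExperiment"))
    if (ncol(x) < 2L) stop("need at least 2 samples")
    if (nrow(x) < 2L) stop("need at least 2 genes")
    m <- if (useAbundance) abundances(x) else counts(x)
    v <- apply(m, 2L, stats::var)
    r <- suppressWarnings(stats::cor(m))
    if (any(v == 0)) {
        warning("zero-variance sample(s): ",
                paste(colnames(m)[v == 0], collapse = ", "))
        r[v == 0, ] <- NA_real_
        r[, v == 0] <- NA_real_
    }
    diag(r) <- ifelse(v > 0, 1, NA_real_)
    r
}
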