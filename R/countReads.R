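#' Read a FASTQ(.gz) file as a character vector of sequences
#'
#' Minimal strict FASTQ reader: records must be complete 4-line blocks whose
#' first line starts with \code{@} and third with \code{+}.  Violations are
#' hard errors naming the 1-based record index, so truncated downloads never
#' silently shorten a sample.
#'
#' @param path FASTQ or gzipped FASTQ file.
#' @return character vector of read sequences.
#' @export
readFastqReads <- function(path) {
    if (!file.exists(path)) stop("FASTQ file not found: ", path)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    if (!length(lines)) return(character())
    if (length(lines) %% 4L != 0L)
        stop(sprintf("truncated FASTQ record %d in %s: %d trailing line(s)",
                     length(lines) %/% 4L + 1L, path, length(lines) %% 4L))
    idx <- seq(1L, length(lines), by = 4L)
    badAt <- which(substr(lines[idx], 1L, 1L) != "@")
    if (length(badAt))
        stop(sprintf("invalid FASTQ record %d in %s: header does not start with '@'",
                     badAt[1], path))
    badPlus <- which(substr(lines[idx + 2L], 1L, 1L) != "+")
    if (length(badPlus))
        stop(sprintf("invalid FASTQ record %d in %s: separator does not start with '+'",
                     badPlus[1], path))
    lines[idx + 1L]
}

reverseComplement <- function(x) {
    comp <- chartr("ACGTacgt", "TGCAtgca", x)
    vapply(strsplit(comp, NULL),
           function(ch) paste(rev(ch), collapse = ""), "")
}

#' Construct a BarseqExperiment from a count matrix and sample metadata
#'
#' @param counts genes-by-samples matrix of non-negative integer counts;
#'   rownames are genes, colnames are sample ids.
#' @param sampleData data.frame with one row per sample (matched to the
#'   columns of \code{counts} by the \code{sample_id} column or rownames)
#'   carrying at least \code{condition}, \code{vessel} and \code{time_h}.
#' @return a \linkS4class{BarseqExperiment}.
#' @export
BarseqExperiment <- function(counts, sampleData) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (!is.null(sampleData$sample_id))
        rownames(sampleData) <- sampleData$sample_id
    if (is.null(colnames(counts)) && nrow(sampleData) == ncol(counts))
        colnames(counts) <- rownames(sampleData)
    miss <- setdiff(colnames(counts), rownames(sampleData))
    if (length(miss))
        stop("samples missing from sample sheet: ", paste(miss, collapse = ", "))
    cd <- sampleData[colnames(counts), , drop = FALSE]
    new("BarseqExperiment",
        SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(cd)))
}

#' Count perfectly matching barcode reads for one sample
#'
#' Implements the strict Bar-seq counting rule: a read contributes one count
#' to a gene only when the extracted barcode is an exact, full-length match
#' to a retained catalog barcode.  Reads with no flank hit, a short
#' remainder, any substitution, or a barcode discarded as ambiguous
#' contribute nothing.  Genes never observed get count 0, so the returned
#' table always spans the full catalog gene universe.
#'
#' @param reads a character vector of read sequences, or a path to a
#'   FASTQ(.gz) file (read via [readFastqReads()]).
#' @param catalog a \linkS4class{BarcodeCatalog}.
#' @param sampleId,condition,vessel,time_h metadata of the sequenced sample.
#' @param flank upstream flanking sequence locating the barcode in the read.
#' @param tryReverseComplement also search the reverse complement of reads
#'   whose forward orientation yielded no flank hit (default \code{FALSE};
#'   amplicon orientation is protocol-dependent).
#' @return a one-sample \linkS4class{BarseqExperiment}; the counting summary
#'   (total, matched, unmatched, ambiguous-discarded reads) is stored in
#'   \code{metadata(x)$countSummary[[sampleId]]}.
#' @export
countReads <- function(reads, catalog, sampleId, condition = "unknown",
                       vessel = "bioreactor", time_h = 0, flank,
                       tryReverseComplement = FALSE) {
    stopifnot(is(catalog, "BarcodeCatalog"))
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readFastqReads(reads)
    bc <- extractBarcode(reads, flank, barcodeLength(catalog))
    if (tryReverseComplement && anyNA(bc)) {
        miss <- which(is.na(bc))
        bc[miss] <- extractBarcode(reverseComplement(reads[miss]), flank,
                                   barcodeLength(catalog))
    }
    entries <- catalogEntries(catalog)
    genes <- sort(unique(entries$gene))
    hit <- match(bc, entries$barcode)           # exact-match index lookup
    matched <- !is.na(hit)
    nAmbiguous <- sum(bc[!matched] %in% discardedBarcodes(catalog),
                      na.rm = TRUE)
    cts <- table(factor(entries$gene[hit[matched]], levels = genes))
    counts <- matrix(as.numeric(cts), ncol = 1L,
                     dimnames = list(genes, sampleId))
    sd <- data.frame(sample_id = sampleId, condition = condition,
                     vessel = vessel, time_h = time_h,
                     row.names = sampleId, stringsAsFactors = FALSE)
    bse <- BarseqExperiment(counts, sd)
    summary <- list(total = length(reads), matched = sum(matched),
                    unmatched = sum(!matched) - nAmbiguous,
                    ambiguous_discarded = nAmbiguous)
    metadata(bse)$countSummary <- stats::setNames(list(summary), sampleId)
    bse
}

#' Combine one-sample BarseqExperiments over a common gene universe
#'
#' @param ... BarseqExperiment objects sharing an identical gene set.
#' @return a multi-sample \linkS4class{BarseqExperiment}.
#' @export
combineSamples <- function(...) {
    xs <- list(...)
    if (length(xs) == 1L && is.list(xs[[1]]) && !is(xs[[1]], "BarseqExperiment"))
        xs <- xs[[1]]
    genes <- rownames(xs[[1]])
    for (x in xs[-1])
        if (!identical(rownames(x), genes))
            stop("gene universes differ between samples")
    counts <- do.call(cbind, lapply(xs, counts))
    cd <- do.call(rbind, lapply(xs, sampleData))
    bse <- BarseqExperiment(counts, cd)
    summaries <- do.call(c, lapply(xs, function(x)
        metadata(x)$countSummary))
    if (length(summaries)) metadata(bse)$countSummary <- summaries
    bse
}
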