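#' Read a count table and its sample sheet from TSV
#'
#' The count table has a first column \code{gene} and one column per sample
#' id; the companion sample sheet has columns \code{sample_id},
#' \code{condition}, \code{vessel} and \code{time_h}.  Lines starting with
#' \code{#} are treated as comments in both files.
#'
#' @param countsPath path to the counts TSV.
#' @param sampleSheetPath path to the sample sheet TSV.
#' @return a \linkS4class{BarseqExperiment}.
#' @export
readCountTable <- function(countsPath, sampleSheetPath) {
    tab <- utils::read.delim(countsPath, check.names = FALSE,
                             comment.char = "#")
    if (colnames(tab)[1] != "gene")
        stop("count table must have 'gene' as its first column: ", countsPath)
    if (anyDuplicated(tab$gene))
        stop("duplicate gene identifiers in count table")
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab$gene
    ss <- readSampleSheet(sampleSheetPath)
    BarseqExperiment(counts, ss)
}

#' @rdname readCountTable
#' @param path path to a sample sheet TSV.
#' @export
readSampleSheet <- function(path) {
    ss <- utils::read.delim(path, comment.char = "#")
    need <- c("sample_id", "condition", "vessel", "time_h")
    miss <- setdiff(need, colnames(ss))
    if (length(miss))
        stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(ss$sample_id))
        stop("duplicate sample_id in sample sheet")
    rownames(ss) <- ss$sample_id
    ss
}

#' Write a BarseqExperiment's counts (and sample sheet) to TSV
#'
#' @param x a \linkS4class{BarseqExperiment}.
#' @param countsPath,sampleSheetPath output TSV paths (sample sheet optional).
#' @param header optional comment line (e.g. units and config hash) written
#'   before the column header.
#' @return invisibly, the counts path.
#' @export
writeCountTable <- function(x, countsPath, sampleSheetPath = NULL,
                            header = NULL) {
    df <- data.frame(gene = rownames(x), counts(x), check.names = FALSE)
    writeTsv(df, countsPath, header)
    if (!is.null(sampleSheetPath))
        writeTsv(sampleData(x), sampleSheetPath, header)
    invisible(countsPath)
}

writeTsv <- function(df, path, header = NULL) {
    con <- file(path, "wt")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
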