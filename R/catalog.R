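#' Load a barcode catalog from a TSV file
#'
#' Reads a tab-separated table with header columns \code{barcode} and
#' \code{gene} and builds a \linkS4class{BarcodeCatalog}.  Exact duplicate
#' (barcode, gene) rows are collapsed; barcodes that map to more than one
#' distinct gene are ambiguous for quantification and are moved to the
#' discarded set.  All retained barcodes must share one length.
#'
#' @param path path to the catalog TSV (UTF-8, tab-separated, header
#'   required).
#' @param barcodeLength expected barcode length; defaults to the observed
#'   common length.  A catalog with mixed barcode lengths is rejected.
#' @return a \linkS4class{BarcodeCatalog}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("barcode\tgene",
#'              "ACGTACGTACGTACGTACGT\tYAL001C",
#'              "TTTTACGTACGTACGTACGT\tYAL002W"), tsv)
#' loadCatalog(tsv)
#' @export
loadCatalog <- function(path, barcodeLength = NULL) {
    if (!file.exists(path)) stop("catalog file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    if (!length(lines)) stop("catalog file is empty: ", path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    bcCol <- match("barcode", header)
    geneCol <- match("gene", header)
    if (is.na(bcCol) || is.na(geneCol))
        stop("catalog header must contain columns 'barcode' and 'gene'")
    body <- lines[-1]
    body <- body[nzchar(body)]
    if (!length(body)) stop("catalog has a header but no entries")
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < max(bcCol, geneCol))
    if (length(bad))
        stop(sprintf("malformed catalog row at line %d: expected >= %d columns, got %d",
                     bad[1] + 1L, max(bcCol, geneCol), nf[bad[1]]))
    barcode <- vapply(fields, `[[`, "", bcCol)
    gene <- vapply(fields, `[[`, "", geneCol)
    nonACGT <- grepl("[^ACGT]", barcode)
    if (any(nonACGT))
        stop(sprintf("non-ACGT barcode at line %d: '%s'",
                     which(nonACGT)[1] + 1L, barcode[which(nonACGT)[1]]))
    lens <- unique(nchar(barcode))
    if (length(lens) > 1)
        stop("mixed barcode lengths in catalog: ",
             paste(sort(lens), collapse = ", "))
    if (is.null(barcodeLength)) barcodeLength <- lens
    if (lens != barcodeLength)
        stop(sprintf("barcode length %d does not match expected %d",
                     lens, barcodeLength))

    df <- unique(data.frame(barcode = barcode, gene = gene,
                            stringsAsFactors = FALSE))
    ngenes <- tapply(df$gene, df$barcode, function(g) length(unique(g)))
    ambiguous <- names(ngenes)[ngenes > 1]
    keep <- df[!df$barcode %in% ambiguous, , drop = FALSE]
    keep <- keep[order(keep$barcode), , drop = FALSE]  # sorted exact-match index
    rownames(keep) <- NULL
    new("BarcodeCatalog", entries = keep,
        discarded = sort(ambiguous),
        barcodeLength = as.integer(barcodeLength))
}

#' Extract barcodes downstream of an exact flank match
#'
#' Finds the first exact occurrence of \code{flank} in each read and returns
#' the \code{barcodeLength}-mer immediately following it.  Reads without the
#' flank, or with fewer than \code{barcodeLength} bases left after it, yield
#' \code{NA}.  Quality scores are never consulted: downstream perfect-match
#' counting already discards errored barcodes.
#'
#' @param reads character vector of read sequences.
#' @param flank non-empty upstream flanking sequence searched for literally.
#' @param barcodeLength barcode length to extract (default 20).
#' @return character vector of barcodes, \code{NA} where extraction failed.
#' @export
extractBarcode <- function(reads, flank, barcodeLength = 20L) {
    if (!is.character(flank) || length(flank) != 1L || !nzchar(flank))
        stop("flank must be a single non-empty string")
    pos <- regexpr(flank, reads, fixed = TRUE)
    start <- ifelse(pos > 0, pos + nchar(flank), NA_integer_)
    bc <- substr(reads, start, start + barcodeLength - 1L)
    bc[is.na(start) | nchar(bc) < barcodeLength] <- NA_character_
    bc
}
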