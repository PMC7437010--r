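flank <- "GATGTCCACGAGGTCTCT"

test_that("countReads counts only perfect full-length matches", {
    b1 <- strrep("ACGT", 5)
    b2 <- strrep("GGCA", 5)
    cat <- loadCatalog(writeCatalogTsv(c(b1, b2), c("geneA", "geneB")))

    reads <- rep(paste0("AA", flank, b1, "CC"), 100)
    bse <- countReads(reads, cat, "s1", flank = flank)
    expect_equal(unname(counts(bse)["geneA", 1]), 100)
    expect_equal(unname(counts(bse)["geneB", 1]), 0)

    # one substitution in the barcode: dropped
    bad <- paste0("AA", flank, sub("A", "T", b1), "CC")
    bse2 <- countReads(c(reads, rep(bad, 5)), cat, "s1", flank = flank)
    expect_equal(unname(counts(bse2)["geneA", 1]), 100)
    s <- S4Vectors::metadata(bse2)$countSummary$s1
    expect_equal(s$total, 105)
    expect_equal(s$matched, 100)
})

test_that("reads carrying a discarded ambiguous barcode contribute nothing", {
    b1 <- strrep("ACGT", 5)
    b2 <- strrep("GGCA", 5)
    cat <- loadCatalog(writeCatalogTsv(c(b1, b1, b2),
                                       c("geneA", "geneB", "geneC")))
    reads <- rep(paste0(flank, b1), 50)
    bse <- countReads(reads, cat, "s1", flank = flank)
    expect_true(all(counts(bse) == 0))
    expect_equal(S4Vectors::metadata(bse)$countSummary$s1$ambiguous_discarded, 50)
})

test_that("FASTQ structure violations are hard errors with a record index", {
    p <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), p)
    expect_error(readFastqReads(p), "record 2")
    writeLines(c("@r1", "ACGT", "x", "IIII"), p)
    expect_error(readFastqReads(p), "'\\+'")
    writeLines(c("r1", "ACGT", "+", "IIII"), p)
    expect_error(readFastqReads(p), "'@'")
})

test_that("emitFastq/countReads round trip is exact at zero error rate", {
    genes <- sprintf("g%02d", 1:40)
    cat <- randomCatalog(genes, seed = 5)
    for (seed in c(1, 9, 33)) {
        set.seed(seed)
        planted <- setNames(rpois(40, 25), genes)
        fq <- tempfile(fileext = ".fastq.gz")
        emitFastq(planted, cat, flank, fq, errorRate = 0, seed = seed)
        got <- counts(countReads(fq, cat, "s1", flank = flank))[genes, 1]
        expect_identical(unname(got), as.numeric(planted))
    }
})

test_that("with errors, totals never exceed planted and every counted read matched", {
    genes <- sprintf("g%02d", 1:30)
    cat <- randomCatalog(genes, seed = 2)
    planted <- setNames(rep(50, 30), genes)
    fq <- tempfile(fileext = ".fastq")
    emitFastq(planted, cat, flank, fq, errorRate = 0.05, seed = 4)
    bse <- countReads(fq, cat, "s1", flank = flank)
    expect_lte(sum(counts(bse)), sum(planted))
    expect_true(all(counts(bse)[, 1] <= planted))
    # re-scan: every extracted barcode that was counted is a catalog barcode
    reads <- readFastqReads(fq)
    bc <- extractBarcode(reads, flank, 20)
    matched <- bc %in% catalogEntries(cat)$barcode
    expect_equal(sum(counts(bse)), sum(matched))
})

test_that("reverse-complement fallback recovers flipped reads when enabled", {
    b1 <- strrep("ACGT", 5)
    cat <- loadCatalog(writeCatalogTsv(b1, "geneA"))
    fwd <- paste0("AA", flank, b1, "CC")
    rc <- vapply(strsplit(chartr("ACGT", "TGCA", fwd), NULL),
                 function(ch) paste(rev(ch), collapse = ""), "")
    expect_equal(unname(counts(countReads(rc, cat, "s", flank = flank))[1, 1]), 0)
    expect_equal(unname(counts(countReads(rc, cat, "s", flank = flank,
                                          tryReverseComplement = TRUE))[1, 1]), 1)
})
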