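Package: barseqpop
Title: Population Dynamics of Pooled Barcoded Deletion Libraries from Bar-seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the population dynamics of pooled, barcoded
    mutant libraries (such as the Saccharomyces cerevisiae deletion
    collection) profiled by barcode sequencing (Bar-seq) across seed trains
    and batch or fed-batch cultivations. Covers barcode extraction and
    perfect-match counting from FASTQ, starting-pool filtering and
    pseudocount normalization, detection and diversity-loss tracking,
    Pearson correlation matrices, Bray-Curtis beta-diversity statistics
    (PCoA, non-metric multidimensional scaling, PERMANOVA with restricted
    permutations, beta dispersion), classification of lost, depleted and
    enriched mutants with set comparisons and hypergeometric term
    enrichment, plus a pooled-competition simulator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, Metagenomics, Microbiome, PooledScreens, Software
RoxygenNote: 7.3.3
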