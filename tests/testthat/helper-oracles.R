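# Independent brute-force oracles and tiny fixture builders.  Each oracle
# is written as the most literal possible rendition of the definition, so
# the implementation under test is never on both sides of a comparison.

makeBse <- function(counts, condition = rep("A", ncol(counts)),
                    time_h = seq_len(ncol(counts)) - 1,
                    vessel = "bioreactor") {
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    BarseqExperiment(counts, data.frame(
        sample_id = colnames(counts), condition = condition,
        vessel = vessel, time_h = time_h, row.names = colnames(counts)))
}

writeCatalogTsv <- function(barcode, gene, path = tempfile(fileext = ".tsv")) {
    writeLines(c("barcode\tgene", paste(barcode, gene, sep = "\t")), path)
    path
}

# pairwise loop, scalar accumulation
bruteBray <- function(m) {
    n <- nrow(m)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        num <- 0; den <- 0
        for (g in seq_len(ncol(m))) {
            num <- num + min(m[i, g], m[j, g])
            den <- den + m[i, g] + m[j, g]
        }
        d[i, j] <- 1 - 2 * num / den
    }
    d
}

# literal sum over the upper tail of the hypergeometric pmf
bruteHyper <- function(k, K, n, N) {
    tot <- 0
    for (i in k:min(n, K))
        tot <- tot + choose(K, i) * choose(N - K, n - i)
    tot / choose(N, n)
}

# literal step-up: sort, take running minima from the largest rank down
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
    out <- numeric(m)
    out[o] <- q
    out
}

# membership-key enumeration of a Venn partition
bruteVenn <- function(sets) {
    universe <- unique(unlist(sets))
    out <- list()
    for (g in universe) {
        inSets <- names(sets)[vapply(sets, function(s) g %in% s, NA)]
        key <- paste(inSets, collapse = "&")
        out[[key]] <- c(out[[key]], g)
    }
    out
}

# one-factor pseudo-F recomputed from first principles on a distance matrix
bruteFstat <- function(D, g) {
    n <- nrow(D)
    g <- as.character(g)
    sst <- sum(D[upper.tri(D)]^2) / n
    ssw <- 0
    for (lv in unique(g)) {
        idx <- which(g == lv)
        sub <- D[idx, idx, drop = FALSE]
        ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}
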