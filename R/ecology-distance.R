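#' Bray-Curtis dissimilarity between samples
#'
#' Compositional dissimilarity
#' \deqn{d_{ij} = 1 - \frac{2\sum_g \min(x_{ig}, x_{jg})}{\sum_g x_{ig} + \sum_g x_{jg}}}
#' computed between all sample pairs.  0 for identical compositions, 1 for
#' disjoint supports.  On a \linkS4class{BarseqExperiment} the pseudocounted
#' abundance assay is used (run [normalizeAbundance()] first).
#'
#' @param x a \linkS4class{BarseqExperiment} with an abundance assay, or a
#'   numeric samples-by-features matrix with non-negative rows.
#' @return a [stats::dist] object labelled by sample id.
#' @export
brayCurtis <- function(x) {
    m <- if (is(x, "BarseqExperiment")) t(abundances(x)) else as.matrix(x)
    if (any(m < 0)) stop("Bray-Curtis requires non-negative abundances")
    rs <- rowSums(m)
    if (any(rs == 0))
        stop("sample(s) with zero total abundance: ",
             paste(rownames(m)[rs == 0], collapse = ", "))
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) {
        shared <- colSums(pmin(t(m[-seq_len(i), , drop = FALSE]), m[i, ]))
        d[i, (i + 1L):n] <- 1 - 2 * shared / (rs[(i + 1L):n] + rs[i])
    }
    stats::as.dist(d + t(d))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the Gower-centered matrix \eqn{-\frac12 D^2}:
#' coordinates are taken from the top-k positive eigenvalues; negative
#' eigenvalues (Bray-Curtis is not Euclidean-embeddable) are retained in the
#' spectrum so that downstream corrections — the imaginary-axis adjustment
#' in [betaDispersion()] — can account for them.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param k number of coordinate axes, \code{k < n} samples.
#' @return an \linkS4class{Ordination} (method \code{"PCoA"}) whose
#'   \code{eigenvalues} hold the full centered spectrum.
#' @export
pcoa <- function(d, k = 2L) {
    D <- as.matrix(d)
    n <- nrow(D)
    if (k >= n) stop("k must be smaller than the number of samples")
    ec <- gowerEigen(D)
    lambda <- ec$values
    pos <- which(lambda > max(abs(lambda), 1e-300) * 1e-9)
    use <- pos[seq_len(min(k, length(pos)))]
    pts <- matrix(0, n, k, dimnames = list(rownames(D), paste0("Axis", seq_len(k))))
    if (length(use))
        pts[, seq_along(use)] <- ec$vectors[, use, drop = FALSE] %*%
            diag(sqrt(lambda[use]), length(use))
    new("Ordination", points = pts, stress = NA_real_,
        eigenvalues = lambda, method = "PCoA",
        details = list(k = as.integer(k), nPositive = length(pos)))
}

# Gower-centered eigendecomposition of -D^2/2, eigenvalues sorted decreasing
gowerEigen <- function(D) {
    A <- -0.5 * D^2
    n <- nrow(A)
    J <- diag(n) - 1 / n
    G <- J %*% A %*% J
    ec <- eigen((G + t(G)) / 2, symmetric = TRUE)
    ec
}
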