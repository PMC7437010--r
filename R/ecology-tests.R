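#' Distance-based permutational ANOVA (PERMANOVA, one term)
#'
#' Anderson's distance-based decomposition for a single factor:
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n}, \eqn{SS_{within}} computed
#' analogously within groups, and
#' \eqn{F = (SS_{between}/(a-1)) / (SS_{within}/(n-a))}.  Significance comes
#' from permuting group labels.
#'
#' With repeated measures the free shuffle is invalid, so \code{strata}
#' restricts the permutations: labels are shuffled only within each stratum
#' — except when every stratum carries a single label value (e.g. a feeding
#' regime constant over a reactor's time series), in which case whole strata
#' exchange labels, making the stratum (reactor) the exchangeable unit and
#' never splitting its samples.
#'
#' When the number of distinct label arrangements does not exceed the
#' requested permutations the test enumerates them all and reports the exact
#' permutation p-value (fraction of arrangements, identity included, with
#' \eqn{F \ge F_{obs}}); otherwise it samples and uses
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param labels grouping vector/factor, one value per sample (>= 2 groups).
#' @param nPermutations permutations to draw (default 999).
#' @param strata optional stratum id per sample restricting the shuffles.
#' @param seed integer seed for the permutation draws.
#' @param term label naming the tested factor in the result.
#' @param returnPermutations keep the permuted label matrix in
#'   \code{details$permutations} (for permutation-trace audits).
#' @return a \linkS4class{PermanovaResult}.
#' @export
permanova <- function(d, labels, nPermutations = 999L, strata = NULL,
                      seed = NULL, term = "group",
                      returnPermutations = FALSE) {
    D2 <- as.matrix(d)^2
    n <- nrow(D2)
    labels <- as.factor(labels)
    if (length(labels) != n) stop("one label per sample required")
    if (nlevels(droplevels(labels)) < 2L) stop("need at least 2 groups")
    labels <- droplevels(labels)
    a <- nlevels(labels)
    if (!is.null(seed)) set.seed(seed)

    ssWithin <- function(g) {
        s <- 0
        for (lv in unique(g)) {
            idx <- which(g == lv)
            s <- s + sum(D2[idx, idx]) / (2 * length(idx))
        }
        s
    }
    ssTotal <- sum(D2) / (2 * n)
    fStat <- function(g) {
        ssw <- ssWithin(g)
        ((ssTotal - ssw) / (a - 1)) / (ssw / (n - a))
    }
    Fobs <- fStat(labels)

    blockMode <- FALSE
    if (!is.null(strata)) {
        strata <- as.factor(strata)
        if (length(strata) != n) stop("one stratum per sample required")
        perBlock <- tapply(as.character(labels), strata,
                           function(x) length(unique(x)))
        blockMode <- all(perBlock == 1L)
        if (blockMode && nlevels(droplevels(strata)) < 2L)
            stop("degenerate strata: fewer than 2 exchangeable units")
    }

    permuteOnce <- function() {
        if (is.null(strata)) return(labels[sample.int(n)])
        if (blockMode) {
            blocks <- levels(strata)
            blockLab <- vapply(blocks, function(b)
                as.character(labels[strata == b][1]), "")
            newLab <- blockLab[sample.int(length(blocks))]
            factor(newLab[match(strata, blocks)], levels = levels(labels))
        } else {
            out <- labels
            for (b in levels(strata)) {
                idx <- which(strata == b)
                out[idx] <- labels[idx][sample.int(length(idx))]
            }
            out
        }
    }

    exhaustiveArrangements <- function() {
        if (is.null(strata)) {
            msetPermutations(as.character(labels), limit = nPermutations + 1)
        } else if (blockMode) {
            blocks <- levels(strata)
            blockLab <- vapply(blocks, function(b)
                as.character(labels[strata == b][1]), "")
            bl <- msetPermutations(blockLab, limit = nPermutations + 1)
            if (is.null(bl)) return(NULL)
            t(apply(bl, 1L, function(row) row[match(strata, blocks)]))
        } else NULL
    }

    arr <- exhaustiveArrangements()
    if (!is.null(arr)) {
        checkComplete <- function(g) {
            if (length(unique(g)) < a) stop("degenerate strata: a group vanished under permutation")
            g
        }
        Fall <- apply(arr, 1L, function(row)
            fStat(checkComplete(factor(row, levels = levels(labels)))))
        p <- mean(Fall >= Fobs - 1e-12)
        res <- new("PermanovaResult", term = term, pseudoF = Fobs,
                   R2 = (ssTotal - ssWithin(labels)) / ssTotal, pValue = p,
                   nPermutations = nrow(arr) - 1L,
                   strata = if (is.null(strata)) NA_character_ else "strata",
                   details = list(
                       exhaustive = TRUE, permF = Fall,
                       SS = c(total = ssTotal,
                              within = ssWithin(labels),
                              between = ssTotal - ssWithin(labels)),
                       permutations = if (returnPermutations) arr else NULL))
        return(res)
    }

    permLabels <- if (returnPermutations)
        matrix(NA_character_, nPermutations, n) else NULL
    Fperm <- numeric(nPermutations)
    for (i in seq_len(nPermutations)) {
        g <- permuteOnce()
        if (length(unique(g)) < a)
            stop("degenerate strata: a group vanished under permutation")
        Fperm[i] <- fStat(g)
        if (returnPermutations) permLabels[i, ] <- as.character(g)
    }
    p <- (1 + sum(Fperm >= Fobs - 1e-12)) / (1 + nPermutations)
    new("PermanovaResult", term = term, pseudoF = Fobs,
        R2 = (ssTotal - ssWithin(labels)) / ssTotal, pValue = p,
        nPermutations = as.integer(nPermutations),
        strata = if (is.null(strata)) NA_character_ else "strata",
        details = list(exhaustive = FALSE, permF = Fperm,
                       SS = c(total = ssTotal, within = ssWithin(labels),
                              between = ssTotal - ssWithin(labels)),
                       permutations = permLabels))
}

# all distinct permutations of a multiset, or NULL if more than `limit`
msetPermutations <- function(x, limit) {
    tab <- table(x)
    count <- exp(lgamma(length(x) + 1) - sum(lgamma(tab + 1)))
    if (round(count) > limit) return(NULL)
    items <- names(tab)
    rec <- function(remaining) {
        if (sum(remaining) == 0L) return(list(character()))
        out <- list()
        for (k in seq_along(items)) {
            if (remaining[k] == 0L) next
            rem <- remaining
            rem[k] <- rem[k] - 1L
            for (tail in rec(rem))
                out[[length(out) + 1L]] <- c(items[k], tail)
        }
        out
    }
    do.call(rbind, rec(as.integer(tab)))
}

#' Homogeneity of multivariate dispersion (beta dispersion)
#'
#' Projects the samples into full principal-coordinate space (positive axes
#' real, negative axes imaginary) and measures each sample's distance to its
#' group centroid, subtracting the squared imaginary-axis component from the
#' squared real-axis component and flooring at zero — the standard
#' correction for non-Euclidean dissimilarities such as Bray-Curtis.  The
#' distances are compared across groups with a classical one-way ANOVA F
#' (F-distribution p-value) and a permutation p-value, plus pairwise
#' permutation comparisons adjusted by Benjamini-Hochberg.  Groups with a
#' single sample keep their distance (0 by construction) but are excluded
#' from all tests.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param groups grouping vector/factor, one value per sample.
#' @param nPermutations permutations for the global and pairwise tests.
#' @param seed integer seed for the permutation draws.
#' @return a \linkS4class{DispersionResult}.
#' @export
betaDispersion <- function(d, groups, nPermutations = 999L, seed = NULL) {
    D <- as.matrix(d)
    n <- nrow(D)
    groups <- droplevels(as.factor(groups))
    if (length(groups) != n) stop("one group per sample required")
    if (!is.null(seed)) set.seed(seed)

    ec <- gowerEigen(D)
    lambda <- ec$values
    tolEig <- max(abs(lambda), 1e-300) * 1e-8
    posAx <- which(lambda > tolEig)
    negAx <- which(lambda < -tolEig)
    R <- ec$vectors[, posAx, drop = FALSE] %*%
        diag(sqrt(lambda[posAx]), length(posAx))
    I <- ec$vectors[, negAx, drop = FALSE] %*%
        diag(sqrt(-lambda[negAx]), length(negAx))

    dists <- numeric(n)
    for (lv in levels(groups)) {
        idx <- which(groups == lv)
        cR <- colMeans(R[idx, , drop = FALSE])
        cI <- colMeans(I[idx, , drop = FALSE])
        d2 <- rowSums(sweep(R[idx, , drop = FALSE], 2L, cR)^2) -
              rowSums(sweep(I[idx, , drop = FALSE], 2L, cI)^2)
        dists[idx] <- sqrt(pmax(d2, 0))
    }
    names(dists) <- rownames(D)
    groupMeans <- tapply(dists, groups, mean)

    sizes <- table(groups)
    testable <- names(sizes)[sizes >= 2L]
    excluded <- setdiff(levels(groups), testable)
    anovaF <- anovaP <- permP <- NA_real_
    pairwise <- data.frame(groupA = character(), groupB = character(),
                           F = numeric(), p_perm = numeric(),
                           q_BH = numeric())
    if (length(testable) >= 2L) {
        sel <- groups %in% testable
        y <- dists[sel]
        g <- droplevels(groups[sel])
        anovaF <- oneWayF(y, g)
        k <- nlevels(g)
        anovaP <- stats::pf(anovaF, k - 1, length(y) - k, lower.tail = FALSE)
        Fperm <- replicate(nPermutations, oneWayF(y, g[sample.int(length(y))]))
        permP <- (1 + sum(Fperm >= anovaF - 1e-12)) / (1 + nPermutations)
        prs <- utils::combn(testable, 2L)
        pp <- apply(prs, 2L, function(pr) {
            s <- g %in% pr
            y2 <- y[s]; g2 <- droplevels(g[s])
            Fo <- oneWayF(y2, g2)
            Fp <- replicate(nPermutations,
                            oneWayF(y2, g2[sample.int(length(y2))]))
            c(Fo, (1 + sum(Fp >= Fo - 1e-12)) / (1 + nPermutations))
        })
        pairwise <- data.frame(groupA = prs[1, ], groupB = prs[2, ],
                               F = pp[1, ], p_perm = pp[2, ],
                               q_BH = bhAdjust(pp[2, ]))
    }
    new("DispersionResult", distances = dists, groups = groups,
        groupMeans = as.numeric(groupMeans) |>
            stats::setNames(names(groupMeans)),
        anovaF = anovaF, anovaP = anovaP, permP = permP,
        pairwise = pairwise,
        details = list(eigenvalues = lambda, nImaginaryAxes = length(negAx),
                       excludedGroups = excluded, seed = seed,
                       nPermutations = as.integer(nPermutations)))
}

# classical one-way ANOVA F on a numeric response
oneWayF <- function(y, g) {
    g <- droplevels(as.factor(g))
    gm <- mean(y)
    means <- tapply(y, g, mean)
    ns <- tapply(y, g, length)
    ssb <- sum(ns * (means - gm)^2)
    ssw <- sum((y - means[g])^2)
    k <- nlevels(g)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / (k - 1)) / (ssw / (length(y) - k))
}
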