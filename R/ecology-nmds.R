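#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimizes Kruskal stress-1,
#' \deqn{S = \sqrt{\sum_{i<j} (d_{ij} - \hat d_{ij})^2 / \sum_{i<j} d_{ij}^2},}
#' where \eqn{d} are configuration distances and \eqn{\hat d} the monotone
#' (isotonic, pool-adjacent-violators) regression of \eqn{d} on the ranks of
#' the observed dissimilarities.  Ties in the observed dissimilarities are
#' treated in the primary fashion (tied pairs may take distinct disparities).
#'
#' One restart starts from the PCoA configuration of \code{d}, the remaining
#' \code{nRestarts - 1} from random Gaussian configurations; within each
#' restart a gradient step with backtracking line search is only ever
#' accepted if it lowers the (freshly re-isotonized) stress, so the stress
#' trace is non-increasing by construction.  The best restart is returned;
#' given the same seed the result is reproducible.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix over
#'   \code{n >= k + 2} samples.
#' @param k embedding dimension (default 2).
#' @param nRestarts number of starts (default 20, including the PCoA start).
#' @param maxIter maximum accepted gradient steps per restart (default 300).
#' @param seed integer seed controlling the random starts.
#' @param tol relative stress-improvement threshold declaring convergence.
#' @return an \linkS4class{Ordination} (method \code{"NMDS"}).  On
#'   non-convergence the best configuration is returned with a warning and
#'   \code{details$converged = FALSE}.  \code{details$trace} holds the
#'   accepted stress values of the winning restart,
#'   \code{details$stressPerRestart} the final stress of every restart.
#' @export
nmds <- function(d, k = 2L, nRestarts = 20L, maxIter = 300L, seed = NULL,
                 tol = 1e-7) {
    D <- as.matrix(d)
    n <- nrow(D)
    if (n < k + 2L) stop("NMDS needs at least k + 2 samples")
    if (!is.null(seed)) set.seed(seed)
    dObs <- D[lower.tri(D)]
    ii <- unlist(lapply(seq_len(n - 1L), function(j) (j + 1L):n))
    jj <- rep(seq_len(n - 1L), times = (n - 1L):1L)

    if (all(dObs == 0)) {
        pts <- matrix(0, n, k, dimnames = list(rownames(D), NULL))
        return(new("Ordination", points = pts, stress = 0,
                   eigenvalues = numeric(), method = "NMDS",
                   details = list(converged = TRUE, trace = 0,
                                  stressPerRestart = 0,
                                  nRestarts = 1L, seed = seed)))
    }

    best <- NULL
    perRestart <- numeric(nRestarts)
    traces <- vector("list", nRestarts)
    convs <- logical(nRestarts)
    pcoaStart <- ordinationPoints(pcoa(D, k))
    for (r in seq_len(nRestarts)) {
        X0 <- if (r == 1L) pcoaStart else matrix(stats::rnorm(n * k), n, k)
        fit <- nmdsOneRestart(X0, dObs, ii, jj, maxIter, tol)
        perRestart[r] <- fit$stress
        traces[[r]] <- fit$trace
        convs[r] <- fit$converged
        if (is.null(best) || fit$stress < best$stress) {
            best <- fit
            best$restart <- r
        }
    }
    if (!best$converged)
        warning("NMDS did not converge within maxIter; returning best configuration")
    pts <- best$X
    rownames(pts) <- rownames(D)
    new("Ordination", points = pts, stress = best$stress,
        eigenvalues = numeric(), method = "NMDS",
        details = list(converged = best$converged, trace = best$trace,
                       stressPerRestart = perRestart,
                       tracePerRestart = traces,
                       convergedPerRestart = convs,
                       bestRestart = best$restart,
                       nRestarts = as.integer(nRestarts), seed = seed))
}

# stress-1 plus disparities for a configuration distance vector
nmdsStress <- function(dCur, dObs) {
    ord <- order(dObs, dCur)             # primary tie treatment
    yf <- stats::isoreg(dCur[ord])$yf    # PAVA on config distances in rank order
    dhat <- numeric(length(dCur))
    dhat[ord] <- yf
    list(stress = sqrt(sum((dCur - dhat)^2) / sum(dCur^2)), dhat = dhat)
}

nmdsOneRestart <- function(X, dObs, ii, jj, maxIter, tol) {
    eps <- 1e-12
    configDist <- function(X) {
        diffs <- X[ii, , drop = FALSE] - X[jj, , drop = FALSE]
        pmax(sqrt(rowSums(diffs^2)), eps)
    }
    dCur <- configDist(X)
    st <- nmdsStress(dCur, dObs)
    stress <- st$stress
    trace <- stress
    alpha <- 0.2
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
        if (stress < 1e-10) { converged <- TRUE; break }
        Sstar <- sum((dCur - st$dhat)^2)
        Tstar <- sum(dCur^2)
        gPair <- stress * ((dCur - st$dhat) / Sstar - dCur / Tstar)
        w <- gPair / dCur
        diffs <- (X[ii, , drop = FALSE] - X[jj, , drop = FALSE]) * w
        grad <- rowsum(diffs, ii, reorder = FALSE)
        gi <- rowsum(-diffs, jj, reorder = FALSE)
        G <- matrix(0, nrow(X), ncol(X))
        G[as.integer(rownames(grad)), ] <- grad
        G[as.integer(rownames(gi)), ] <- G[as.integer(rownames(gi)), ] + gi
        gnorm <- sqrt(sum(G^2))
        if (gnorm < 1e-14) { converged <- TRUE; break }
        scale <- sqrt(sum(X^2)) / gnorm
        improved <- FALSE
        a <- alpha
        for (half in seq_len(30L)) {
            Xnew <- X - a * scale * G
            dNew <- configDist(Xnew)
            stNew <- nmdsStress(dNew, dObs)
            if (stNew$stress < stress) { improved <- TRUE; break }
            a <- a / 2
        }
        if (!improved) { converged <- TRUE; break }
        rel <- (stress - stNew$stress) / stress
        X <- Xnew; dCur <- dNew; st <- stNew; stress <- stNew$stress
        trace <- c(trace, stress)
        alpha <- min(a * 1.5, 1)
        if (rel < tol) { converged <- TRUE; break }
    }
    list(X = X, stress = stress, trace = trace, converged = converged)
}
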