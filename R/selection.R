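#' Classify mutant selection between two timepoints
#'
#' Applies the count-and-abundance rules for one condition and time window:
#' a mutant is \emph{lost} when its raw count at the later timepoint falls
#' below \code{lossThreshold} (regardless of its abundance trend); otherwise
#' \emph{depleted} when its relative abundance dropped by at least
#' \code{depletionFraction} (default 50\%); otherwise \emph{enriched} when
#' its relative abundance rose at least \code{enrichmentFold}-fold (an
#' interpretation knob — the qualitative "more fit" criterion is not
#' quantified by convention); otherwise \emph{retained}.  Statuses are
#' mutually exclusive and exhaustive over the gene universe.
#'
#' @param x a \linkS4class{BarseqExperiment} carrying both the counts and
#'   abundance assays (run [normalizeAbundance()] first).
#' @param condition condition to classify.
#' @param tFrom,tTo window boundaries in hours; both timepoints must exist
#'   for the condition.
#' @param lossThreshold count below which a mutant is lost (default 10).
#' @param depletionFraction minimum relative-abundance drop calling
#'   depletion (default 0.5).
#' @param enrichmentFold minimum abundance fold increase calling enrichment
#'   (default 2).
#' @return data.frame with one row per gene: gene, condition, t_from_h,
#'   t_to_h, status (factor lost/depleted/enriched/retained), count_from,
#'   count_to, ab_from, ab_to, fold_change.
#' @export
classifySelection <- function(x, condition, tFrom, tTo,
                              lossThreshold = 10L, depletionFraction = 0.5,
                              enrichmentFold = 2.0) {
    stopifnot(is(x, "BarseqExperiment"))
    sd <- sampleData(x)
    pick <- function(t) {
        id <- rownames(sd)[sd$condition == condition & sd$time_h == t]
        if (!length(id))
            stop(sprintf("no sample for condition '%s' at %g h", condition, t))
        id[1]
    }
    sFrom <- pick(tFrom); sTo <- pick(tTo)
    cts <- counts(x); ab <- abundances(x)
    cf <- cts[, sFrom]; ct <- cts[, sTo]
    af <- ab[, sFrom]; at <- ab[, sTo]
    status <- ifelse(ct < lossThreshold, "lost",
              ifelse(at <= (1 - depletionFraction) * af, "depleted",
              ifelse(at >= enrichmentFold * af, "enriched", "retained")))
    data.frame(gene = rownames(x), condition = condition,
               t_from_h = tFrom, t_to_h = tTo,
               status = factor(status, levels = c("lost", "depleted",
                                                  "enriched", "retained")),
               count_from = cf, count_to = ct,
               ab_from = af, ab_to = at, fold_change = at / af,
               row.names = NULL)
}

#' Inclusion-exclusion partition of gene sets across conditions
#'
#' Given one gene set per condition (e.g. the lost-or-depleted mutants of
#' each bioreactor), produces the full Venn partition: every non-empty
#' combination of conditions gets a region holding the genes in exactly
#' those conditions.  Region sizes sum to the size of the union.
#'
#' @param sets named list of character vectors (>= 2 conditions), or a named
#'   list of [classifySelection()] call tables combined with
#'   \code{statuses}.
#' @param statuses when \code{sets} holds call tables, the statuses whose
#'   genes enter each set (default \code{c("lost", "depleted")}).
#' @return data.frame with columns region (conditions joined by \code{"&"}),
#'   n, and a list-column genes.
#' @export
compareConditions <- function(sets, statuses = c("lost", "depleted")) {
    if (length(sets) < 2L) stop("need at least 2 conditions")
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("sets must be named by condition")
    sets <- lapply(sets, function(s) {
        if (is.data.frame(s)) {
            if (!all(c("gene", "status") %in% colnames(s)))
                stop("call tables need 'gene' and 'status' columns")
            unique(s$gene[s$status %in% statuses])
        } else unique(as.character(s))
    })
    conds <- names(sets)
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                                 dimnames = list(NULL, conds))
    key <- apply(member, 1L, function(row)
        paste(conds[row], collapse = "&"))
    combos <- unlist(lapply(seq_along(conds), function(k)
        utils::combn(conds, k, paste, collapse = "&")))
    genes <- lapply(combos, function(cb) universe[key == cb])
    data.frame(region = combos, n = lengths(genes),
               genes = I(genes), row.names = NULL)
}

#' Load a gene-to-term annotation table
#'
#' Reads a TSV with columns \code{gene}, \code{term} and optionally
#' \code{description}, and fixes the background gene universe that
#' enrichment tests condition on.  Restricting the background to the genes
#' the experiment could actually observe (the post-t0-filter universe)
#' avoids detection-bias inflation relative to a whole-genome background.
#'
#' @param path annotation TSV.
#' @param background character vector of background genes; defaults to all
#'   genes in the table.  Annotated genes outside the background are
#'   dropped (they could never be observed).
#' @return list with \code{gene2terms} (named list), \code{termDesc} (named
#'   character) and \code{background}.
#' @export
loadAnnotation <- function(path, background = NULL) {
    tab <- utils::read.delim(path, comment.char = "#")
    if (!all(c("gene", "term") %in% colnames(tab)))
        stop("annotation TSV needs columns 'gene' and 'term'")
    if (is.null(tab$description)) tab$description <- tab$term
    if (is.null(background)) background <- unique(tab$gene)
    tab <- tab[tab$gene %in% background, , drop = FALSE]
    list(gene2terms = lapply(split(tab$term, tab$gene), unique),
         termDesc = stats::setNames(tab$description, tab$term)[
             !duplicated(tab$term)],
         background = unique(background))
}

#' Hypergeometric term enrichment of a gene list
#'
#' For every annotation term with at least one hit in the list, computes the
#' upper-tail hypergeometric p-value
#' \deqn{p = \sum_{i \ge k} {K \choose i}{N-K \choose n-i} / {N \choose n}}
#' (k hits among the n list genes, K term genes among the N background
#' genes), the fold enrichment \eqn{(k/n)/(K/N)}, and Benjamini-Hochberg
#' q-values across the tested terms.  Results are sorted by q then p.
#'
#' @param geneList character vector of genes, a subset of the annotation
#'   background.
#' @param annotation an annotation object from [loadAnnotation()] (or a list
#'   with the same shape).
#' @return data.frame: term, description, k, n_list, K, N, fold_enrichment,
#'   p, q.
#' @export
hypergeometricEnrichment <- function(geneList, annotation) {
    geneList <- unique(geneList)
    if (!length(geneList)) stop("gene list is empty")
    offenders <- setdiff(geneList, annotation$background)
    if (length(offenders))
        stop("gene(s) absent from background: ",
             paste(offenders, collapse = ", "))
    N <- length(annotation$background)
    nList <- length(geneList)
    g2t <- annotation$gene2terms
    hitTerms <- table(unlist(g2t[intersect(geneList, names(g2t))]))
    if (!length(hitTerms)) return(data.frame(
        term = character(), description = character(), k = integer(),
        n_list = integer(), K = integer(), N = integer(),
        fold_enrichment = numeric(), p = numeric(), q = numeric()))
    termSizes <- table(unlist(lapply(g2t, unique)))
    k <- as.integer(hitTerms)
    K <- as.integer(termSizes[names(hitTerms)])
    p <- stats::phyper(k - 1L, K, N - K, nList, lower.tail = FALSE)
    res <- data.frame(
        term = names(hitTerms),
        description = unname(annotation$termDesc[names(hitTerms)]),
        k = k, n_list = nList, K = K, N = N,
        fold_enrichment = (k / nList) / (K / N),
        p = p, q = bhAdjust(p), row.names = NULL)
    res[order(res$q, res$p, res$term), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Maps p-values to q-values with the step-up rule
#' \eqn{q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j} (capped at 1), returned in
#' the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same length and order.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric())
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    q <- pmin(1, cummin(m / seq(m, 1) * p[o]))
    q[order(o)]
}
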