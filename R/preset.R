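#' Preset landscape and schedule mimicking a scale-up competition study
#'
#' Emits the layout of a pooled-competition scale-up experiment: a shared
#' two-stage seed train (Seed1, Seed2), then two shake flasks (SF1, SF2), a
#' batch bioreactor (BR, sampled to 72 h) and four fed-batch bioreactors
#' (CF4, CF6 constant feed; DF4, DF6 DO-signal feed) sampled at
#' 0/5/24/33/48/72/119 h.  A late-stress phase spanning 48-72 h carries
#' planted negative selection for CF4 and CF6 (weaker for DF4, none for
#' DF6), and CF6 additionally starts its stress in the 33-48 h window —
#' emulating the abrupt diversity collapse that ethanol accumulation under
#' an overfeeding constant-rate regime causes, with CF6 hit hardest.  All
#' other phases are neutral.
#'
#' Generation counts per phase are abstractions (cultivations are specified
#' in hours, not generations): 5 per seed stage, 7 across the batch phase,
#' 6 per fed-batch sampling interval.
#'
#' @param seed integer seed for drawing the planted gene sets.
#' @param nGenes size of the mutant pool (default 3000).
#' @param nStress number of planted stress-sensitive genes per stressed
#'   condition (default 5\% of the pool).
#' @param stressS named per-generation selection coefficients of the
#'   late-stress (48-72 h) phase per condition.
#' @param cf6EarlyS coefficient of CF6's additional 33-48 h stress phase.
#' @return list with \code{landscape} (\linkS4class{FitnessLandscape}),
#'   \code{schedule} (see [processSchedule()]) and \code{plantedSets}
#'   (named list of stress-sensitive genes per condition).
#' @export
presetStudyDesign <- function(seed = 1L, nGenes = 3000L,
                              nStress = round(0.05 * nGenes),
                              stressS = c(CF4 = -0.35, CF6 = -0.75,
                                          DF4 = -0.15),
                              cf6EarlyS = -0.35) {
    set.seed(seed)
    genes <- sprintf("gene%04d", seq_len(nGenes))
    fed <- c("CF4", "CF6", "DF4", "DF6")
    batchOnly <- c("SF1", "SF2", "BR")

    rows <- list(
        data.frame(phase = c("Seed1", "Seed2"), condition = "*",
                   start_h = c(0, 24), end_h = c(24, 48), generations = 5,
                   bottleneck_cells = NA))
    mainPhases <- function(cond, times, gens) {
        data.frame(phase = sprintf("%s_%g_%g", cond, times[-length(times)],
                                   times[-1]),
                   condition = cond,
                   start_h = times[-length(times)], end_h = times[-1],
                   generations = gens, bottleneck_cells = NA)
    }
    tFed <- c(0, 5, 24, 33, 48, 72, 119)
    gFed <- c(2, 3, 2, 6, 6, 6)          # batch ~7 gens, then 6 per interval
    tBatch <- c(0, 5, 24, 33, 48, 72)
    gBatch <- c(2, 3, 2, 6, 6)
    for (cond in fed) rows[[length(rows) + 1L]] <- mainPhases(cond, tFed, gFed)
    for (cond in batchOnly)
        rows[[length(rows) + 1L]] <- mainPhases(cond, tBatch, gBatch)
    sch <- do.call(rbind, rows)
    schedule <- processSchedule(sch$phase, sch$condition, sch$start_h,
                                sch$end_h, sch$generations,
                                sch$bottleneck_cells)

    s <- matrix(0, nGenes, nrow(schedule),
                dimnames = list(genes, schedule$phase))
    plantedSets <- list()
    for (cond in names(stressS)) {
        if (stressS[[cond]] == 0) next
        pg <- sample(genes, nStress)
        plantedSets[[cond]] <- pg
        s[pg, sprintf("%s_48_72", cond)] <- stressS[[cond]]
    }
    if (!is.null(plantedSets$CF6) && cf6EarlyS != 0)
        s[plantedSets$CF6, "CF6_33_48"] <- cf6EarlyS
    list(landscape = FitnessLandscape(s), schedule = schedule,
         plantedSets = plantedSets)
}

#' Synthetic annotation with one planted enriched term
#'
#' Builds a local gene-to-term annotation (a stand-in for a curated
#' genome-wide ontology) in which one focus term annotates exactly the
#' given focus genes, plus random background terms.  Used to validate the
#' enrichment stack: a gene list recovering the focus genes must flag the
#' focus term as enriched.
#'
#' @param background gene universe.
#' @param focusGenes genes the planted term annotates (subset of
#'   background).
#' @param focusTerm id of the planted term.
#' @param nTerms number of additional random terms.
#' @param termSize genes per random term.
#' @param seed integer seed.
#' @return annotation list as from [loadAnnotation()].
#' @export
syntheticAnnotation <- function(background, focusGenes,
                                focusTerm = "planted_stress_response",
                                nTerms = 20L, termSize = 50L, seed = 1L) {
    stopifnot(all(focusGenes %in% background))
    set.seed(seed)
    terms <- list()
    terms[[focusTerm]] <- focusGenes
    for (i in seq_len(nTerms))
        terms[[sprintf("random_term_%02d", i)]] <-
            sample(background, min(termSize, length(background)))
    gene2terms <- list()
    for (tm in names(terms))
        for (g in terms[[tm]])
            gene2terms[[g]] <- c(gene2terms[[g]], tm)
    list(gene2terms = gene2terms,
         termDesc = stats::setNames(names(terms), names(terms)),
         background = background)
}
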