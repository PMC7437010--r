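#' Run the full Bar-seq population-dynamics pipeline from one config
#'
#' Orchestrates count loading (or FASTQ counting), t0 filtering,
#' pseudocount normalization, detection/loss tracking, Pearson correlation,
#' Bray-Curtis, PCoA/NMDS, PERMANOVA and beta dispersion, selection
#' classification, Venn set comparison and term enrichment, writing one TSV
#' per stage into \code{outputDir}.  Stages without their required inputs
#' are skipped and marked so in the report.  Every numeric output carries a
#' comment header naming its units and the config hash; all stochastic
#' stages run under the seed recorded in the config, so rerunning the same
#' config on the same inputs reproduces identical outputs.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized entries (all thresholds optional with the package
#'   defaults): \describe{
#'   \item{counts, sampleSheet}{paths of a count-table TSV and its sample
#'     sheet — or instead \code{fastq} (named list sample id -> path),
#'     \code{catalog}, \code{flank}, \code{sampleSheet}.}
#'   \item{t0Sample, t0Threshold}{starting-pool filter (threshold 10).}
#'   \item{pseudocount, detectionThreshold, lossThresholds}{10, 10,
#'     c(1, 5, 10, 20).}
#'   \item{seed, k, nRestarts, nPermutations, permanovaTerm, strata}{ecology
#'     settings; \code{strata} names a sample-sheet column.}
#'   \item{selection}{list(condition, tFrom, tTo) for the selection stage,
#'     optionally lossThreshold, depletionFraction, enrichmentFold;
#'     \code{conditions} (several) triggers the Venn stage.}
#'   \item{annotation}{annotation TSV for the enrichment stage.}
#'   \item{outputDir}{output directory, created if absent.}}
#' @return the run report: a list with per-stage status, output file paths,
#'   md5 checksums, seeds, collected warnings and the package version.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (is.null(config$outputDir)) stop("config$outputDir is required")
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    cfgFile <- tempfile()
    writeLines(deparse(config[order(names(config))]), cfgFile)
    cfgHash <- unname(tools::md5sum(cfgFile))
    unlink(cfgFile)

    report <- list(stages = list(), files = character(),
                   checksums = character(), seeds = list(),
                   warnings = character(),
                   version = as.character(utils::packageVersion("barseqpop")),
                   configHash = cfgHash)
    seed <- config$seed %||% 1L
    report$seeds$master <- seed
    noteWarn <- function(w) {
        report$warnings <<- c(report$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
    }
    out <- function(name) file.path(config$outputDir, name)
    emit <- function(df, name, units, stage) {
        path <- out(name)
        writeTsv(df, path, sprintf("units=%s config=%s", units, cfgHash))
        report$files[stage] <<- path
        report$checksums[stage] <<- unname(tools::md5sum(path))
        path
    }
    done <- function(stage, status = "ok")
        report$stages[[stage]] <<- status
    fail <- function(stage, e)
        stop(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), call. = FALSE)

    withCallingHandlers({
        # -- counting ----------------------------------------------------
        if (!is.null(config$counts)) {
            bse <- tryCatch(readCountTable(config$counts, config$sampleSheet),
                            error = function(e) fail("count", e))
            done("count", "skipped(input)")
        } else {
            if (is.null(config$fastq) || is.null(config$catalog))
                stop("config needs either counts+sampleSheet or fastq+catalog+sampleSheet")
            catalog <- loadCatalog(config$catalog)
            ss <- readSampleSheet(config$sampleSheet)
            samples <- tryCatch(lapply(names(config$fastq), function(id) {
                countReads(config$fastq[[id]], catalog, sampleId = id,
                           condition = ss[id, "condition"],
                           vessel = ss[id, "vessel"],
                           time_h = ss[id, "time_h"], flank = config$flank)
            }), error = function(e) fail("count", e))
            bse <- combineSamples(samples)
            done("count")
        }
        emit(data.frame(gene = rownames(bse), counts(bse),
                        check.names = FALSE),
             "counts_raw.tsv", "reads", "count")

        # -- t0 filter + normalization ----------------------------------
        if (!is.null(config$t0Sample)) {
            bse <- tryCatch(filterT0(bse, config$t0Sample,
                                     config$t0Threshold %||% 10L),
                            error = function(e) fail("filter_t0", e))
            done("filter_t0")
        } else done("filter_t0", "skipped(no t0Sample)")
        bse <- tryCatch(normalizeAbundance(bse, config$pseudocount %||% 10L),
                        error = function(e) fail("normalize", e))
        done("normalize")
        emit(data.frame(gene = rownames(bse), abundances(bse),
                        check.names = FALSE),
             "abundance.tsv", "relative_abundance", "normalize")

        # -- detection / loss windows -----------------------------------
        detTh <- config$detectionThreshold %||% 10L
        det <- do.call(rbind, lapply(colnames(bse), function(s) {
            pr <- detectionProfile(bse, s, detTh)
            data.frame(sample_id = s, threshold = detTh,
                       n_detected = pr$n_detected,
                       n_not_detected = pr$n_not_detected)
        }))
        emit(det, "detection_profiles.tsv", "gene_count", "detection")
        done("detection")

        sd <- sampleData(bse)
        multi <- names(which(table(sd$condition) >= 2L))
        multi <- multi[vapply(multi, function(cc)
            length(unique(sd$time_h[sd$condition == cc])) >= 2L, NA)]
        if (length(multi)) {
            lw <- do.call(rbind, lapply(multi, function(cc)
                lossWindows(bse, cc,
                            config$lossThresholds %||% c(1L, 5L, 10L, 20L)
                            )$windows))
            emit(lw, "loss_windows.tsv", "gene_count", "loss_windows")
            done("loss_windows")
        } else done("loss_windows", "skipped(<2 timepoints)")

        # -- Pearson -----------------------------------------------------
        r <- pearsonMatrix(bse)
        emit(data.frame(sample_id = rownames(r), r, check.names = FALSE),
             "pearson.tsv", "pearson_r", "pearson")
        done("pearson")

        # -- ecology -----------------------------------------------------
        d <- brayCurtis(bse)
        dm <- as.matrix(d)
        emit(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
             "bray_curtis.tsv", "bray_curtis_dissimilarity", "bray_curtis")
        done("bray_curtis")

        k <- config$k %||% 2L
        ordp <- pcoa(d, k)
        ordn <- nmds(d, k = k, nRestarts = config$nRestarts %||% 20L,
                     seed = seed)
        report$seeds$nmds <- seed
        pts <- ordinationPoints(ordn)
        emit(data.frame(sample_id = rownames(pts), pts,
                        stress = ordinationStress(ordn),
                        check.names = FALSE),
             "nmds.tsv", "ordination_coordinate", "nmds")
        pp <- ordinationPoints(ordp)
        emit(data.frame(sample_id = rownames(pp), pp, check.names = FALSE),
             "pcoa.tsv", "ordination_coordinate", "pcoa")
        done("nmds"); done("pcoa")

        term <- config$permanovaTerm %||% "condition"
        labels <- sd[[term]]
        if (length(unique(labels)) >= 2L) {
            strata <- if (!is.null(config$strata)) sd[[config$strata]]
            pm <- permanova(d, labels,
                            nPermutations = config$nPermutations %||% 999L,
                            strata = strata, seed = seed, term = term)
            report$seeds$permanova <- seed
            emit(data.frame(term = pm@term, pseudo_F = pm@pseudoF,
                            R2 = pm@R2, p_value = pm@pValue,
                            n_permutations = pm@nPermutations),
                 "permanova.tsv", "statistic", "permanova")
            done("permanova")
            bd <- betaDispersion(d, labels,
                                 nPermutations = config$nPermutations %||% 999L,
                                 seed = seed)
            emit(data.frame(sample_id = names(bd@distances),
                            group = as.character(bd@groups),
                            distance_to_centroid = bd@distances),
                 "beta_dispersion.tsv", "distance", "beta_dispersion")
            done("beta_dispersion")
        } else {
            done("permanova", "skipped(<2 groups)")
            done("beta_dispersion", "skipped(<2 groups)")
        }

        # -- selection / venn / enrichment ------------------------------
        selCfg <- config$selection
        if (!is.null(selCfg)) {
            classifyOne <- function(cond) classifySelection(
                bse, cond, selCfg$tFrom, selCfg$tTo,
                lossThreshold = selCfg$lossThreshold %||% 10L,
                depletionFraction = selCfg$depletionFraction %||% 0.5,
                enrichmentFold = selCfg$enrichmentFold %||% 2.0)
            conds <- selCfg$conditions %||% selCfg$condition
            calls <- tryCatch(lapply(conds, classifyOne),
                              error = function(e) fail("selection", e))
            names(calls) <- conds
            emit(do.call(rbind, calls), "selection_calls.tsv",
                 "count_and_abundance", "selection")
            done("selection")
            if (length(conds) >= 2L) {
                venn <- compareConditions(calls)
                emit(data.frame(region = venn$region, n = venn$n),
                     "venn.tsv", "gene_count", "venn")
                done("venn")
            } else done("venn", "skipped(<2 conditions)")
            if (!is.null(config$annotation)) {
                ann <- loadAnnotation(config$annotation,
                                      background = rownames(bse))
                hits <- unique(unlist(lapply(calls, function(cl)
                    cl$gene[cl$status %in% c("lost", "depleted")])))
                if (length(hits)) {
                    enr <- hypergeometricEnrichment(hits, ann)
                    emit(enr, "enrichment.tsv", "statistic", "enrichment")
                    done("enrichment")
                } else done("enrichment", "skipped(empty gene list)")
            } else done("enrichment", "skipped(no annotation)")
        } else {
            done("selection", "skipped(no selection config)")
            done("venn", "skipped(no selection config)")
            done("enrichment", "skipped(no selection config)")
        }
    }, warning = noteWarn)

    report
}
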