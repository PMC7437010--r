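#' Construct a fitness landscape
#'
#' @param s genes-by-phases matrix of per-generation selection coefficients
#'   with gene rownames and unique phase colnames.  Lethal phenotypes must
#'   be encoded as \code{s = -1 + eps} for a small positive eps; \code{1 + s}
#'   must stay strictly positive.
#' @return a \linkS4class{FitnessLandscape}.
#' @export
FitnessLandscape <- function(s) new("FitnessLandscape", s = as.matrix(s))

#' Build a process schedule table
#'
#' A schedule row describes one cultivation phase: its id, the condition it
#' belongs to (\code{"*"} marks the shared seed-train trunk every condition
#' inherits), start and end time in hours, the number of generations the
#' population grows during the phase, and an optional bottleneck (number of
#' cells surviving the transfer dilution at the end of the phase;
#' \code{NA} = no bottleneck).  Phases must not overlap within a condition
#' and sampling happens at phase boundaries.
#'
#' @param phase,condition,start_h,end_h,generations,bottleneck_cells vectors
#'   of equal length (see above).
#' @return validated schedule data.frame.
#' @export
processSchedule <- function(phase, condition, start_h, end_h, generations,
                            bottleneck_cells = NA) {
    sch <- data.frame(phase = phase, condition = condition,
                      start_h = start_h, end_h = end_h,
                      generations = generations,
                      bottleneck_cells = bottleneck_cells)
    if (anyDuplicated(sch$phase)) stop("phase ids must be unique")
    if (any(sch$end_h <= sch$start_h)) stop("phases must have end_h > start_h")
    if (any(sch$generations <= 0)) stop("generations must be positive")
    for (cond in unique(sch$condition)) {
        p <- sch[sch$condition == cond, , drop = FALSE]
        p <- p[order(p$start_h), , drop = FALSE]
        if (nrow(p) > 1L && any(p$start_h[-1] < p$end_h[-nrow(p)]))
            stop("overlapping phases for condition ", cond)
    }
    sch
}

#' Simulate the true abundance trajectory of a pooled competition
#'
#' Standard haploid selection model: within a phase of \eqn{g} generations
#' every mutant's abundance is multiplied by \eqn{(1+s)^g} (with \eqn{s} its
#' per-generation selection coefficient for that phase) and the pool is
#' renormalized.  If a phase sets \code{bottleneck_cells}, a multinomial
#' draw of that many cells resamples the pool at the phase boundary,
#' modelling serial-transfer dilution; the recorded abundance at the
#' boundary is the pre-transfer culture.  Phases with condition \code{"*"}
#' form a shared trunk (the seed train) simulated once; each trunk phase is
#' recorded as its own pseudo-condition at the phase's end time.  Every
#' other condition continues from the trunk endpoint through its own
#' phases, recorded at time 0 (inoculation) and every phase end.
#'
#' @param landscape a \linkS4class{FitnessLandscape}; phases missing from it
#'   are treated as fully neutral.
#' @param schedule a schedule from [processSchedule()].
#' @param initialAbundance optional named abundance vector over the
#'   landscape's genes; defaults to a normalized log-normal draw
#'   (heavy-tailed, \code{sdlog = initialSigma}) mimicking the uneven
#'   starting pool of a real deletion collection.
#' @param seed integer seed (initial draw and bottlenecks).
#' @param initialSigma sdlog of the default initial log-normal draw.
#' @return a \linkS4class{SimTruth}.
#' @export
simulateTrajectory <- function(landscape, schedule, initialAbundance = NULL,
                               seed = 1L, initialSigma = 1.0) {
    stopifnot(is(landscape, "FitnessLandscape"))
    s <- selectionCoefficients(landscape)
    if (any(1 + s <= 0))
        stop("(1 + s) must be strictly positive; encode lethality as s = -1 + eps")
    genes <- rownames(s)
    set.seed(seed)
    x0 <- if (is.null(initialAbundance)) {
        draw <- stats::rlnorm(length(genes), 0, initialSigma)
        stats::setNames(draw / sum(draw), genes)
    } else {
        if (!identical(sort(names(initialAbundance)), sort(genes)))
            stop("initialAbundance must be named by the landscape's genes")
        ia <- initialAbundance[genes]
        ia / sum(ia)
    }

    phaseS <- function(phase) {
        if (phase %in% colnames(s)) s[, phase] else rep(0, length(genes))
    }
    advance <- function(x, phase, generations) {
        x <- x * (1 + phaseS(phase))^generations
        x / sum(x)
    }
    bottleneck <- function(x, cells) {
        if (is.na(cells)) return(x)
        cts <- stats::rmultinom(1L, as.integer(cells), x)[, 1]
        cts / sum(cts)
    }

    abundances <- list(); times <- list()
    trunk <- schedule[schedule$condition == "*", , drop = FALSE]
    trunk <- trunk[order(trunk$start_h), , drop = FALSE]
    x <- x0
    for (i in seq_len(nrow(trunk))) {
        x <- advance(x, trunk$phase[i], trunk$generations[i])
        abundances[[trunk$phase[i]]] <- matrix(x, nrow = 1L,
            dimnames = list(NULL, genes))
        times[[trunk$phase[i]]] <- trunk$end_h[i]
        x <- bottleneck(x, trunk$bottleneck_cells[i])
    }
    xTrunkEnd <- x

    conds <- setdiff(unique(schedule$condition), "*")
    for (cond in conds) {
        ph <- schedule[schedule$condition == cond, , drop = FALSE]
        ph <- ph[order(ph$start_h), , drop = FALSE]
        x <- xTrunkEnd
        rows <- list(x)
        tt <- ph$start_h[1]
        for (i in seq_len(nrow(ph))) {
            x <- advance(x, ph$phase[i], ph$generations[i])
            rows[[length(rows) + 1L]] <- x
            tt <- c(tt, ph$end_h[i])
            x <- bottleneck(x, ph$bottleneck_cells[i])
        }
        abundances[[cond]] <- do.call(rbind, rows)
        colnames(abundances[[cond]]) <- genes
        times[[cond]] <- tt
    }

    nz <- which(s != 0, arr.ind = TRUE)
    phase2cond <- stats::setNames(schedule$condition, schedule$phase)
    planted <- data.frame(
        gene = genes[nz[, 1]],
        phase = colnames(s)[nz[, 2]],
        condition = unname(phase2cond[colnames(s)[nz[, 2]]]),
        s = s[nz], row.names = NULL)
    new("SimTruth", abundances = abundances, times = times,
        planted = planted, landscape = landscape,
        schedule = schedule, seed = as.integer(seed))
}

#' Multinomially sample sequencing reads from the true abundances
#'
#' Sequencing a pooled sample to a given depth is modelled as a single
#' multinomial draw over the true relative abundances.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param condition,time_h which recorded sample to sequence.
#' @param depth positive total read count.
#' @param seed integer seed.
#' @param sampleId sample id (default \code{<condition>_<time>h}).
#' @return a one-sample \linkS4class{BarseqExperiment}.
#' @export
sampleReads <- function(truth, condition, time_h, depth, seed = 1L,
                        sampleId = NULL) {
    stopifnot(is(truth, "SimTruth"))
    if (depth <= 0) stop("depth must be positive")
    tt <- truth@times[[condition]]
    if (is.null(tt)) stop("unknown condition: ", condition)
    i <- match(time_h, tt)
    if (is.na(i)) stop(sprintf("no timepoint %g h for condition %s",
                               time_h, condition))
    set.seed(seed)
    x <- truth@abundances[[condition]][i, ]
    cts <- stats::rmultinom(1L, as.integer(depth), x)[, 1]
    if (is.null(sampleId)) sampleId <- sprintf("%s_%gh", condition, time_h)
    vessel <- if (grepl("^(Seed|SF)", condition)) "shake_flask" else "bioreactor"
    BarseqExperiment(
        matrix(cts, ncol = 1L, dimnames = list(names(x), sampleId)),
        data.frame(sample_id = sampleId, condition = condition,
                   vessel = vessel, time_h = time_h,
                   row.names = sampleId))
}

#' Sequence every recorded sample of a simulation
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param depth reads per sample.
#' @param seed integer seed; per-sample draws are taken sequentially so the
#'   whole table is reproducible from this one seed.
#' @param conditions subset of conditions (default all).
#' @return a multi-sample \linkS4class{BarseqExperiment}.
#' @export
simulateCounts <- function(truth, depth, seed = 1L, conditions = NULL) {
    stopifnot(is(truth, "SimTruth"))
    if (is.null(conditions)) conditions <- names(truth@abundances)
    set.seed(seed)
    samples <- list()
    for (cond in conditions) {
        tt <- truth@times[[cond]]
        ab <- truth@abundances[[cond]]
        for (i in seq_along(tt)) {
            cts <- stats::rmultinom(1L, as.integer(depth), ab[i, ])[, 1]
            id <- sprintf("%s_%gh", cond, tt[i])
            vessel <- if (grepl("^(Seed|SF)", cond)) "shake_flask"
                      else "bioreactor"
            samples[[id]] <- BarseqExperiment(
                matrix(cts, ncol = 1L, dimnames = list(colnames(ab), id)),
                data.frame(sample_id = id, condition = cond,
                           vessel = vessel, time_h = tt[i], row.names = id))
        }
    }
    combineSamples(samples)
}

#' Generate a random barcode catalog for a gene set
#'
#' Draws distinct random barcodes of one length, one per gene — handy as
#' ground truth for read-level round trips.
#'
#' @param genes gene identifiers.
#' @param barcodeLength barcode length (default 20).
#' @param seed integer seed.
#' @return a \linkS4class{BarcodeCatalog}.
#' @export
randomCatalog <- function(genes, barcodeLength = 20L, seed = 1L) {
    set.seed(seed)
    repeat {
        bc <- vapply(seq_along(genes), function(i)
            paste(sample(c("A", "C", "G", "T"), barcodeLength,
                         replace = TRUE), collapse = ""), "")
        if (!anyDuplicated(bc)) break
    }
    entries <- data.frame(barcode = bc, gene = genes)
    entries <- entries[order(entries$barcode), , drop = FALSE]
    rownames(entries) <- NULL
    new("BarcodeCatalog", entries = entries, discarded = character(),
        barcodeLength = as.integer(barcodeLength))
}

#' Emit synthetic FASTQ reads for a counted sample
#'
#' Writes one read per count with layout random-prefix + flank + barcode +
#' random-suffix padded to \code{readLength}, constant quality, and
#' independent per-base substitution errors on the barcode
#' (\code{errorRate}) and, separately, on the flank (\code{flankErrorRate};
#' a corrupted flank makes the read drop out at extraction).  With
#' \code{errorRate = 0} a [countReads()] round trip reproduces the counts
#' exactly; with error rate \eqn{e} the expected recovered fraction is
#' \eqn{(1-e)^L}.
#'
#' @param counts named count vector (gene -> count) or a one-sample
#'   \linkS4class{BarseqExperiment}.
#' @param catalog a \linkS4class{BarcodeCatalog} covering every counted
#'   gene.
#' @param flank upstream flanking sequence.
#' @param path output FASTQ path (gzipped if it ends in \code{.gz}).
#' @param errorRate per-base substitution probability on the barcode.
#' @param flankErrorRate per-base substitution probability on the flank.
#' @param readLength total read length.
#' @param seed integer seed.
#' @return invisibly, \code{path}.
#' @export
emitFastq <- function(counts, catalog, flank, path, errorRate = 0,
                      flankErrorRate = 0, readLength = 80L, seed = 1L) {
    stopifnot(is(catalog, "BarcodeCatalog"))
    if (is(counts, "BarseqExperiment")) {
        stopifnot(ncol(counts) == 1L)
        counts <- counts(counts)[, 1]
    }
    counts <- counts[counts > 0]
    entries <- catalogEntries(catalog)
    bcOf <- stats::setNames(entries$barcode, entries$gene)
    missing <- setdiff(names(counts), names(bcOf))
    if (length(missing))
        stop("counted gene(s) without a catalog barcode: ",
             paste(utils::head(missing, 5), collapse = ", "))
    L <- barcodeLength(catalog)
    fl <- nchar(flank)
    if (fl + L > readLength)
        stop("flank plus barcode exceed readLength")
    set.seed(seed)
    bc <- rep(unname(bcOf[names(counts)]), counts)
    n <- length(bc)
    bases <- c("A", "C", "G", "T")

    mutate <- function(seqs, rate, len) {
        if (rate <= 0) return(seqs)
        for (pos in seq_len(len)) {
            hit <- stats::runif(n) < rate
            if (!any(hit)) next
            cur <- substr(seqs[hit], pos, pos)
            ci <- match(cur, bases)
            newi <- ((ci - 1L + sample.int(3L, sum(hit), replace = TRUE)) %% 4L) + 1L
            substr(seqs[hit], pos, pos) <- bases[newi]
        }
        seqs
    }
    bc <- mutate(bc, errorRate, L)
    flanks <- mutate(rep(flank, n), flankErrorRate, fl)

    room <- readLength - fl - L
    preLen <- if (room > 0) sample.int(room + 1L, n, replace = TRUE) - 1L
              else integer(n)
    sufLen <- room - preLen
    randSeq <- function(lens) {
        maxLen <- max(lens, 0L)
        if (maxLen == 0L) return(rep("", length(lens)))
        m <- matrix(sample(bases, length(lens) * maxLen, replace = TRUE),
                    nrow = length(lens))
        full <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
        substr(full, 1L, lens)
    }
    reads <- paste0(randSeq(preLen), flanks, bc, randSeq(sufLen))
    qual <- strrep("I", readLength)
    out <- character(4L * n)
    out[seq(1L, length(out), 4L)] <- paste0("@read", seq_len(n))
    out[seq(2L, length(out), 4L)] <- reads
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- qual
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(out, con)
    invisible(path)
}
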