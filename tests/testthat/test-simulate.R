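twoPhaseSchedule <- function(bottleneck = NA) {
    processSchedule(phase = c("p1", "p2"), condition = c("A", "A"),
                    start_h = c(0, 24), end_h = c(24, 48),
                    generations = c(1, 1), bottleneck_cells = bottleneck)
}

test_that("neutral trajectories without bottleneck are exactly time-invariant", {
    s <- matrix(0, 20, 2, dimnames = list(sprintf("g%d", 1:20), c("p1", "p2")))
    tr <- simulateTrajectory(FitnessLandscape(s), twoPhaseSchedule(), seed = 3)
    ab <- trueAbundances(tr, "A")
    expect_equal(ab[1, ], ab[2, ])
    expect_equal(ab[1, ], ab[3, ])
    expect_true(all(abs(rowSums(ab) - 1) < 1e-12))
})

test_that("one selective generation follows the multiplicative update", {
    s <- matrix(c(0, -0.5, 0, 0), 2, 2,
                dimnames = list(c("g1", "g2"), c("p1", "p2")))
    tr <- simulateTrajectory(FitnessLandscape(s), twoPhaseSchedule(),
                             initialAbundance = c(g1 = 0.5, g2 = 0.5),
                             seed = 1)
    ab <- trueAbundances(tr, "A")
    expect_equal(unname(ab[2, ]), c(2 / 3, 1 / 3))   # (0.5, 0.25)/0.75
})

test_that("s = -0.3 over 10 generations shrinks the odds by 0.7^10", {
    s <- matrix(c(-0.3, 0), 2, 1, dimnames = list(c("g1", "g2"), "p1"))
    sch <- processSchedule("p1", "A", 0, 24, generations = 10)
    tr <- simulateTrajectory(FitnessLandscape(s), sch,
                             initialAbundance = c(g1 = 0.5, g2 = 0.5),
                             seed = 1)
    ab <- trueAbundances(tr, "A")
    odds0 <- ab[1, "g1"] / ab[1, "g2"]
    odds1 <- ab[2, "g1"] / ab[2, "g2"]
    expect_equal(unname(odds1 / odds0), 0.7^10, tolerance = 1e-12)
})

test_that("lethal coefficients are rejected", {
    s <- matrix(c(-1, 0), 2, 1, dimnames = list(c("g1", "g2"), "p1"))
    expect_error(simulateTrajectory(FitnessLandscape(s),
                                    processSchedule("p1", "A", 0, 24, 5)),
                 "strictly positive")
})

test_that("bottlenecks resample the pool and the recorded sample is pre-transfer", {
    s <- matrix(0, 50, 2, dimnames = list(sprintf("g%d", 1:50), c("p1", "p2")))
    tr <- simulateTrajectory(FitnessLandscape(s), twoPhaseSchedule(200),
                             seed = 5)
    ab <- trueAbundances(tr, "A")
    expect_equal(ab[1, ], ab[2, ])            # phase-1 sample taken before transfer
    expect_false(isTRUE(all.equal(ab[2, ], ab[3, ])))  # drift after bottleneck
    expect_true(all(abs(rowSums(ab) - 1) < 1e-12))
})

test_that("sampleReads draws a reproducible multinomial of the right depth", {
    s <- matrix(0, 1, 1, dimnames = list("only", "p1"))
    sch <- processSchedule("p1", "A", 0, 24, 5)
    tr <- simulateTrajectory(FitnessLandscape(s), sch, seed = 1)
    one <- sampleReads(tr, "A", 24, depth = 1000, seed = 2)
    expect_equal(unname(counts(one)[1, 1]), 1000)
    expect_error(sampleReads(tr, "A", 24, depth = 0), "positive")
    expect_error(sampleReads(tr, "A", 99, depth = 10), "timepoint")

    again <- sampleReads(tr, "A", 24, depth = 1000, seed = 2)
    expect_identical(counts(one), counts(again))
})

test_that("multinomial sampling is unbiased within binomial-moment bounds", {
    set.seed(30)
    x <- c(g1 = 0.6, g2 = 0.3, g3 = 0.1)
    s <- matrix(0, 3, 1, dimnames = list(names(x), "p1"))
    tr <- simulateTrajectory(FitnessLandscape(s),
                             processSchedule("p1", "A", 0, 24, 1),
                             initialAbundance = x, seed = 1)
    depth <- 2000
    draws <- vapply(1:200, function(i)
        counts(sampleReads(tr, "A", 24, depth, seed = i))[, 1],
        numeric(3))
    for (g in names(x)) {
        expE <- depth * x[g]
        se <- sqrt(depth * x[g] * (1 - x[g]) / 200)
        expect_lt(abs(mean(draws[g, ]) - expE), 3 * se)
    }
})

test_that("emitFastq validates layout and loses everything at error rate 1", {
    genes <- sprintf("g%d", 1:10)
    cat <- randomCatalog(genes, seed = 6)
    expect_error(emitFastq(setNames(rep(5, 10), genes), cat,
                           flank = strrep("A", 70), path = tempfile(),
                           readLength = 80),
                 "exceed readLength")
    fq <- tempfile(fileext = ".fastq")
    emitFastq(setNames(rep(50, 10), genes), cat, "GATGTCCACG", fq,
              errorRate = 1, seed = 7)
    bse <- countReads(fq, cat, "s", flank = "GATGTCCACG")
    expect_lt(sum(counts(bse)), 5)   # corrupted barcodes; collisions ~ none
})

test_that("the preset study design is deterministic and shaped as documented", {
    p1 <- presetStudyDesign(seed = 21, nGenes = 200, nStress = 10)
    p2 <- presetStudyDesign(seed = 21, nGenes = 200, nStress = 10)
    expect_identical(selectionCoefficients(p1$landscape),
                     selectionCoefficients(p2$landscape))
    expect_identical(p1$plantedSets, p2$plantedSets)

    s <- selectionCoefficients(p1$landscape)
    expect_setequal(names(p1$plantedSets), c("CF4", "CF6", "DF4"))
    expect_true(all(s[p1$plantedSets$CF6, "CF6_48_72"] == -0.75))
    expect_true(all(s[p1$plantedSets$CF6, "CF6_33_48"] == -0.35))
    expect_true(all(s[, "Seed1"] == 0))
    # CF6 carries the strongest late stress
    expect_lt(min(s[, "CF6_48_72"]), min(s[, "CF4_48_72"]))
})

test_that("a neutral preset keeps final richness statistically level across conditions", {
    pre <- presetStudyDesign(seed = 22, nGenes = 400,
                             stressS = c(CF4 = 0, CF6 = 0, DF4 = 0))
    expect_length(pre$plantedSets, 0L)
    tr <- simulateTrajectory(pre$landscape, pre$schedule, seed = 22)
    bse <- simulateCounts(tr, depth = 4e5, seed = 23,
                          conditions = c("CF4", "CF6", "DF4", "DF6"))
    rich <- vapply(c("CF4", "CF6", "DF4", "DF6"), function(cc)
        detectionProfile(bse, sprintf("%s_119h", cc), 10)$n_detected, 0L)
    expect_gt(chisq.test(rich)$p.value, 0.01)
})
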