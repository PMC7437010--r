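test_that("perfect two-group separation attains the minimal enumerated p", {
    D <- matrix(1, 6, 6)
    D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0; diag(D) <- 0
    g <- rep(c("A", "B"), each = 3)
    res <- permanova(as.dist(D), g, nPermutations = 999, seed = 1)
    expect_true(res@details$exhaustive)
    # only the observed split and its label swap reach F = Inf
    expect_equal(res@pValue, 2 / 20)
    expect_equal(res@R2, 1)
})

test_that("exhaustive permutation p equals the brute-force enumeration", {
    set.seed(19)
    m <- matrix(rexp(6 * 15), 6)
    D <- as.matrix(brayCurtis(m / rowSums(m)))
    g <- rep(c("A", "B"), each = 3)
    res <- permanova(as.dist(D), g, nPermutations = 999, seed = 3)
    expect_true(res@details$exhaustive)

    combos <- combn(6, 3)
    Fall <- apply(combos, 2, function(idx) {
        lab <- rep("B", 6); lab[idx] <- "A"
        bruteFstat(D, lab)
    })
    Fobs <- bruteFstat(D, g)
    expect_equal(res@pseudoF, Fobs, tolerance = 1e-12)
    expect_equal(res@pValue, mean(Fall >= Fobs - 1e-12))
})

test_that("pseudo-F and R2 agree with vegan::adonis2", {
    skip_if_not_installed("vegan")
    set.seed(4)
    m <- matrix(rexp(12 * 30), 12)
    d <- brayCurtis(m / rowSums(m))
    g <- rep(c("A", "B", "C"), each = 4)
    res <- permanova(d, g, nPermutations = 99, seed = 5)
    adf <- data.frame(g = g)
    va <- vegan::adonis2(d ~ g, data = adf, permutations = 99)
    expect_equal(res@pseudoF, va$F[1], tolerance = 1e-10)
    expect_equal(res@R2, va$R2[1], tolerance = 1e-10)
})

test_that("sampled p follows the permutation-count formula", {
    set.seed(6)
    m <- matrix(rexp(12 * 20), 12)
    d <- brayCurtis(m / rowSums(m))
    g <- sample(rep(c("A", "B"), each = 6))
    res <- permanova(d, g, nPermutations = 199, seed = 8)
    expect_false(res@details$exhaustive)
    expect_equal(res@pValue,
                 (1 + sum(res@details$permF >= res@pseudoF - 1e-12)) / 200)
})

test_that("whole-stratum exchange never splits a reactor's samples", {
    # 4 reactors x 3 timepoints; feeding regime constant within each reactor
    reactor <- rep(c("r1", "r2", "r3", "r4"), each = 3)
    regime <- rep(c("CF", "CF", "DF", "DF"), each = 3)
    set.seed(2)
    m <- matrix(rexp(12 * 25), 12)
    d <- brayCurtis(m / rowSums(m))
    res <- permanova(d, regime, nPermutations = 500, strata = reactor,
                     seed = 9, returnPermutations = TRUE)
    perms <- res@details$permutations
    expect_false(is.null(perms))
    for (i in seq_len(nrow(perms)))
        expect_true(all(tapply(perms[i, ], reactor,
                               function(x) length(unique(x))) == 1))
})

test_that("within-stratum shuffles preserve each stratum's label multiset", {
    reactor <- rep(c("r1", "r2", "r3"), each = 4)
    phase <- rep(c("early", "early", "late", "late"), 3)
    set.seed(10)
    m <- matrix(rexp(12 * 25), 12)
    d <- brayCurtis(m / rowSums(m))
    res <- permanova(d, phase, nPermutations = 300, strata = reactor,
                     seed = 11, returnPermutations = TRUE)
    perms <- res@details$permutations
    for (i in seq_len(nrow(perms)))
        for (r in unique(reactor)) {
            idx <- reactor == r
            expect_equal(sort(perms[i, idx]), sort(phase[idx]))
        }
})

test_that("degenerate designs are rejected", {
    d <- dist(matrix(rnorm(12), 6))
    expect_error(permanova(d, rep("A", 6)), "at least 2 groups")
    expect_error(permanova(d, rep(c("A", "B"), each = 3),
                           strata = rep("r1", 3)),
                 "one stratum per sample")
})
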