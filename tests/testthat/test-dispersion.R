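test_that("a group of identical samples has zero dispersion", {
    m <- rbind(a = c(5, 5, 0), b = c(5, 5, 0), c = c(5, 5, 0),
               d = c(9, 1, 3), e = c(1, 9, 4), f = c(2, 2, 9))
    d <- brayCurtis(m / rowSums(m))
    res <- betaDispersion(d, rep(c("same", "diff"), each = 3),
                          nPermutations = 99, seed = 1)
    expect_true(all(res@distances[1:3] < 1e-10))
    expect_gt(res@groupMeans["diff"], 0)
})

test_that("two congruent groups have F near zero and p near one", {
    pts <- matrix(c(0, 0, 1, 0, 0, 1, 10, 10, 11, 10, 10, 11),
                  ncol = 2, byrow = TRUE)
    d <- dist(pts)
    res <- betaDispersion(d, rep(c("A", "B"), each = 3),
                          nPermutations = 199, seed = 2)
    expect_lt(res@anovaF, 1e-10)
    expect_gt(res@permP, 0.9)
})

test_that("distances to centroid match vegan::betadisper on Bray-Curtis", {
    skip_if_not_installed("vegan")
    set.seed(13)
    m <- matrix(rexp(10 * 30), 10)
    m <- m / rowSums(m)
    d <- brayCurtis(m)
    g <- rep(c("A", "B"), each = 5)
    res <- betaDispersion(d, g, nPermutations = 49, seed = 3)
    vb <- vegan::betadisper(d, g, type = "centroid")
    expect_equal(unname(res@distances), unname(vb$distances),
                 tolerance = 1e-8)
    av <- anova(vb)
    expect_equal(res@anovaF, av$`F value`[1], tolerance = 1e-8)
    expect_equal(res@anovaP, av$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("singleton groups keep their distance but are excluded from tests", {
    set.seed(4)
    m <- matrix(rexp(7 * 20), 7)
    d <- brayCurtis(m / rowSums(m))
    g <- c("A", "A", "A", "B", "B", "B", "solo")
    res <- betaDispersion(d, g, nPermutations = 99, seed = 5)
    expect_equal(res@details$excludedGroups, "solo")
    expect_equal(unname(res@distances[7]), 0)   # its own centroid
    expect_false(any(res@pairwise$groupA == "solo" |
                     res@pairwise$groupB == "solo"))
    expect_false(is.na(res@anovaF))
})

test_that("pairwise permutation comparisons carry BH-adjusted q-values", {
    set.seed(6)
    base <- matrix(rexp(12 * 25), 12)
    base <- base / rowSums(base)
    base[9:12, ] <- base[9:12, ] * matrix(rexp(4 * 25, 2), 4)  # extra spread
    d <- brayCurtis(base / rowSums(base))
    g <- rep(c("A", "B", "C"), each = 4)
    res <- betaDispersion(d, g, nPermutations = 199, seed = 7)
    expect_equal(nrow(res@pairwise), 3L)
    expect_equal(res@pairwise$q_BH, bruteBH(res@pairwise$p_perm))
})
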