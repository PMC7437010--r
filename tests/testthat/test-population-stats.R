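test_that("detectionProfile applies an inclusive threshold", {
    bse <- makeBse(cbind(s1 = c(g1 = 10, g2 = 9, g3 = 0)))
    pr <- detectionProfile(bse, "s1", 10)
    expect_equal(pr$n_detected, 1L)
    expect_equal(pr$detected_genes, "g1")
    expect_equal(pr$n_detected + pr$n_not_detected, 3L)

    expect_equal(detectionProfile(bse, "s1", 0)$n_detected, 3L)
    all10 <- makeBse(cbind(s1 = c(g1 = 10, g2 = 10)))
    expect_equal(detectionProfile(all10, "s1", 10)$n_detected, 2L)
    expect_error(detectionProfile(bse, "nope"), "unknown sample")
})

test_that("detection sets are nested across increasing thresholds", {
    set.seed(11)
    m <- matrix(rnbinom(200, mu = 15, size = 0.7), 40,
                dimnames = list(sprintf("g%d", 1:40), NULL))
    bse <- makeBse(m, condition = rep("A", 5), time_h = 1:5)
    for (s in colnames(bse)) {
        prev <- NULL
        for (th in c(1, 5, 10, 20)) {
            det <- detectionProfile(bse, s, th)$detected_genes
            if (!is.null(prev)) expect_true(all(det %in% prev))
            prev <- det
        }
    }
})

test_that("lossWindows does set arithmetic on consecutive detection sets", {
    # detection sets {g1,g2,g3} -> {g1,g2} -> {g1} at threshold 10
    m <- cbind(t0 = c(g1 = 50, g2 = 50, g3 = 50),
               t1 = c(50, 50, 0), t2 = c(50, 0, 0))
    bse <- makeBse(m, condition = rep("A", 3), time_h = c(0, 24, 48))
    lw <- lossWindows(bse, "A", thresholds = 10)
    expect_equal(lw$windows$n_lost, c(1, 1))
    # tie on n_lost broken by the earliest window
    expect_equal(lw$maxLoss$t_start_h, 0)

    flat <- makeBse(cbind(t0 = m[, 1], t1 = m[, 1], t2 = m[, 1]),
                    condition = rep("A", 3), time_h = c(0, 24, 48))
    expect_true(all(lossWindows(flat, "A")$windows$n_lost == 0))
    expect_error(lossWindows(makeBse(m[, 1, drop = FALSE]), "A"),
                 "fewer than 2 timepoints")
})

test_that("lost minus gained over all windows telescopes to first minus last richness", {
    set.seed(3)
    m <- matrix(rnbinom(300, mu = 12, size = 0.5), 50,
                dimnames = list(sprintf("g%d", 1:50), NULL))
    bse <- makeBse(m, condition = rep("A", 6), time_h = seq(0, 100, 20))
    for (th in c(1, 5, 10, 20)) {
        w <- lossWindows(bse, "A", thresholds = th)$windows
        first <- detectionProfile(bse, colnames(bse)[1], th)$n_detected
        last <- detectionProfile(bse, colnames(bse)[6], th)$n_detected
        expect_equal(sum(w$n_lost) - sum(w$n_gained), first - last)
    }
})

test_that("pearsonMatrix correlates raw counts with textbook results", {
    x <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
    bse <- makeBse(cbind(a = x, b = 2 * x, c = rev(x)),
                   condition = rep("A", 3), time_h = 1:3)
    r <- pearsonMatrix(bse)
    expect_equal(unname(r["a", "b"]), 1)
    expect_equal(unname(r["a", "c"]), -1)
    expect_equal(unname(diag(r)), rep(1, 3))
    expect_true(max(abs(r - t(r))) < 1e-12)

    z <- makeBse(cbind(a = x, z = rep(5, 4)), condition = c("A", "A"),
                 time_h = 1:2)
    expect_warning(rz <- pearsonMatrix(z), "zero-variance")
    expect_true(all(is.na(rz["z", ])))
    expect_equal(unname(rz["a", "a"]), 1)
})
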