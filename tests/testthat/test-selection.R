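selBse <- function(c48, c72) {
    m <- cbind(t48 = c48, t72 = c72)
    normalizeAbundance(makeBse(m, condition = c("CF4", "CF4"),
                               time_h = c(48, 72)))
}

test_that("classifySelection applies the lost/depleted/enriched rules in order", {
    # gene below the count threshold is lost regardless of abundance trend
    bse <- selBse(c(gA = 5, gB = 1000, gC = 1000),
                  c(gA = 9, gB = 2000, gC = 100))
    cl <- classifySelection(bse, "CF4", 48, 72)
    expect_equal(as.character(cl$status[cl$gene == "gA"]), "lost")

    # 60% relative-abundance drop with a healthy count: depleted
    bse2 <- selBse(c(gA = 100, gB = 9890), c(gA = 500, gB = 123456))
    ab <- abundances(bse2)
    expect_lt(ab["gA", 2] / ab["gA", 1], 0.5)
    cl2 <- classifySelection(bse2, "CF4", 48, 72)
    expect_equal(as.character(cl2$status[cl2$gene == "gA"]), "depleted")

    # flat abundance, adequate count: retained
    bse3 <- selBse(c(gA = 100, gB = 100), c(gA = 100, gB = 100))
    expect_true(all(classifySelection(bse3, "CF4", 48, 72)$status ==
                    "retained"))

    expect_error(classifySelection(bse, "CF4", 48, 96), "96")
    expect_error(classifySelection(bse, "BR", 48, 72), "BR")
})

test_that("statuses are mutually exclusive and exhaustive", {
    set.seed(15)
    m <- matrix(rnbinom(400, mu = 60, size = 0.6), 200,
                dimnames = list(sprintf("g%d", 1:200), c("a", "b")))
    bse <- normalizeAbundance(makeBse(m, condition = c("X", "X"),
                                      time_h = c(48, 72)))
    cl <- classifySelection(bse, "X", 48, 72)
    expect_equal(nrow(cl), 200L)
    expect_false(any(is.na(cl$status)))
    expect_setequal(cl$gene, rownames(bse))
})

test_that("compareConditions produces the full inclusion-exclusion partition", {
    cc <- compareConditions(list(A = c("g1", "g2"), B = c("g2", "g3")))
    get <- function(region) cc$n[cc$region == region]
    expect_equal(get("A"), 1L)
    expect_equal(get("B"), 1L)
    expect_equal(get("A&B"), 1L)
    expect_equal(cc$genes[[which(cc$region == "A&B")]], "g2")

    tripl <- compareConditions(list(A = "g1", B = "g1", C = "g1"))
    expect_equal(tripl$n[tripl$region == "A&B&C"], 1L)
    expect_equal(sum(tripl$n), 1L)
})

test_that("region counts equal brute-force enumeration on random sets", {
    set.seed(16)
    pool <- sprintf("g%04d", 1:600)
    for (i in 1:50) {
        sets <- list(A = sample(pool, 174), B = sample(pool, 253),
                     C = sample(pool, 39))
        cc <- compareConditions(sets)
        oracle <- bruteVenn(sets)
        expect_equal(sum(cc$n), length(unique(unlist(sets))))
        for (region in cc$region) {
            want <- oracle[[region]]
            expect_setequal(cc$genes[[which(cc$region == region)]],
                            if (is.null(want)) character() else want)
        }
    }
})

test_that("hypergeometric p matches the enumeration oracle", {
    # N=20, K=5, n=4, k=3 -> 155/4845
    expect_equal(bruteHyper(3, 5, 4, 20), 155 / 4845)
    bg <- sprintf("g%02d", 1:20)
    ann <- list(gene2terms = setNames(lapply(bg[1:5], function(g) "T1"),
                                      bg[1:5]),
                termDesc = c(T1 = "term one"), background = bg)
    res <- hypergeometricEnrichment(c(bg[1:3], bg[20]), ann)
    expect_equal(res$p, 155 / 4845)
    expect_equal(res$fold_enrichment, 3)

    # k = n = K = N: p = 1, fold = 1
    ann2 <- list(gene2terms = setNames(lapply(bg, function(g) "T1"), bg),
                 termDesc = c(T1 = "t"), background = bg)
    resAll <- hypergeometricEnrichment(bg, ann2)
    expect_equal(resAll$p, 1)
    expect_equal(resAll$fold_enrichment, 1)

    # a term with no hit in the list is not reported
    ann3 <- list(gene2terms = list(g01 = "T1", g02 = "T2"),
                 termDesc = c(T1 = "a", T2 = "b"), background = bg)
    res3 <- hypergeometricEnrichment("g01", ann3)
    expect_equal(res3$term, "T1")

    expect_error(hypergeometricEnrichment("nope", ann), "absent")
    expect_error(hypergeometricEnrichment(character(), ann), "empty")
})

test_that("hypergeometric p equals the oracle across random small designs", {
    set.seed(17)
    for (i in 1:50) {
        N <- sample(10:30, 1)
        K <- sample(1:(N - 1), 1)
        n <- sample(1:(N - 1), 1)
        bg <- sprintf("x%02d", 1:N)
        termGenes <- sample(bg, K)
        lst <- sample(bg, n)
        k <- length(intersect(lst, termGenes))
        if (k == 0) next
        ann <- list(gene2terms = setNames(lapply(termGenes, function(g) "T"),
                                          termGenes),
                    termDesc = c(T = "t"), background = bg)
        res <- hypergeometricEnrichment(lst, ann)
        expect_equal(res$p, bruteHyper(k, K, n, N), tolerance = 1e-12)
    }
})

test_that("bhAdjust implements the step-up rule", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(0.05, 6)), rep(0.05, 6))
    expect_error(bhAdjust(c(0.1, 0)), "\\(0, 1\\]")
    expect_error(bhAdjust(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("bhAdjust matches brute force and stats::p.adjust on random vectors", {
    set.seed(18)
    for (i in 1:100) {
        p <- runif(sample(1:40, 1))
        q <- bhAdjust(p)
        expect_equal(q, bruteBH(p), tolerance = 1e-12)
        expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    }
})
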