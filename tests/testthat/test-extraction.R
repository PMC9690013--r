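test_that("binarization is a strict threshold", {
    g <- named(matrix(c(1, 1, 1, 1), 2, 2))
    expect_true(all(binarizeGamma(g, 0.99)@u == 1L))
    gEq <- named(matrix(0.8, 2, 2))
    expect_true(all(binarizeGamma(gEq, 0.8)@u == 0L))  # ties map to 0
    g3 <- named(matrix(0.1, 3, 3))
    g3[1:2, 1:2] <- 0.9
    u <- binarizeGamma(g3, 0.8)@u
    expect_identical(unname(u), rbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(0L, 0L, 0L)))
    expect_error(binarizeGamma(named(matrix(2, 2, 2)), 0.5), "\\[0,1\\]")
})

test_that("sorting moves dense lines to the corner, stably and per group", {
    ## already sorted: identity permutations
    u0 <- named(rbind(c(0L, 0L), c(0L, 1L)))
    s0 <- sortMembership(binarizeGamma(u0 * 0.9 + 0.05, 0.5))
    expect_identical(s0@rowOrder, 1:2)
    expect_identical(s0@colOrder, 1:2)

    ## all-equal row sums: original order preserved
    uEq <- named(matrix(1L, 3, 2))
    sEq <- sortMembership(binarizeGamma(uEq * 0.9, 0.5))
    expect_identical(sEq@rowOrder, 1:3)

    ## two groups, one dense column each: dense column last within its block
    u <- matrix(0L, 4, 6)
    u[, 2] <- 1L  # dense column in group A (cols 1:3)
    u[, 5] <- 1L  # dense column in group B (cols 4:6)
    u <- named(u)
    grp <- setNames(rep(c("A", "B"), each = 3), colnames(u))
    s <- sortMembership(binarizeGamma(u * 0.9 + 0.05, 0.5), colGroups = grp)
    expect_identical(s@colGroups, rep(c("A", "B"), each = 3))
    expect_identical(s@colOrder[3], 2L)   # densest of group A at its end
    expect_identical(s@colOrder[6], 5L)   # densest of group B at its end
    expect_error(
        sortMembership(binarizeGamma(u * 0.9 + 0.05, 0.5),
                       colGroups = c(s1 = "A")),
        "no group label")
})

test_that("growth from a seed recovers clean and one-hole blocks", {
    ## exact 2x2 block of 1s, zeros elsewhere
    u <- matrix(0L, 4, 5); u[3:4, 4:5] <- 1L
    bm <- sortedMembership(u)
    b <- growFromSeed(bm, NULL, pAve = 0.95)
    expect_setequal(biclusterRows(b), c("g3", "g4"))
    expect_setequal(biclusterCols(b), c("s4", "s5"))
    expect_equal(onesFraction(b), 1)

    ## 3x3 block with one hole inside a 5x5 matrix
    u2 <- matrix(0L, 5, 5); u2[1:3, 1:3] <- 1L; u2[2, 2] <- 0L
    bm2 <- sortedMembership(u2)
    loose <- growFromSeed(bm2, NULL, pAve = 0.85)
    expect_equal(length(biclusterRows(loose)) * length(biclusterCols(loose)), 9L)
    expect_equal(onesFraction(loose), 8 / 9)
    strict <- growFromSeed(bm2, NULL, pAve = 0.95)
    expect_equal(length(biclusterRows(strict)) * length(biclusterCols(strict)), 6L)
    expect_equal(onesFraction(strict), 1)

    ## all-zero matrix: empty-result signal
    expect_null(growFromSeed(sortedMembership(matrix(0L, 4, 4)), NULL, 0.9))
    ## explicit seed on a 0 cell: empty-result signal
    expect_null(growFromSeed(bm, seed = c(1L, 1L), pAve = 0.9))
})

test_that("greedy growth matches the exhaustive search on block-structured matrices", {
    runCases <- function(seed, flips) {
        set.seed(seed)
        ratios <- numeric(0)
        for (trial in 1:40) {
            I <- sample(6:8, 1); J <- sample(6:8, 1)
            u <- matrix(0L, I, J)
            u[sample(I, sample(3:(I - 1), 1)),
              sample(J, sample(3:(J - 1), 1))] <- 1L
            nf <- if (flips > 0) sample(0:flips, 1) else 0L
            if (nf > 0) {
                ix <- sample(I * J, nf)
                u[ix] <- 1L - u[ix]
            }
            bm <- sortedMembership(u)
            for (pAve in c(0.7, 0.85, 0.95)) {
                sc <- ebbiclust:::.resolveSeed(bm, NULL)
                if (is.null(sc)) next
                oracle <- growOracleArea(bm@u, sc, pAve)
                b <- growFromSeed(bm, NULL, pAve)
                got <- if (is.null(b))
                    0L else length(biclusterRows(b)) * length(biclusterCols(b))
                if (oracle > 0) ratios <- c(ratios, got / oracle)
            }
        }
        ratios
    }
    clean <- runCases(42, 0)
    expect_true(all(clean == 1))           # unambiguous path: exact match
    noisy <- runCases(42, 2)
    expect_true(all(noisy >= 0.9))         # bounded area deficit
})

test_that("extraction pipeline handles empty, multiple and grouped cases", {
    ## gamma identically zero-ish: empty set
    g0 <- named(matrix(0, 6, 6))
    expect_identical(length(extractBiclusters(g0, ac = 0.5)), 0L)

    ## two disjoint planted blocks, sequential extraction with refitting
    Y <- withr::with_seed(11, {
        Y <- matrix(rnorm(80 * 100), 80, 100)
        Y[1:12, 1:12] <- rnorm(144, 5, 1)
        Y[40:51, 60:71] <- rnorm(144, 5, 1)
        named(Y)
    })
    fit <- suppressMessages(fitBicMixture(Y))
    bs <- suppressMessages(
        extractBiclusters(fit, Y = Y, ac = 0.8, pAve = 0.9, maxBiclusters = 3))
    expect_identical(length(bs), 2L)
    t1 <- Bicluster(paste0("g", 1:12), paste0("s", 1:12))
    t2 <- Bicluster(paste0("g", 40:51), paste0("s", 60:71))
    truth <- BiclusterSet(list(t1, t2))
    expect_gte(recoveryScore(truth, bs), 0.9)
    ## cell-disjoint
    cellsOf <- function(b) outer(biclusterRows(b), biclusterCols(b), paste)
    expect_length(intersect(cellsOf(bs[[1]]), cellsOf(bs[[2]])), 0L)

    ## single-group bicluster warning under column groups
    gg <- named(matrix(0.05, 6, 6)); gg[1:3, 1:3] <- 0.95
    grp <- setNames(rep(c("A", "B"), each = 3), colnames(gg))
    expect_warning(extractBiclusters(gg, ac = 0.8, pAve = 0.9, colGroups = grp),
                   "single group")
})

test_that("extraction is deterministic and monotone in its thresholds", {
    sim <- simConstantBicluster(6, nRow = 50, nCol = 60,
                                blockRows = 10, blockCols = 12)
    fit <- fitBicMixture(simValues(sim))
    g <- posteriorGamma(fit)

    b1 <- extractBiclusters(fit, ac = 0.8, pAve = 0.95)
    b2 <- extractBiclusters(fit, ac = 0.8, pAve = 0.95)
    expect_identical(b1@biclusters, b2@biclusters)

    ## raising ac never increases the number of 1s
    nOnes <- vapply(c(0.2, 0.5, 0.8, 0.95),
                    function(a) sum(binarizeGamma(g, a)@u), numeric(1))
    expect_true(all(diff(nOnes) <= 0))

    ## raising pAve never enlarges the extracted area (same u, same seed)
    areas <- vapply(c(0.5, 0.7, 0.9, 0.99), function(pv) {
        bs <- extractBiclusters(fit, ac = 0.8, pAve = pv)
        if (length(bs) == 0L) return(0)
        length(biclusterRows(bs[[1]])) * length(biclusterCols(bs[[1]]))
    }, numeric(1))
    expect_true(all(diff(areas) <= 0))

    ## every reported bicluster satisfies its purity constraint
    for (pv in c(0.6, 0.8, 0.95)) {
        bs <- extractBiclusters(fit, ac = 0.8, pAve = pv)
        for (k in seq_len(length(bs))) expect_gte(onesFraction(bs[[k]]), pv)
    }
})

test_that("gene-anchored seeds resolve to that gene's best cell", {
    g <- named(matrix(0.05, 8, 8))
    g[2:4, 3:5] <- 0.95
    bs <- extractBiclusters(g, ac = 0.8, pAve = 0.9, seed = "g3")
    expect_true("g3" %in% biclusterRows(bs[[1]]))
    expect_setequal(biclusterRows(bs[[1]]), paste0("g", 2:4))
    bs2 <- extractBiclusters(g, ac = 0.8, pAve = 0.9, seed = c("g2", "s3"))
    expect_setequal(biclusterCols(bs2[[1]]), paste0("s", 3:5))
    expect_error(extractBiclusters(g, seed = "nope"), "not found")
})
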