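test_that("initialization finds the two components and honours overrides", {
    sim <- simConstantBicluster(1)
    model <- initializeModel(simValues(sim))
    expect_gt(model@theta1@mu, 8);  expect_lt(model@theta1@mu, 11)
    expect_gt(model@theta2@mu, 3.5); expect_lt(model@theta2@mu, 4.8)
    expect_identical(c(model@p1, model@p2), c(0.5, 0.5))

    expect_error(initializeModel(matrix(5, 4, 4)), "degenerate")

    th <- list(makeParams(7, 2, 1, 1, I = 4, J = 4),
               makeParams(0, 1, 1, 1, I = 4, J = 4))
    passed <- initializeModel(named(matrix(rnorm(16), 4, 4)), initTheta = th)
    expect_identical(passed@theta1, th[[1]])
    expect_identical(passed@theta2, th[[2]])
})

test_that("E-step with identical components returns the priors", {
    Y <- named(matrix(rnorm(20), 4, 5))
    model <- makeToyModel(1, 1, I = 4, J = 5, p1 = 0.3, p2 = 0.7)
    prev <- BicPosterior(r1 = rep(0.5, 4), r2 = rep(0.5, 5))
    post <- eStep(Y, model, prev)
    expect_equal(post@r1, rep(0.3, 4))
    expect_equal(post@r2, rep(0.7, 5))
    expect_equal(post@gamma, matrix(0.21, 4, 5))
})

test_that("enumeration oracle matches priors, hand expansion and probability bounds", {
    ## identical components: exact posteriors equal the priors
    Y <- named(matrix(rnorm(6), 2, 3))
    model <- makeToyModel(0, 0, I = 2, J = 3, p1 = 0.25, p2 = 0.6)
    ex <- enumeratePosterior(Y, model)
    expect_equal(ex$r1, rep(0.25, 2), tolerance = 1e-12)
    expect_equal(ex$r2, rep(0.6, 3), tolerance = 1e-12)
    expect_equal(ex$gamma, matrix(0.15, 2, 3), tolerance = 1e-12)

    ## 2x2: fully hand-expanded 16-configuration sum
    Y2 <- named(matrix(c(3.1, 0.2, -0.5, 2.8), 2, 2))
    model2 <- makeToyModel(3, 0, sigma2 = 0.5, delta2 = 0.2, tau2 = 0.3,
                           I = 2, J = 2, p1 = 0.4, p2 = 0.55)
    l1 <- outer(1:2, 1:2, Vectorize(function(i, j)
        cellLogDensity(Y2[i, j], model2@theta1, i, j)))
    l2 <- outer(1:2, 1:2, Vectorize(function(i, j)
        cellLogDensity(Y2[i, j], model2@theta2, i, j)))
    ws <- array(dim = c(2, 2, 2, 2))
    for (z11 in 0:1) for (z12 in 0:1) for (z21 in 0:1) for (z22 in 0:1) {
        z1 <- c(z11, z12); z2 <- c(z21, z22)
        lw <- 0
        for (i in 1:2) for (j in 1:2) {
            lw <- lw + if (z1[i] * z2[j] == 1) l1[i, j] else l2[i, j]
        }
        lw <- lw + sum(log(ifelse(z1 == 1, 0.4, 0.6))) +
                   sum(log(ifelse(z2 == 1, 0.55, 0.45)))
        ws[z11 + 1, z12 + 1, z21 + 1, z22 + 1] <- exp(lw)
    }
    tot <- sum(ws)
    r1hand <- c(sum(ws[2, , , ]), sum(ws[, 2, , ])) / tot
    r2hand <- c(sum(ws[, , 2, ]), sum(ws[, , , 2])) / tot
    ex2 <- enumeratePosterior(Y2, model2)
    expect_equal(ex2$r1, r1hand, tolerance = 1e-10)
    expect_equal(ex2$r2, r2hand, tolerance = 1e-10)
    expect_equal(ex2$gamma[1, 1], sum(ws[2, , 2, ]) / tot, tolerance = 1e-10)

    ## joint moments never exceed the marginals
    for (i in 1:2) for (j in 1:2) {
        expect_lte(ex2$gamma[i, j], min(ex2$r1[i], ex2$r2[j]) + 1e-12)
    }
    expect_error(enumeratePosterior(named(matrix(0, 12, 12)), model2),
                 "refusing")
})

test_that("mean-field E-step agrees with enumeration on separated problems", {
    ## planted 2x2 block at mu1 = 10 over mu2 = 0 background
    Y <- withr::with_seed(5, {
        Y <- matrix(rnorm(16), 4, 4)
        Y[1:2, 1:2] <- rnorm(4, 10, 1)
        named(Y)
    })
    model <- makeToyModel(10, 0, I = 4, J = 4, p1 = 0.5, p2 = 0.5)
    mf <- eStepConverged(Y, model)
    ex <- enumeratePosterior(Y, model)
    expect_lt(max(abs(mf@gamma - ex$gamma)), 0.02)
    expect_true(all(mf@gamma[1:2, 1:2] > 0.99))
    expect_true(all(mf@gamma[3:4, 3:4] < 0.01))

    ## single row: column posteriors against a direct Bayes computation
    Y1 <- named(matrix(c(8.2, -0.1, 7.9, 0.3), 1, 4))
    m1 <- makeToyModel(8, 0, I = 1, J = 4, p1 = 0.9, p2 = 0.5)
    mf1 <- eStepConverged(Y1, m1)
    ex1 <- enumeratePosterior(Y1, m1)
    expect_lt(max(abs(mf1@r2 - ex1$r2)), 0.02)
})

test_that("M-step limits reproduce weighted means and the ANOVA decomposition", {
    Y <- withr::with_seed(2, named(matrix(rnorm(30, 5, 2), 5, 6)))
    post1 <- BicPosterior(r1 = rep(1, 5), r2 = rep(1, 6))

    ## gamma = 1, tiny effect variances: effects vanish, component 1
    ## collapses to the global weighted mean / population variance
    tiny <- BicMixtureModel(
        makeParams(0, 1, 1e-10, 1e-10, I = 5, J = 6),
        makeParams(0, 1, 1, 1, I = 5, J = 6), 0.5, 0.5)
    up <- mStep(Y, post1, tiny)
    expect_equal(up@theta1@mu, mean(Y), tolerance = 1e-6)
    expect_equal(up@theta1@sigma2, mean((Y - mean(Y))^2), tolerance = 1e-4)

    ## gamma = 1, huge effect variances: mu + alpha_i + beta_j reproduces
    ## the additive (two-way ANOVA) decomposition of Y
    huge <- BicMixtureModel(
        makeParams(mean(Y), 1, 1e6, 1e6, I = 5, J = 6),
        makeParams(0, 1, 1, 1, I = 5, J = 6), 0.5, 0.5)
    up2 <- mStep(Y, post1, huge)
    fitted <- up2@theta1@mu + outer(up2@theta1@alpha, up2@theta1@beta, `+`)
    anova <- outer(rowMeans(Y), colMeans(Y), `+`) - mean(Y)
    expect_equal(fitted, anova, tolerance = 1e-3, ignore_attr = TRUE)

    ## checkerboard gamma: every update recomputed term by term
    Y3 <- named(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3))
    r1 <- c(0.9, 0.2, 0.7); r2 <- c(0.3, 0.8, 0.5)
    post3 <- BicPosterior(r1 = r1, r2 = r2)
    m3 <- BicMixtureModel(
        makeParams(4, 2, 0.5, 0.8, I = 3, J = 3,
                   alpha = c(0.2, -0.1, 0), beta = c(0.1, 0, -0.2)),
        makeParams(5, 1, 0.3, 0.3, I = 3, J = 3), 0.5, 0.5)
    up3 <- mStep(Y3, post3, m3)
    W <- outer(r1, r2)
    th <- m3@theta1
    betaHand <- numeric(3)
    for (j in 1:3) {
        num <- den <- 0
        for (i in 1:3) {
            num <- num + W[i, j] * (Y3[i, j] - th@mu - th@alpha[i])
            den <- den + W[i, j]
        }
        betaHand[j] <- th@tau2 * num / (th@tau2 * den + th@sigma2)
    }
    alphaHand <- numeric(3)
    for (i in 1:3) {
        num <- den <- 0
        for (j in 1:3) {
            num <- num + W[i, j] * (Y3[i, j] - th@mu - betaHand[j])
            den <- den + W[i, j]
        }
        alphaHand[i] <- th@delta2 * num / (th@delta2 * den + th@sigma2)
    }
    betaC <- betaHand - mean(betaHand)
    alphaC <- alphaHand - mean(alphaHand)
    muHand <- sum(W * (Y3 - outer(alphaC, betaC, `+`))) / sum(W)
    residHand <- Y3 - muHand - outer(alphaC, betaC, `+`)
    expect_equal(up3@theta1@beta, betaC, tolerance = 1e-12)
    expect_equal(up3@theta1@alpha, alphaC, tolerance = 1e-12)
    expect_equal(up3@theta1@mu, muHand, tolerance = 1e-12)
    expect_equal(up3@theta1@sigma2, sum(W * residHand^2) / sum(W),
                 tolerance = 1e-12)
    expect_equal(up3@theta1@delta2, mean(alphaC^2), tolerance = 1e-12)
    expect_equal(up3@theta1@tau2, mean(betaC^2), tolerance = 1e-12)
    ## membership priors are posterior means, capped at the minority bound
    expect_equal(up3@p1, min(mean(r1), 0.5))
    expect_equal(up3@p2, min(mean(r2), 0.5))
    lowPost <- BicPosterior(r1 = r1 * 0.5, r2 = r2 * 0.5)
    upLow <- mStep(Y3, lowPost, m3)
    expect_equal(upLow@p1, mean(r1 * 0.5))
    expect_equal(upLow@p2, mean(r2 * 0.5))
})

test_that("fit converges immediately with a huge tolerance", {
    sim <- simConstantBicluster(2, nRow = 30, nCol = 40,
                               blockRows = 8, blockCols = 8)
    fit <- fitBicMixture(simValues(sim), epsilon = 1e6, maxIter = 50)
    expect_true(hasConverged(fit))
    expect_lte(nIterations(fit), 2L)
})

test_that("objective trace is non-decreasing on varied inputs", {
    sims <- list(simConstantBicluster(3, nRow = 40, nCol = 50,
                                      blockRows = 8, blockCols = 10),
                 simRowScaleShift(3, nRow = 50, nCol = 60,
                                  blockRows = 15, blockCols = 15),
                 simTwoGroupRatio(3, nGenes = 40, nGroupA = 15, nGroupB = 15,
                                  blockGenes = 8, blockPerGroup = 5))
    for (sim in sims) {
        fit <- fitBicMixture(simValues(sim))
        expect_true(all(diff(logLikTrace(fit)) > -1e-8),
                    label = paste("monotone trace,", sim@regime))
    }
    Ynoise <- withr::with_seed(9, named(matrix(rnorm(30 * 40), 30, 40)))
    fitN <- suppressMessages(fitBicMixture(Ynoise))
    expect_true(all(diff(logLikTrace(fitN)) > -1e-8))
})

test_that("pure-noise matrices yield no confident membership", {
    for (s in 1:5) {
        Y <- withr::with_seed(s, named(matrix(rnorm(60 * 80), 60, 80)))
        fit <- suppressMessages(fitBicMixture(Y))
        expect_lt(max(posteriorGamma(fit)), 0.5)
    }
})

test_that("posteriors are equivariant under row/column permutations", {
    sim <- simConstantBicluster(4, nRow = 30, nCol = 36,
                                blockRows = 8, blockCols = 8)
    Y <- simValues(sim)
    fit <- fitBicMixture(Y)
    pr <- withr::with_seed(1, sample(nrow(Y)))
    pc <- withr::with_seed(2, sample(ncol(Y)))
    fitP <- fitBicMixture(Y[pr, pc])
    expect_equal(rowPosterior(fitP), rowPosterior(fit)[pr], tolerance = 1e-6)
    expect_equal(colPosterior(fitP), colPosterior(fit)[pc], tolerance = 1e-6)
    expect_equal(posteriorGamma(fitP), posteriorGamma(fit)[pr, pc],
                 tolerance = 1e-6)
})

test_that("divergence and restart plumbing behave", {
    sim <- simConstantBicluster(5, nRow = 30, nCol = 40,
                                blockRows = 8, blockCols = 8)
    f1 <- fitBicMixture(simValues(sim), nRestarts = 3, rngSeed = 7)
    f2 <- fitBicMixture(simValues(sim), nRestarts = 3, rngSeed = 7)
    expect_identical(logLikTrace(f1), logLikTrace(f2))
    expect_true(hasConverged(f1))
})
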