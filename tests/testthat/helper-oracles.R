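## Shared fixtures and independent oracles. Oracles here are deliberately
## written as plain brute-force loops, independent of the package's
## vectorized implementation paths.

## component parameters with zero effects, for toy problems
makeParams <- function(mu, sigma2 = 1, delta2 = 1, tau2 = 1, I = 2L, J = 2L,
                       alpha = numeric(I), beta = numeric(J)) {
    ComponentParams(mu, sigma2, delta2, tau2, alpha, beta)
}

makeToyModel <- function(mu1, mu2, sigma2 = 1, delta2 = 1, tau2 = 1,
                         I = 2L, J = 2L, p1 = 0.5, p2 = 0.5) {
    BicMixtureModel(makeParams(mu1, sigma2, delta2, tau2, I, J),
                    makeParams(mu2, sigma2, delta2, tau2, I, J),
                    p1 = p1, p2 = p2)
}

named <- function(m) {
    if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
    m
}

## iterate the mean-field E-step to its fixed point at fixed parameters
eStepConverged <- function(Y, model, sweeps = 200L) {
    post <- BicPosterior(r1 = rep(model@p1, nrow(Y)),
                         r2 = rep(model@p2, ncol(Y)))
    for (s in seq_len(sweeps)) {
        nxt <- eStep(Y, model, post)
        if (max(abs(nxt@r1 - post@r1), abs(nxt@r2 - post@r2)) < 1e-12) break
        post <- nxt
    }
    nxt
}

## exhaustive maximum-area qualifying submatrix containing the seed
## (single column group): row and column intervals in the sorted
## arrangement, overall ones fraction >= pAve, and every selected line at
## least min(pAve, 1/2) ones within the submatrix
growOracleArea <- function(u, seedSorted, pAve) {
    I <- nrow(u); J <- ncol(u)
    lineFloor <- min(pAve, 0.5)
    best <- 0L
    for (a in seq_len(seedSorted[1L])) for (b in seedSorted[1L]:I)
        for (cc in seq_len(seedSorted[2L])) for (d in seedSorted[2L]:J) {
            sub <- u[a:b, cc:d, drop = FALSE]
            if (mean(sub) < pAve) next
            if (any(rowMeans(sub) < lineFloor) ||
                any(colMeans(sub) < lineFloor)) next
            best <- max(best, length(sub))
        }
    best
}

## binary membership with sorted orders from a 0/1 matrix
sortedMembership <- function(u, ac = 0.5, colGroups = NULL) {
    g <- named(u * 0.9 + 0.05)
    sortMembership(binarizeGamma(g, ac), colGroups = colGroups)
}

## cell-set Jaccard recomputed by explicit enumeration of (row, col) pairs
jaccardByEnumeration <- function(b1, b2) {
    cells <- function(b) {
        as.vector(outer(biclusterRows(b), biclusterCols(b), paste, sep = "\r"))
    }
    c1 <- cells(b1); c2 <- cells(b2)
    length(intersect(c1, c2)) / length(union(c1, c2))
}

## random bicluster set over a shared id space
randomBiclusterSet <- function(n, nGenes = 20L, nSamples = 15L) {
    BiclusterSet(lapply(seq_len(n), function(k) {
        Bicluster(rows = paste0("g", sort(sample.int(nGenes, sample(2:6, 1)))),
                  cols = paste0("s", sort(sample.int(nSamples, sample(2:6, 1)))))
    }))
}

scoreRegime <- function(sim, ac, pAve) {
    fit <- fitBicMixture(simValues(sim))
    truth <- BiclusterSet(list(trueBicluster(sim)))
    bs <- extractBiclusters(fit, ac = ac, pAve = pAve)
    list(fit = fit, bs = bs, truth = truth,
         recovery = recoveryScore(truth, bs),
         relevance = relevanceScore(truth, bs))
}
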