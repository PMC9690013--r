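## Variational EM for the two-component bicluster mixture.

.VAR_FLOOR <- 1e-8
.P_CLAMP <- 1e-12

#' Initialize the mixture model from the data
#'
#' Component means and variances are seeded from a deterministic
#' two-cluster split of the pooled cell values: one centre at the pooled
#' median, the other at the mean of the 0.5% tail that deviates more from
#' the median (so a low-valued planted signal is found just as well as a
#' high-valued one). The minority/extreme cluster seeds the bicluster
#' component. Row/column effect variances start at a fixed fraction (0.1)
#' of the corresponding noise variance; effects start at zero.
#'
#' @param Y numeric matrix (validated with [validateExpressionMatrix()]).
#' @param initP numeric(2); starting membership priors (rows, columns).
#' @param initTheta optional list of two [ComponentParams-class] objects
#'   (bicluster, background) echoed as-is, bypassing the data-driven seed.
#' @return A [BicMixtureModel-class].
#' @export
initializeModel <- function(Y, initP = c(0.5, 0.5), initTheta = NULL) {
    Y <- validateExpressionMatrix(Y)
    if (any(initP <= 0) || any(initP >= 1))
        stop("'initP' entries must lie in (0,1)")
    I <- nrow(Y); J <- ncol(Y)
    if (!is.null(initTheta)) {
        stopifnot(length(initTheta) == 2L)
        return(BicMixtureModel(initTheta[[1L]], initTheta[[2L]],
                               p1 = initP[1L], p2 = initP[2L]))
    }
    y <- as.vector(Y)
    if (stats::var(y) <= .Machine$double.eps)
        stop("degenerate input: matrix is (numerically) constant")
    med <- stats::median(y)
    qs <- stats::quantile(y, c(0.005, 0.995), names = FALSE)
    hi <- mean(y[y >= qs[2L]]); lo <- mean(y[y <= qs[1L]])
    tailCentre <- if ((hi - med) >= (med - lo)) hi else lo
    km <- stats::kmeans(y, centers = matrix(c(med, tailCentre), ncol = 1L),
                        iter.max = 100L)
    bicCl <- 2L  # cluster seeded at the extreme tail
    yb <- y[km$cluster == bicCl]
    yg <- y[km$cluster != bicCl]
    if (length(yb) < 2L || length(yg) < 2L)
        stop("degenerate input: could not split cell values into two groups")
    ## refine the hard split by a scalar two-component Gaussian fit of the
    ## pooled cell values (deterministic; the hard split is its start)
    sm <- .scalarMixEM(y, mean(yb), stats::var(yb), mean(yg), stats::var(yg),
                       length(yb) / length(y))
    mu1 <- sm$mu1; s1 <- max(sm$s1, .VAR_FLOOR)
    mu2 <- sm$mu2; s2 <- max(sm$s2, .VAR_FLOOR)
    ## effect variances start at a fixed fraction of the noise variance;
    ## structure-free data sends them to their floor, as it should
    theta1 <- ComponentParams(mu1, s1, 0.1 * s1, 0.1 * s1,
                              numeric(I), numeric(J))
    theta2 <- ComponentParams(mu2, s2, 0.1 * s2, 0.1 * s2,
                              numeric(I), numeric(J))
    BicMixtureModel(theta1, theta2, p1 = initP[1L], p2 = initP[2L])
}

## Scalar two-component Gaussian mixture EM over the pooled cell values,
## used only to seed the component means/variances. Deterministic.
.scalarMixEM <- function(y, mu1, s1, mu2, s2, w1, iters = 100L) {
    s1 <- max(s1, .VAR_FLOOR); s2 <- max(s2, .VAR_FLOOR)
    w1 <- min(max(w1, 1e-6), 1 - 1e-6)
    for (k in seq_len(iters)) {
        l1 <- stats::dnorm(y, mu1, sqrt(s1), log = TRUE) + log(w1)
        l2 <- stats::dnorm(y, mu2, sqrt(s2), log = TRUE) + log1p(-w1)
        r <- stats::plogis(l1 - l2)
        sr <- sum(r)
        if (sr < 2 || sum(1 - r) < 2) break
        mu1n <- sum(r * y) / sr
        s1n <- max(sum(r * (y - mu1n)^2) / sr, .VAR_FLOOR)
        mu2n <- sum((1 - r) * y) / (length(y) - sr)
        s2n <- max(sum((1 - r) * (y - mu2n)^2) / (length(y) - sr), .VAR_FLOOR)
        w1n <- sr / length(y)
        done <- max(abs(mu1n - mu1), abs(mu2n - mu2)) < 1e-8
        mu1 <- mu1n; s1 <- s1n; mu2 <- mu2n; s2 <- s2n; w1 <- w1n
        if (done) break
    }
    list(mu1 = mu1, s1 = s1, mu2 = mu2, s2 = s2, w1 = w1)
}

#' One E-step sweep (mean-field update of the membership posterior)
#'
#' Updates the row posteriors first, using the previous column posteriors,
#' then the column posteriors using the fresh row values:
#' \deqn{\mathrm{logit}\, r_{1i} = \mathrm{logit}\, p_1 +
#'   \sum_j r_{2j}\,[\log f_1(y_{ij}) - \log f_2(y_{ij})],}
#' symmetrically for columns, and \eqn{\gamma_{ij} = r_{1i} r_{2j}}. The
#' per-cell log-likelihood ratio uses the conditional Gaussian densities
#' at the current effect estimates. All arithmetic is in log space; the
#' logistic map replaces an explicit log-sum-exp.
#'
#' @param Y numeric matrix.
#' @param model a [BicMixtureModel-class].
#' @param prev the previous [BicPosterior-class] (only `r2` is consumed).
#' @return The updated [BicPosterior-class].
#' @export
eStep <- function(Y, model, prev) {
    if (length(prev@r2) != ncol(Y) || length(prev@r1) != nrow(Y))
        stop("posterior dimensions do not match 'Y'")
    L <- .cellLogLikMatrix(Y, model@theta1) - .cellLogLikMatrix(Y, model@theta2)
    lo1 <- stats::qlogis(model@p1) + as.vector(L %*% prev@r2)
    r1 <- stats::plogis(lo1)
    lo2 <- stats::qlogis(model@p2) + as.vector(crossprod(L, r1))
    r2 <- stats::plogis(lo2)
    BicPosterior(r1 = r1, r2 = r2)
}

#' One M-step (membership-weighted parameter updates)
#'
#' Updates the bicluster component with weights \eqn{\gamma_{ij}} and the
#' background with \eqn{1-\gamma_{ij}}. Within a component, updates are
#' exact coordinate maximizers of the expected complete-data
#' log-likelihood, in order: column effects (ridge shrinkage,
#' \eqn{\beta_j = \tau^2 \sum_i w_{ij} r_{ij} / (\tau^2 \sum_i w_{ij} + \sigma^2)}
#' with \eqn{r_{ij}} the residual), row effects (symmetrically with
#' \eqn{\delta^2}), grand mean, noise variance, then the effect variances
#' as the plain means of the squared effects (each effect's prior counts
#' once per line). Membership priors become the means of the row/column
#' posteriors. Variances are floored at 1e-8. A component whose total
#' weight is (numerically) zero is left unchanged, with a message.
#'
#' @param Y numeric matrix.
#' @param posterior a [BicPosterior-class].
#' @param model the current [BicMixtureModel-class].
#' @return The updated [BicMixtureModel-class].
#' @export
mStep <- function(Y, posterior, model) {
    if (!identical(dim(Y), dim(posterior@gamma)))
        stop("posterior dimensions do not match 'Y'")
    g <- posterior@gamma
    theta1 <- .mStepComponent(Y, g, model@theta1)
    theta2 <- .mStepComponent(Y, 1 - g, model@theta2)
    ## the bicluster is the minority class by convention: capping the
    ## membership priors at 1/2 keeps the component labels identified
    ## (the boundary value still ascends the objective)
    p1 <- min(max(mean(posterior@r1), .P_CLAMP), 0.5)
    p2 <- min(max(mean(posterior@r2), .P_CLAMP), 0.5)
    BicMixtureModel(theta1, theta2, p1 = p1, p2 = p2)
}

.mStepComponent <- function(Y, W, params) {
    sw <- sum(W)
    if (sw <= .Machine$double.eps * length(W)) {
        message("component received (numerically) zero weight; parameters left unchanged")
        return(params)
    }
    mu <- params@mu; s2 <- params@sigma2
    d2 <- params@delta2; t2 <- params@tau2
    colW <- colSums(W); rowW <- rowSums(W)
    ## column effects, then row effects with the fresh columns: ridge
    ## (posterior-mean) shrinkage, with the effective sample size of a
    ## line given by its total membership weight
    beta <- t2 * colSums(W * (Y - mu - params@alpha)) / (t2 * colW + s2)
    alpha <- d2 * rowSums(W * sweep(Y - mu, 2L, beta)) / (d2 * rowW + s2)
    ## centring the effects (their mean is absorbed by the grand mean
    ## right below) leaves every fitted cell mean unchanged and can only
    ## increase the effects' prior term: the mean/effect split is
    ## otherwise unidentified and would drift for many iterations
    beta <- beta - mean(beta)
    alpha <- alpha - mean(alpha)
    fit0 <- outer(alpha, beta, `+`)
    muNew <- sum(W * (Y - fit0)) / sw
    resid <- Y - muNew - fit0
    s2New <- max(sum(W * resid^2) / sw, .VAR_FLOOR)
    ## effect variances: each effect's prior is counted once per line, so
    ## the maximizers are the plain means of the squared effects
    d2New <- max(mean(alpha^2), .VAR_FLOOR)
    t2New <- max(mean(beta^2), .VAR_FLOOR)
    ComponentParams(muNew, s2New, d2New, t2New, alpha, beta)
}

#' Fit the bicluster mixture model by variational EM
#'
#' Alternates [eStep()] and [mStep()] from [initializeModel()] until the
#' change in the variational objective (the expected complete-data
#' log-likelihood plus the membership entropy) falls below `epsilon`, or
#' `maxIter` is reached. Membership posteriors are initialized by a
#' burn-in that marginalizes the opposite indicator cell by cell, which is
#' robust to an uninformative start. After convergence a deterministic
#' refinement leg re-proposes row/column effects for *every* line from the
#' opposite axis's memberships and re-runs the EM, keeping whichever leg
#' ends with the better objective — this lets member lines whose values
#' mimic the background (until their effect is known) be recovered. With
#' `nRestarts > 1`, restarts 2..n additionally perturb the initial
#' component means with seed-derived Gaussian jitter; the best restart is
#' returned.
#'
#' Two identifiability conventions apply: the membership priors are capped
#' at 1/2 (the bicluster is the minority class), and if the fitted
#' components' marginal densities are numerically indistinguishable
#' (symmetrized KL below 0.05 nats — no bicluster signal), the membership
#' posteriors are reset to their priors, with a message.
#'
#' @param Y numeric matrix (genes x samples).
#' @param epsilon convergence tolerance on the objective change
#'   (default 1e-5, the conventional value for this model family).
#' @param maxIter iteration cap (default 500).
#' @param initP starting membership priors, default `c(0.5, 0.5)`.
#' @param initTheta optional starting component parameters, see
#'   [initializeModel()].
#' @param rngSeed integer seed for randomized restarts (only source of
#'   randomness; with `nRestarts = 1` the fit is fully deterministic).
#' @param nRestarts number of restarts (default 1).
#' @param relative if `TRUE`, the stopping rule uses the relative rather
#'   than absolute objective change.
#' @param verbose print per-iteration objective values.
#' @return A [BicFit-class].
#' @examples
#' sim <- simConstantBicluster(1, nRow = 60, nCol = 80,
#'                             blockRows = 10, blockCols = 10)
#' fit <- fitBicMixture(simValues(sim))
#' mixtureModel(fit)
#' @export
fitBicMixture <- function(Y, epsilon = 1e-5, maxIter = 500L,
                          initP = c(0.5, 0.5), initTheta = NULL,
                          rngSeed = 1L, nRestarts = 1L,
                          relative = FALSE, verbose = FALSE) {
    Y <- validateExpressionMatrix(Y)
    stopifnot(epsilon > 0, maxIter >= 1L, nRestarts >= 1L)
    jitters <- if (nRestarts > 1L) {
        withr::with_seed(as.integer(rngSeed) %% .Machine$integer.max,
                         stats::rnorm(2L * nRestarts))
    } else numeric(2L)
    best <- NULL
    for (r in seq_len(nRestarts)) {
        model0 <- initializeModel(Y, initP = initP, initTheta = initTheta)
        if (r > 1L) {
            jit <- jitters[(2L * r - 1L):(2L * r)]
            th1 <- model0@theta1; th2 <- model0@theta2
            th1@mu <- th1@mu + jit[1L] * sqrt(th1@sigma2)
            th2@mu <- th2@mu + jit[2L] * sqrt(th2@sigma2)
            model0 <- BicMixtureModel(th1, th2, model0@p1, model0@p2)
        }
        fit <- .emLoop(Y, model0, epsilon, maxIter, relative, verbose)
        if (is.null(best) ||
            fit@logLikTrace[fit@nIter] > best@logLikTrace[best@nIter])
            best <- fit
    }
    ## structured refinement leg: a line excluded throughout the fit never
    ## had its effect estimated (its ridge weights were ~0), so a genuine
    ## member line whose values mimic the background *until* its effect is
    ## known can stay locked out. Re-propose effects for every line from
    ## the opposite axis's memberships alone, re-run the EM from there,
    ## and keep whichever leg ends with the better objective.
    fit2 <- .emLoop(Y, .refineEffects(Y, best), epsilon, maxIter,
                    relative, verbose)
    if (fit2@logLikTrace[fit2@nIter] > best@logLikTrace[best@nIter])
        best <- fit2
    best
}

.refineEffects <- function(Y, fit) {
    model <- fit@model
    th <- model@theta1
    r1 <- fit@posterior@r1; r2 <- fit@posterior@r2
    mu <- th@mu; s2 <- th@sigma2; d2 <- th@delta2; t2 <- th@tau2
    beta <- t2 * as.vector(crossprod(Y - mu - th@alpha, r1)) /
        (t2 * sum(r1) + s2)
    mu <- mu + mean(beta)          # keep fitted cell means unchanged
    beta <- beta - mean(beta)
    alpha <- d2 * as.vector(sweep(Y - mu, 2L, beta) %*% r2) /
        (d2 * sum(r2) + s2)
    mu <- mu + mean(alpha)
    alpha <- alpha - mean(alpha)
    BicMixtureModel(ComponentParams(mu, s2, d2, t2, alpha, beta),
                    model@theta2, model@p1, model@p2)
}

## Membership burn-in used to initialize the posterior: row/column
## updates that marginalize the *other* index's indicator cell by cell,
## logit r1i = logit p1 + sum_j log[r2j f1(y_ij) + (1 - r2j) f2(y_ij)] - log f2(y_ij).
## Each cell's contribution is bounded below by log(1 - r2j), so under an
## uncertain start the many off-bicluster cells of a genuine bicluster row
## cannot outvote its member cells — unlike the linearized mean-field sum,
## whose flat-start fixed point can collapse to "no bicluster". Run at
## fixed parameters until the memberships stabilize; the main EM loop then
## proceeds with the exact mean-field coordinate updates.
.burnInPosterior <- function(Y, model, maxSweeps = 25L, tol = 1e-6) {
    I <- nrow(Y); J <- ncol(Y)
    L <- .cellLogLikMatrix(Y, model@theta1) - .cellLogLikMatrix(Y, model@theta2)
    mixTerm <- function(L, w) {
        ## log(w * exp(L) + 1 - w), columns of L weighted by w, stably
        t0 <- pmax(L, 0)
        t0 + log(w * exp(L - t0) + (1 - w) * exp(-t0))
    }
    r1 <- rep(model@p1, I); r2 <- rep(model@p2, J)
    for (s in seq_len(maxSweeps)) {
        R2 <- matrix(r2, I, J, byrow = TRUE)
        r1n <- stats::plogis(stats::qlogis(model@p1) + rowSums(mixTerm(L, R2)))
        R1 <- matrix(r1n, I, J)
        r2n <- stats::plogis(stats::qlogis(model@p2) + colSums(mixTerm(L, R1)))
        done <- max(abs(r1n - r1), abs(r2n - r2)) < tol
        r1 <- r1n; r2 <- r2n
        if (done) break
    }
    BicPosterior(r1 = r1, r2 = r2)
}

.emLoop <- function(Y, model, epsilon, maxIter, relative, verbose) {
    post <- .burnInPosterior(Y, model)
    trace <- numeric(0)
    objPrev <- -Inf
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        post <- eStep(Y, model, post)
        model <- mStep(Y, post, model)
        obj <- .elbo(Y, post, model)
        if (!is.finite(obj))
            stop("EM objective became non-finite at iteration ", iter)
        trace <- c(trace, obj)
        if (verbose)
            message(sprintf("iter %3d: objective %.6f", iter, obj))
        delta <- obj - objPrev
        if (relative && is.finite(objPrev)) delta <- abs(delta / objPrev)
        if (is.finite(objPrev) && abs(delta) < epsilon) {
            converged <- TRUE
            break
        }
        objPrev <- obj
    }
    if (.componentsIndistinguishable(model)) {
        ## with theta1 = theta2 the likelihood is invariant to the
        ## memberships and the exact posterior equals the prior; when the
        ## fitted components are numerically that close, the iterated
        ## posteriors are amplified noise, so report the symmetric answer
        message("fitted components are (numerically) indistinguishable; ",
                "no bicluster signal - membership posteriors equal priors")
        post <- BicPosterior(r1 = rep(model@p1, nrow(Y)),
                             r2 = rep(model@p2, ncol(Y)))
    }
    new("BicFit", model = model, posterior = post, logLikTrace = trace,
        nIter = iter, converged = converged, dimnames = dimnames(Y))
}

## symmetrized KL divergence between the two components' marginal cell
## densities (random effects integrated out); below ~0.05 nats the
## densities overlap almost completely and membership is unidentified.
.componentsIndistinguishable <- function(model, tol = 0.05) {
    S1 <- model@theta1@sigma2 + model@theta1@delta2 + model@theta1@tau2
    S2 <- model@theta2@sigma2 + model@theta2@delta2 + model@theta2@tau2
    dmu2 <- (model@theta1@mu - model@theta2@mu)^2
    sym <- 0.25 * (S1 / S2 + S2 / S1 - 2) + 0.25 * dmu2 * (1 / S1 + 1 / S2)
    is.finite(sym) && sym < tol
}
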