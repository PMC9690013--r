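## Exact posterior by brute-force enumeration. Test oracle for the
## mean-field E-step; exponential in I+J, so restricted to tiny inputs.

#' Exact membership posterior by enumeration
#'
#' Computes \eqn{E[z_{1i}]}, \eqn{E[z_{2j}]} and \eqn{E[z_{1i} z_{2j}]}
#' exactly by summing the complete joint likelihood over all
#' \eqn{2^{I+J}} configurations of the membership indicators, using the
#' same per-cell likelihoods as [eStep()]. Intended as an independent
#' check of the mean-field approximation on small problems.
#'
#' Note the returned object reports the exact product moments
#' \eqn{E[z_{1i} z_{2j}]} in its `gamma` slot by construction of the
#' computation, whereas a [BicPosterior-class] built from marginals alone
#' would factorize; for the well-separated problems where the mean-field
#' fit is trustworthy the two coincide.
#'
#' @param Y numeric matrix with `nrow(Y) + ncol(Y) <= 20`.
#' @param model a [BicMixtureModel-class].
#' @return A list with `r1`, `r2` (exact marginals) and `gamma` (exact
#'   joint moments \eqn{E[z_{1i} z_{2j}]}).
#' @export
enumeratePosterior <- function(Y, model) {
    stopifnot(is.matrix(Y), is.numeric(Y), all(is.finite(Y)))
    I <- nrow(Y); J <- ncol(Y)
    if (I + J > 20L)
        stop("refusing enumeration for I + J > 20 (2^(I+J) configurations)")
    L1 <- .cellLogLikMatrix(Y, model@theta1)
    L2 <- .cellLogLikMatrix(Y, model@theta2)
    lp1 <- log(model@p1); lq1 <- log1p(-model@p1)
    lp2 <- log(model@p2); lq2 <- log1p(-model@p2)
    nCfg <- 2L^(I + J)
    logw <- numeric(nCfg)
    z1s <- matrix(0L, nCfg, I)
    z2s <- matrix(0L, nCfg, J)
    for (cfg in seq_len(nCfg) - 1L) {
        bits <- as.integer(intToBits(cfg))[seq_len(I + J)]
        z1 <- bits[seq_len(I)]
        z2 <- bits[I + seq_len(J)]
        inB <- outer(z1, z2) == 1L
        logw[cfg + 1L] <- sum(L1[inB]) + sum(L2[!inB]) +
            sum(ifelse(z1 == 1L, lp1, lq1)) + sum(ifelse(z2 == 1L, lp2, lq2))
        z1s[cfg + 1L, ] <- z1
        z2s[cfg + 1L, ] <- z2
    }
    w <- exp(logw - max(logw))
    w <- w / sum(w)
    r1 <- as.vector(crossprod(z1s, w))
    r2 <- as.vector(crossprod(z2s, w))
    gamma <- matrix(0, I, J)
    for (k in seq_len(nCfg))
        gamma <- gamma + w[k] * outer(z1s[k, ], z2s[k, ])
    list(r1 = r1, r2 = r2, gamma = gamma)
}

## Iterate the mean-field E-step to a fixed point at fixed model
## parameters; used when comparing against the enumeration oracle.
.eStepFixedPoint <- function(Y, model, maxSweeps = 200L, tol = 1e-12) {
    post <- BicPosterior(r1 = rep(model@p1, nrow(Y)),
                         r2 = rep(model@p2, ncol(Y)))
    for (s in seq_len(maxSweeps)) {
        nxt <- eStep(Y, model, post)
        if (max(abs(nxt@r1 - post@r1), abs(nxt@r2 - post@r2)) < tol) {
            post <- nxt
            break
        }
        post <- nxt
    }
    post
}
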