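## Core densities of the two-component Gaussian random-effects mixture.

#' Validate an expression matrix
#'
#' Checks the contract every modelling function in the package relies on: a
#' numeric matrix with at least two rows and columns, all values finite,
#' unique row and column identifiers, and (if given) a group label for
#' every column.
#'
#' @param Y numeric matrix (genes x samples). Missing dimnames are filled
#'   in as `g1..gI` / `s1..sJ`.
#' @param colGroups optional character vector of sample group labels, named
#'   by column identifier (or unnamed of length `ncol(Y)`).
#' @return `Y`, with dimnames guaranteed, invisibly usable downstream.
#' @export
validateExpressionMatrix <- function(Y, colGroups = NULL) {
    if (!is.matrix(Y) || !is.numeric(Y))
        stop("'Y' must be a numeric matrix")
    if (nrow(Y) < 2L || ncol(Y) < 2L)
        stop("'Y' must have at least 2 rows and 2 columns")
    if (!all(is.finite(Y)))
        stop("'Y' must contain only finite values")
    if (is.null(rownames(Y))) rownames(Y) <- paste0("g", seq_len(nrow(Y)))
    if (is.null(colnames(Y))) colnames(Y) <- paste0("s", seq_len(ncol(Y)))
    if (anyDuplicated(rownames(Y)))
        stop("duplicate row identifiers: ",
             paste(unique(rownames(Y)[duplicated(rownames(Y))]), collapse = ", "))
    if (anyDuplicated(colnames(Y)))
        stop("duplicate column identifiers: ",
             paste(unique(colnames(Y)[duplicated(colnames(Y))]), collapse = ", "))
    if (!is.null(colGroups)) {
        if (is.null(names(colGroups))) {
            if (length(colGroups) != ncol(Y))
                stop("unnamed 'colGroups' must have one label per column")
            names(colGroups) <- colnames(Y)
        }
        if (!all(colnames(Y) %in% names(colGroups)))
            stop("every column must have a group label")
    }
    Y
}

.checkParams <- function(params) {
    if (params@sigma2 <= 0 || params@delta2 <= 0 || params@tau2 <= 0)
        stop("component variances must be strictly positive")
    invisible(params)
}

#' Per-cell Gaussian log-density under one component
#'
#' With `marginal = FALSE` this is the density of a cell conditional on the
#' current row/column effect estimates,
#' \eqn{N(y;\, \mu + \alpha_i + \beta_j,\, \sigma^2)}. With
#' `marginal = TRUE` the random effects are integrated out and the density
#' is \eqn{N(y;\, \mu,\, \sigma^2 + \delta^2 + \tau^2)}. Both are proper
#' densities in \eqn{y}.
#'
#' @param y numeric scalar, the cell value.
#' @param params a [ComponentParams-class].
#' @param i,j row and column index of the cell (used to pick
#'   \eqn{\alpha_i}, \eqn{\beta_j} in the conditional form).
#' @param marginal logical; integrate the random effects out?
#' @return The log-density (scalar).
#' @examples
#' p <- ComponentParams(0, 1, 1, 1, numeric(3), numeric(3))
#' cellLogDensity(0, p, 1, 1, marginal = FALSE)  # log(1/sqrt(2*pi))
#' @export
cellLogDensity <- function(y, params, i, j, marginal = FALSE) {
    .checkParams(params)
    if (i < 1L || i > length(params@alpha) || j < 1L || j > length(params@beta))
        stop("cell index out of range")
    if (marginal) {
        stats::dnorm(y, mean = params@mu,
                     sd = sqrt(params@sigma2 + params@delta2 + params@tau2),
                     log = TRUE)
    } else {
        stats::dnorm(y, mean = params@mu + params@alpha[i] + params@beta[j],
                     sd = sqrt(params@sigma2), log = TRUE)
    }
}

## I x J matrix of per-cell conditional log-densities for one component:
## N(y; mu + alpha_i + beta_j, sigma^2) at the current effect estimates.
## The effects' own Gaussian priors enter the objective once per
## row/column (see .effectPriorLogLik), not per cell, so the E-step ratio
## uses these conditional densities alone.
.cellLogLikMatrix <- function(Y, params) {
    resid <- Y - params@mu - outer(params@alpha, params@beta, `+`)
    stats::dnorm(resid, sd = sqrt(params@sigma2), log = TRUE)
}

## log-prior of the effect estimates of one component: each row effect is
## N(0, delta^2), each column effect N(0, tau^2), each counted once.
.effectPriorLogLik <- function(params) {
    sum(stats::dnorm(params@alpha, sd = sqrt(params@delta2), log = TRUE)) +
        sum(stats::dnorm(params@beta, sd = sqrt(params@tau2), log = TRUE))
}

.marginalLogLikMatrix <- function(Y, params) {
    stats::dnorm(Y, mean = params@mu,
                 sd = sqrt(params@sigma2 + params@delta2 + params@tau2),
                 log = TRUE)
}

#' Expected complete-data log-likelihood
#'
#' The expectation, under a factorized posterior, of the complete-data
#' log-likelihood: a membership-weighted sum of per-cell log-densities plus
#' the Bernoulli prior terms for the row and column indicators,
#' \deqn{\sum_{ij} [\gamma_{ij} \log f_1(y_{ij}) + (1-\gamma_{ij}) \log f_2(y_{ij})]
#'   + \sum_i [r_{1i} \log p_1 + (1-r_{1i})\log(1-p_1)]
#'   + \sum_j [r_{2j} \log p_2 + (1-r_{2j})\log(1-p_2)].}
#'
#' With `marginal = TRUE` (default) the per-cell densities integrate the
#' random effects out; with `marginal = FALSE` they condition on the
#' current effect estimates (the data term of the internal EM objective,
#' which additionally counts each effect's Gaussian prior once per
#' row/column).
#'
#' @param Y numeric matrix.
#' @param posterior a [BicPosterior-class] dimensioned for `Y`.
#' @param model a [BicMixtureModel-class].
#' @param marginal logical; which per-cell density to use.
#' @return Scalar log-likelihood value.
#' @export
completeLogLik <- function(Y, posterior, model, marginal = TRUE) {
    if (!identical(dim(Y), dim(posterior@gamma)))
        stop("posterior dimensions do not match 'Y'")
    if (length(model@theta1@alpha) != nrow(Y) ||
        length(model@theta1@beta) != ncol(Y))
        stop("model dimensions do not match 'Y'")
    llmat <- if (marginal) .marginalLogLikMatrix else .cellLogLikMatrix
    l1 <- llmat(Y, model@theta1)
    l2 <- llmat(Y, model@theta2)
    g <- posterior@gamma
    dataTerm <- sum(g * l1 + (1 - g) * l2)
    priorTerm <- sum(posterior@r1 * log(model@p1) +
                     (1 - posterior@r1) * log1p(-model@p1)) +
                 sum(posterior@r2 * log(model@p2) +
                     (1 - posterior@r2) * log1p(-model@p2))
    dataTerm + priorTerm
}

## Bernoulli entropy with 0 log 0 = 0.
.bernEntropy <- function(r) {
    h <- numeric(length(r))
    ok <- r > 0 & r < 1
    h[ok] <- -(r[ok] * log(r[ok]) + (1 - r[ok]) * log1p(-r[ok]))
    sum(h)
}

## Variational lower bound: expected complete-data log-likelihood (cell
## densities conditional on the effect estimates, plus each effect's
## Gaussian prior counted once) plus the entropy of the factorized
## membership posterior. This is the objective whose trace is guaranteed
## non-decreasing under the E/M updates.
.elbo <- function(Y, posterior, model) {
    completeLogLik(Y, posterior, model, marginal = FALSE) +
        .effectPriorLogLik(model@theta1) + .effectPriorLogLik(model@theta2) +
        .bernEntropy(posterior@r1) + .bernEntropy(posterior@r2)
}
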