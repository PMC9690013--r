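#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Parameters of one mixture component
#'
#' One component of the bicluster mixture model. A cell assigned to
#' component \eqn{k} is modelled as
#' \deqn{y_{ij} = \mu_k + \alpha_{ki} + \beta_{kj} + \varepsilon_{kij},}
#' with row effects \eqn{\alpha_{ki} \sim N(0, \delta_k^2)}, column effects
#' \eqn{\beta_{kj} \sim N(0, \tau_k^2)} and noise
#' \eqn{\varepsilon_{kij} \sim N(0, \sigma_k^2)}. The `alpha` and `beta`
#' slots hold the current empirical-Bayes (shrinkage) point estimates of the
#' random effects.
#'
#' @slot mu numeric(1); grand mean of the component, in matrix units.
#' @slot sigma2 numeric(1); cell noise variance, strictly positive.
#' @slot delta2 numeric(1); row-effect variance, strictly positive.
#' @slot tau2 numeric(1); column-effect variance, strictly positive.
#' @slot alpha numeric(I); row effect estimates.
#' @slot beta numeric(J); column effect estimates.
#' @export
setClass("ComponentParams",
    representation(mu = "numeric", sigma2 = "numeric", delta2 = "numeric",
                   tau2 = "numeric", alpha = "numeric", beta = "numeric"))

setValidity("ComponentParams", function(object) {
    msg <- character()
    for (nm in c("mu", "sigma2", "delta2", "tau2"))
        if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
            msg <- c(msg, sprintf("'%s' must be a single finite number", nm))
    for (nm in c("sigma2", "delta2", "tau2"))
        if (length(slot(object, nm)) == 1L && is.finite(slot(object, nm)) &&
            slot(object, nm) <= 0)
            msg <- c(msg, sprintf("'%s' must be strictly positive", nm))
    if (!all(is.finite(object@alpha)))
        msg <- c(msg, "'alpha' must be finite")
    if (!all(is.finite(object@beta)))
        msg <- c(msg, "'beta' must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct mixture-component parameters
#'
#' @param mu,sigma2,delta2,tau2 scalar component parameters (variances > 0).
#' @param alpha,beta row/column effect vectors (length I and J).
#' @return A [ComponentParams-class] object.
#' @examples
#' ComponentParams(mu = 0, sigma2 = 1, delta2 = 1, tau2 = 1,
#'                 alpha = numeric(4), beta = numeric(6))
#' @export
ComponentParams <- function(mu, sigma2, delta2, tau2, alpha, beta) {
    new("ComponentParams", mu = as.numeric(mu), sigma2 = as.numeric(sigma2),
        delta2 = as.numeric(delta2), tau2 = as.numeric(tau2),
        alpha = as.numeric(alpha), beta = as.numeric(beta))
}

#' Two-component bicluster mixture model
#'
#' Holds the bicluster component (`theta1`), the background component
#' (`theta2`) and the Bernoulli membership priors `p1` (rows) and `p2`
#' (columns). A cell belongs to the bicluster iff both its row and its
#' column indicator are 1.
#'
#' @slot theta1 [ComponentParams-class]; the bicluster component.
#' @slot theta2 [ComponentParams-class]; the background component.
#' @slot p1 numeric(1) in (0,1); prior row membership probability.
#' @slot p2 numeric(1) in (0,1); prior column membership probability.
#' @export
setClass("BicMixtureModel",
    representation(theta1 = "ComponentParams", theta2 = "ComponentParams",
                   p1 = "numeric", p2 = "numeric"))

setValidity("BicMixtureModel", function(object) {
    msg <- character()
    for (nm in c("p1", "p2")) {
        p <- slot(object, nm)
        if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
            msg <- c(msg, sprintf("'%s' must be a single value in (0,1)", nm))
    }
    if (length(object@theta1@alpha) != length(object@theta2@alpha) ||
        length(object@theta1@beta) != length(object@theta2@beta))
        msg <- c(msg, "components must be dimensioned for the same I and J")
    if (length(msg)) msg else TRUE
})

#' @rdname BicMixtureModel-class
#' @param theta1,theta2 [ComponentParams-class] for bicluster and background.
#' @param p1,p2 membership priors in (0,1).
#' @return A [BicMixtureModel-class] object.
#' @export
BicMixtureModel <- function(theta1, theta2, p1 = 0.5, p2 = 0.5) {
    new("BicMixtureModel", theta1 = theta1, theta2 = theta2,
        p1 = as.numeric(p1), p2 = as.numeric(p2))
}

#' Factorized posterior over the membership indicators
#'
#' The variational (mean-field) posterior: `r1[i]` is the posterior
#' probability that row i belongs to the bicluster, `r2[j]` the same for
#' column j, and `gamma[i, j] = r1[i] * r2[j]` is the posterior probability
#' that cell (i, j) lies in the bicluster.
#'
#' @slot r1 numeric(I) in \[0,1\].
#' @slot r2 numeric(J) in \[0,1\].
#' @slot gamma I x J matrix, the outer product of `r1` and `r2`.
#' @export
setClass("BicPosterior",
    representation(r1 = "numeric", r2 = "numeric", gamma = "matrix"))

setValidity("BicPosterior", function(object) {
    msg <- character()
    rng <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
    if (!rng(object@r1)) msg <- c(msg, "'r1' entries must lie in [0,1]")
    if (!rng(object@r2)) msg <- c(msg, "'r2' entries must lie in [0,1]")
    if (!identical(dim(object@gamma),
                   c(length(object@r1), length(object@r2))))
        msg <- c(msg, "'gamma' must be length(r1) x length(r2)")
    if (length(msg)) msg else TRUE
})

#' @rdname BicPosterior-class
#' @param r1,r2 membership probability vectors.
#' @param gamma optional cell posterior matrix; defaults to `outer(r1, r2)`
#'   (and is forced to be exactly that product).
#' @return A [BicPosterior-class] object.
#' @export
BicPosterior <- function(r1, r2, gamma = NULL) {
    gamma <- outer(as.numeric(r1), as.numeric(r2))
    new("BicPosterior", r1 = as.numeric(r1), r2 = as.numeric(r2),
        gamma = gamma)
}

#' Result of fitting the bicluster mixture model
#'
#' @slot model the final [BicMixtureModel-class].
#' @slot posterior the final [BicPosterior-class].
#' @slot logLikTrace numeric; the variational objective (expected
#'   complete-data log-likelihood plus membership entropy) after each
#'   iteration. Non-decreasing up to numerical tolerance.
#' @slot nIter integer; iterations used.
#' @slot converged logical; whether the stopping rule fired before the
#'   iteration cap.
#' @slot dimnames list; row and column identifiers of the fitted matrix.
#' @export
setClass("BicFit",
    representation(model = "BicMixtureModel", posterior = "BicPosterior",
                   logLikTrace = "numeric", nIter = "integer",
                   converged = "logical", dimnames = "list"))

#' An extracted bicluster
#'
#' @slot rows character; member row (gene) identifiers.
#' @slot cols character; member column (sample) identifiers.
#' @slot meanMembership numeric(1); average posterior membership
#'   probability over the bicluster's cells.
#' @slot onesFraction numeric(1); fraction of the bicluster's cells whose
#'   binary membership indicator is 1.
#' @export
setClass("Bicluster",
    representation(rows = "character", cols = "character",
                   meanMembership = "numeric", onesFraction = "numeric"))

setValidity("Bicluster", function(object) {
    msg <- character()
    if (length(object@rows) == 0L || length(object@cols) == 0L)
        msg <- c(msg, "a Bicluster must have at least one row and one column")
    if (anyDuplicated(object@rows) || anyDuplicated(object@cols))
        msg <- c(msg, "row/column identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' @rdname Bicluster-class
#' @param rows,cols member identifiers.
#' @param meanMembership,onesFraction summary statistics (see slots).
#' @return A [Bicluster-class] object.
#' @export
Bicluster <- function(rows, cols, meanMembership = NA_real_,
                      onesFraction = NA_real_) {
    new("Bicluster", rows = as.character(rows), cols = as.character(cols),
        meanMembership = as.numeric(meanMembership),
        onesFraction = as.numeric(onesFraction))
}

#' An ordered collection of biclusters
#'
#' Sequentially extracted biclusters are cell-disjoint. `provenance` echoes
#' the extraction configuration and fit identifiers.
#'
#' @slot biclusters list of [Bicluster-class].
#' @slot provenance list.
#' @export
setClass("BiclusterSet",
    representation(biclusters = "list", provenance = "list"))

setValidity("BiclusterSet", function(object) {
    ok <- vapply(object@biclusters, function(b) is(b, "Bicluster"), logical(1))
    if (!all(ok)) "all elements must be Bicluster objects" else TRUE
})

#' @rdname BiclusterSet-class
#' @param biclusters list of [Bicluster-class] objects.
#' @param provenance free-form provenance list.
#' @return A [BiclusterSet-class] object.
#' @export
BiclusterSet <- function(biclusters = list(), provenance = list()) {
    new("BiclusterSet", biclusters = biclusters, provenance = provenance)
}

#' A simulated matrix with known planted bicluster
#'
#' @slot values numeric matrix with row/column identifiers.
#' @slot colGroups character or NULL; optional sample group labels, named
#'   by column identifier.
#' @slot trueRows,trueCols integer; indices of the planted bicluster.
#' @slot regime character(1); one of `"constant"`, `"row_scale_shift"`,
#'   `"col_scale_shift"`, `"two_group_ratio"`.
#' @slot params list; generator parameters actually used.
#' @slot seed integer(1); RNG seed that reproduces `values` bit-exactly.
#' @export
setClass("BicSimulation",
    representation(values = "matrix", colGroups = "characterOrNULL",
                   trueRows = "integer", trueCols = "integer",
                   regime = "character", params = "list", seed = "integer"))

setValidity("BicSimulation", function(object) {
    msg <- character()
    if (!all(object@trueRows >= 1L & object@trueRows <= nrow(object@values)))
        msg <- c(msg, "'trueRows' out of bounds")
    if (!all(object@trueCols >= 1L & object@trueCols <= ncol(object@values)))
        msg <- c(msg, "'trueCols' out of bounds")
    if (!is.null(object@colGroups) &&
        !all(colnames(object@values) %in% names(object@colGroups)))
        msg <- c(msg, "'colGroups' must cover every column")
    if (length(msg)) msg else TRUE
})
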