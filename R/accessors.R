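## Accessor generics and show methods for the core classes.

#' @name accessors
#' @title Accessors for fit, posterior and bicluster objects
#' @description Small accessor functions; user code should use these rather
#'   than reaching into slots.
#' @param object a package object (see Methods).
#' @param x a [BiclusterSet-class] (for `[[`/`length`).
#' @param i index.
#' @return The accessed component.
NULL

#' @rdname accessors
#' @export
setGeneric("mixtureModel", function(object) standardGeneric("mixtureModel"))
#' @rdname accessors
#' @export
setGeneric("posteriorOf", function(object) standardGeneric("posteriorOf"))
#' @rdname accessors
#' @export
setGeneric("posteriorGamma", function(object) standardGeneric("posteriorGamma"))
#' @rdname accessors
#' @export
setGeneric("rowPosterior", function(object) standardGeneric("rowPosterior"))
#' @rdname accessors
#' @export
setGeneric("colPosterior", function(object) standardGeneric("colPosterior"))
#' @rdname accessors
#' @export
setGeneric("logLikTrace", function(object) standardGeneric("logLikTrace"))
#' @rdname accessors
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))
#' @rdname accessors
#' @export
setGeneric("hasConverged", function(object) standardGeneric("hasConverged"))
#' @rdname accessors
#' @export
setGeneric("biclusterRows", function(object) standardGeneric("biclusterRows"))
#' @rdname accessors
#' @export
setGeneric("biclusterCols", function(object) standardGeneric("biclusterCols"))
#' @rdname accessors
#' @export
setGeneric("meanMembership", function(object) standardGeneric("meanMembership"))
#' @rdname accessors
#' @export
setGeneric("onesFraction", function(object) standardGeneric("onesFraction"))
#' @rdname accessors
#' @export
setGeneric("biclusters", function(object) standardGeneric("biclusters"))
#' @rdname accessors
#' @export
setGeneric("simValues", function(object) standardGeneric("simValues"))
#' @rdname accessors
#' @export
setGeneric("simGroups", function(object) standardGeneric("simGroups"))
#' @rdname accessors
#' @export
setGeneric("trueBicluster", function(object) standardGeneric("trueBicluster"))

#' @rdname accessors
setMethod("mixtureModel", "BicFit", function(object) object@model)
#' @rdname accessors
setMethod("posteriorOf", "BicFit", function(object) object@posterior)
#' @rdname accessors
setMethod("posteriorGamma", "BicFit", function(object) {
    g <- object@posterior@gamma
    dimnames(g) <- object@dimnames
    g
})
#' @rdname accessors
setMethod("posteriorGamma", "BicPosterior", function(object) object@gamma)
#' @rdname accessors
setMethod("rowPosterior", "BicFit", function(object) object@posterior@r1)
#' @rdname accessors
setMethod("colPosterior", "BicFit", function(object) object@posterior@r2)
#' @rdname accessors
setMethod("logLikTrace", "BicFit", function(object) object@logLikTrace)
#' @rdname accessors
setMethod("nIterations", "BicFit", function(object) object@nIter)
#' @rdname accessors
setMethod("hasConverged", "BicFit", function(object) object@converged)

#' @rdname accessors
setMethod("biclusterRows", "Bicluster", function(object) object@rows)
#' @rdname accessors
setMethod("biclusterCols", "Bicluster", function(object) object@cols)
#' @rdname accessors
setMethod("meanMembership", "Bicluster", function(object) object@meanMembership)
#' @rdname accessors
setMethod("onesFraction", "Bicluster", function(object) object@onesFraction)
#' @rdname accessors
setMethod("biclusters", "BiclusterSet", function(object) object@biclusters)

#' @rdname accessors
#' @export
setMethod("length", "BiclusterSet", function(x) length(x@biclusters))
#' @rdname accessors
#' @export
setMethod("[[", "BiclusterSet", function(x, i) x@biclusters[[i]])

#' @rdname accessors
setMethod("simValues", "BicSimulation", function(object) object@values)
#' @rdname accessors
setMethod("simGroups", "BicSimulation", function(object) object@colGroups)
#' @rdname accessors
setMethod("trueBicluster", "BicSimulation", function(object) {
    Bicluster(rows = rownames(object@values)[object@trueRows],
              cols = colnames(object@values)[object@trueCols],
              meanMembership = 1, onesFraction = 1)
})

setMethod("show", "ComponentParams", function(object) {
    cat(sprintf("ComponentParams: mu=%.4g sigma2=%.4g delta2=%.4g tau2=%.4g (I=%d, J=%d)\n",
                object@mu, object@sigma2, object@delta2, object@tau2,
                length(object@alpha), length(object@beta)))
})

setMethod("show", "BicMixtureModel", function(object) {
    cat("Two-component empirical Bayes bicluster mixture\n")
    cat(sprintf("  priors: p1=%.3f (rows), p2=%.3f (columns)\n",
                object@p1, object@p2))
    cat("  bicluster  "); show(object@theta1)
    cat("  background "); show(object@theta2)
})

setMethod("show", "BicFit", function(object) {
    cat(sprintf("BicFit: %d x %d matrix, %d iteration(s), %s\n",
                length(object@posterior@r1), length(object@posterior@r2),
                object@nIter,
                if (object@converged) "converged" else "not converged"))
    cat(sprintf("  final objective: %.6g\n",
                object@logLikTrace[length(object@logLikTrace)]))
    show(object@model)
})

setMethod("show", "Bicluster", function(object) {
    cat(sprintf("Bicluster: %d gene(s) x %d sample(s); mean membership %.3f; ones fraction %.3f\n",
                length(object@rows), length(object@cols),
                object@meanMembership, object@onesFraction))
})

setMethod("show", "BiclusterSet", function(object) {
    cat(sprintf("BiclusterSet of %d bicluster(s)\n", length(object@biclusters)))
    for (b in object@biclusters) {
        cat("  "); show(b)
    }
})

setMethod("show", "BicSimulation", function(object) {
    cat(sprintf("BicSimulation ('%s'): %d x %d matrix, planted block %d x %d, seed %d\n",
                object@regime, nrow(object@values), ncol(object@values),
                length(object@trueRows), length(object@trueCols), object@seed))
})
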