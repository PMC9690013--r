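## Building the mRNA-to-protein (GE/PA) ratio matrix from paired
## expression platforms, with per-group z-score normalization.

#' Align two omics matrices on shared genes and samples
#'
#' Restricts both matrices to the intersection of their gene and sample
#' identifiers, in matching order (the order of the first matrix), and
#' reports how many identifiers were dropped.
#'
#' @param ge mRNA expression matrix (genes x samples, dimnames required).
#' @param pa protein abundance matrix.
#' @param dropIncomplete drop genes with any missing value in either
#'   platform (default `TRUE`); with `FALSE`, missing cells are left for
#'   [ratioMatrix()] to handle.
#' @return A list with aligned `ge` and `pa` matrices (identical dimnames)
#'   and a `dropped` summary.
#' @export
alignOmics <- function(ge, pa, dropIncomplete = TRUE) {
    stopifnot(is.matrix(ge), is.matrix(pa))
    if (is.null(rownames(ge)) || is.null(rownames(pa)) ||
        is.null(colnames(ge)) || is.null(colnames(pa)))
        stop("both matrices need row and column identifiers")
    genes <- intersect(rownames(ge), rownames(pa))
    samples <- intersect(colnames(ge), colnames(pa))
    if (length(genes) == 0L) stop("no shared gene identifiers")
    if (length(samples) == 0L) stop("no shared sample identifiers")
    geA <- ge[genes, samples, drop = FALSE]
    paA <- pa[genes, samples, drop = FALSE]
    nDropped <- c(genes = nrow(ge) + nrow(pa) - 2L * length(genes),
                  samples = ncol(ge) + ncol(pa) - 2L * length(samples))
    if (dropIncomplete) {
        keep <- stats::complete.cases(geA) & stats::complete.cases(paA)
        if (!all(keep)) {
            message(sum(!keep), " gene(s) dropped for missing values")
            geA <- geA[keep, , drop = FALSE]
            paA <- paA[keep, , drop = FALSE]
        }
    }
    if (any(nDropped > 0L))
        message("alignment dropped ", nDropped[["genes"]], " gene id(s) and ",
                nDropped[["samples"]], " sample id(s) outside the intersection")
    list(ge = geA, pa = paA, dropped = nDropped)
}

#' Per-gene z-score normalization, optionally within sample groups
#'
#' Standardizes every gene row to mean 0 and SD 1 (population SD over the
#' row, sample SD via `stats::sd`), computed within each sample group
#' separately when `colGroups` is given — the standard preparation before
#' contrasting platforms measured on different cohorts. Zero-variance rows
#' map to 0 with a warning.
#'
#' @param m numeric matrix (genes x samples).
#' @param colGroups optional group labels, named by column id (or unnamed,
#'   one per column); when given, normalization is per group.
#' @return The normalized matrix.
#' @export
zscoreNormalize <- function(m, colGroups = NULL) {
    stopifnot(is.matrix(m))
    if (is.null(colGroups)) {
        grp <- rep("all", ncol(m))
    } else {
        if (is.null(names(colGroups))) {
            if (length(colGroups) != ncol(m))
                stop("unnamed 'colGroups' must have one label per column")
            names(colGroups) <- colnames(m)
        }
        if (!all(colnames(m) %in% names(colGroups)))
            stop("every column needs a group label")
        grp <- as.character(colGroups[colnames(m)])
    }
    out <- m
    flat <- 0L
    for (g in unique(grp)) {
        ix <- which(grp == g)
        sub <- m[, ix, drop = FALSE]
        mu <- rowMeans(sub)
        sdv <- apply(sub, 1L, stats::sd)
        zero <- sdv <= .Machine$double.eps
        flat <- flat + sum(zero)
        sdv[zero] <- 1
        z <- (sub - mu) / sdv
        z[zero, ] <- 0
        out[, ix] <- z
    }
    if (flat > 0L)
        warning(flat, " zero-variance gene/group row(s) set to 0")
    out
}

#' mRNA-to-protein ratio matrix
#'
#' Contrasts aligned, normalized mRNA (`ge`) and protein (`pa`) matrices.
#' The default `"difference"` mode returns `ge - pa`, the log-ratio
#' analogue appropriate for z-scored (or log-scale) inputs and the
#' numerically stable choice. `"quotient"` returns the literal `ge / pa`,
#' masking cells whose denominator is below `1e-6` in absolute value and
#' imputing them with the gene's (per-group) mean ratio; more than 50%
#' masked cells is an error advising difference mode.
#'
#' @param ge,pa aligned numeric matrices with identical dimnames (see
#'   [alignOmics()]).
#' @param mode `"difference"` (default) or `"quotient"`.
#' @param colGroups optional group labels used for quotient-mode
#'   imputation.
#' @return The ratio matrix, same shape and dimnames as the inputs.
#' @export
ratioMatrix <- function(ge, pa, mode = c("difference", "quotient"),
                        colGroups = NULL) {
    mode <- match.arg(mode)
    stopifnot(is.matrix(ge), is.matrix(pa))
    if (!identical(dimnames(ge), dimnames(pa)) || !identical(dim(ge), dim(pa)))
        stop("'ge' and 'pa' must be aligned (identical dimnames); see alignOmics()")
    if (mode == "difference") return(ge - pa)
    masked <- abs(pa) < 1e-6
    if (mean(masked) > 0.5)
        stop("more than 50% of denominators are near zero; ",
             "use mode = \"difference\"")
    r <- ge / pa
    r[masked] <- NA_real_
    if (any(masked)) {
        grp <- if (is.null(colGroups)) rep("all", ncol(r)) else {
            if (is.null(names(colGroups)))
                names(colGroups) <- colnames(r)
            as.character(colGroups[colnames(r)])
        }
        for (g in unique(grp)) {
            ix <- which(grp == g)
            sub <- r[, ix, drop = FALSE]
            mu <- rowMeans(sub, na.rm = TRUE)
            mu[!is.finite(mu)] <- 0
            bad <- which(is.na(sub), arr.ind = TRUE)
            if (nrow(bad)) sub[bad] <- mu[bad[, 1L]]
            r[, ix] <- sub
        }
        message(sum(masked), " near-zero denominator cell(s) imputed by the ",
                "gene's group mean ratio")
    }
    r
}
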