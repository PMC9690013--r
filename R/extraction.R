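## Bicluster extraction from the posterior membership probability matrix:
## threshold -> density sort -> seed-anchored greedy growth.

#' Binary membership matrix
#'
#' The thresholded posterior membership matrix together with the row and
#' column permutations applied by [sortMembership()] (identity until
#' sorting) and the column group labels, if any.
#'
#' @slot u 0/1 integer matrix with dimnames.
#' @slot rowOrder,colOrder integer permutations mapping sorted positions
#'   to original indices (`u_sorted = u_original[rowOrder, colOrder]`).
#' @slot colGroups character or NULL; group label per *sorted* column.
#' @export
setClass("BinaryMembership",
    representation(u = "matrix", rowOrder = "integer", colOrder = "integer",
                   colGroups = "characterOrNULL"))

setValidity("BinaryMembership", function(object) {
    msg <- character()
    if (!all(object@u %in% c(0L, 1L)))
        msg <- c(msg, "'u' must be 0/1")
    if (!identical(sort(object@rowOrder), seq_len(nrow(object@u))) ||
        !identical(sort(object@colOrder), seq_len(ncol(object@u))))
        msg <- c(msg, "'rowOrder'/'colOrder' must be valid permutations")
    if (length(msg)) msg else TRUE
})

#' Threshold the posterior membership matrix
#'
#' `u[i, j]` is 1 iff `gamma[i, j] > ac` (strictly); values exactly at the
#' threshold map to 0.
#'
#' @param gamma matrix of posterior membership probabilities in \[0,1\].
#' @param ac membership probability threshold in (0,1); default 0.8.
#' @return A [BinaryMembership-class] with identity orderings.
#' @export
binarizeGamma <- function(gamma, ac = 0.8) {
    stopifnot(is.matrix(gamma), ac > 0, ac < 1)
    if (any(gamma < 0 | gamma > 1))
        stop("'gamma' entries must lie in [0,1]")
    u <- (gamma > ac) + 0L
    storage.mode(u) <- "integer"
    dimnames(u) <- dimnames(gamma)
    new("BinaryMembership", u = u, rowOrder = seq_len(nrow(u)),
        colOrder = seq_len(ncol(u)), colGroups = NULL)
}

#' Sort a binary membership matrix toward its dense corner
#'
#' Rows are sorted by their number of 1s, ascending, so the densest rows
#' end up at the bottom; columns likewise, so the dense corner is
#' bottom-right. When sample groups are supplied the columns are sorted
#' independently within each group and the groups stay contiguous (in
#' order of first appearance). Ties preserve the original order.
#'
#' @param bm a [BinaryMembership-class] (typically from [binarizeGamma()]).
#' @param colGroups optional character vector of group labels, named by
#'   column identifier (or unnamed, one per column).
#' @return The sorted [BinaryMembership-class]; `rowOrder`/`colOrder`
#'   record the permutations.
#' @export
sortMembership <- function(bm, colGroups = NULL) {
    u <- bm@u
    if (!is.null(colGroups)) {
        if (is.null(names(colGroups))) {
            if (length(colGroups) != ncol(u))
                stop("unnamed 'colGroups' must have one label per column")
            names(colGroups) <- colnames(u)
        }
        missingCols <- setdiff(colnames(u), names(colGroups))
        if (length(missingCols))
            stop("no group label for column(s): ",
                 paste(missingCols, collapse = ", "))
        grp <- as.character(colGroups[colnames(u)])
    } else {
        grp <- rep("all", ncol(u))
    }
    rowOrder <- order(rowSums(u))           # stable: ties keep original order
    colOrder <- integer(0)
    for (g in unique(grp)) {                 # groups contiguous, by appearance
        idx <- which(grp == g)
        colOrder <- c(colOrder, idx[order(colSums(u)[idx])])
    }
    new("BinaryMembership",
        u = u[rowOrder, colOrder, drop = FALSE],
        rowOrder = bm@rowOrder[rowOrder],
        colOrder = bm@colOrder[colOrder],
        colGroups = grp[colOrder])
}

## Resolve a user seed to sorted coordinates. seed may be NULL (automatic:
## the 1-cell maximizing row ones + column ones, preferring the dense
## corner on ties), a length-2 vector of original indices, or character
## identifiers (a single gene id is paired with that row's densest cell).
.resolveSeed <- function(bm, seed, gamma = NULL) {
    u <- bm@u
    if (is.null(seed)) {
        if (!any(u == 1L)) return(NULL)
        score <- outer(rowSums(u), colSums(u), `+`)
        score[u == 0L] <- -Inf
        best <- which(score == max(score), arr.ind = TRUE)
        pick <- best[order(best[, 1L] + best[, 2L], best[, 2L],
                           decreasing = TRUE)[1L], ]
        return(c(pick[[1L]], pick[[2L]]))
    }
    if (is.character(seed)) {
        si <- match(seed[1L], rownames(u))
        if (is.na(si)) stop("seed row '", seed[1L], "' not found")
        if (length(seed) >= 2L) {
            sj <- match(seed[2L], colnames(u))
            if (is.na(sj)) stop("seed column '", seed[2L], "' not found")
        } else {
            ## gene-of-interest seed: pair with the row's highest-membership
            ## column (by gamma if available, else by the row's 1s)
            rowVals <- if (!is.null(gamma))
                gamma[bm@rowOrder[si], bm@colOrder] else u[si, ]
            sj <- which.max(rowVals)
        }
        return(c(si, sj))
    }
    seed <- as.integer(seed)
    if (length(seed) != 2L) stop("numeric seed must be c(row, col)")
    si <- match(seed[1L], bm@rowOrder)
    sj <- match(seed[2L], bm@colOrder)
    if (is.na(si) || is.na(sj)) stop("seed indices out of range")
    c(si, sj)
}

#' Grow a bicluster from a seed cell
#'
#' Starting at the seed, alternately attempts to extend the selected row
#' interval and the selected column run(s) one line at a time along the
#' sorted density order, always trying the frontier line with the highest
#' fraction of 1s inside the current span. A candidate line is admitted
#' iff (i) the overall fraction of 1s of the enlarged submatrix stays at
#' least `pAve` and (ii) the candidate line itself is at least
#' `min(pAve, 0.5)` ones within the current span, so a mostly-empty
#' background line can never dilute an already-large bicluster. Growth
#' stops when neither axis can extend. Row selections are contiguous in
#' the sorted arrangement; with column groups, the selection within each
#' group is contiguous.
#'
#' @param bm a sorted [BinaryMembership-class] (see [sortMembership()]).
#' @param seed seed specification (see [extractBiclusters()]); `NULL` for
#'   the automatic densest-cell anchor.
#' @param pAve minimum fraction of 1s in the reported bicluster, in (0,1\].
#' @param gamma optional posterior matrix (original orientation) used to
#'   resolve gene-only seeds and report mean membership.
#' @return A [Bicluster-class], or `NULL` (empty-result signal) when the
#'   seed cell is 0 or no 1s remain.
#' @export
growFromSeed <- function(bm, seed = NULL, pAve = 0.95, gamma = NULL) {
    stopifnot(pAve > 0, pAve <= 1)
    u <- bm@u
    I <- nrow(u); J <- ncol(u)
    sd0 <- .resolveSeed(bm, seed, gamma)
    if (is.null(sd0)) return(NULL)
    si <- sd0[1L]; sj <- sd0[2L]
    if (si < 1L || si > I || sj < 1L || sj > J) stop("seed out of bounds")
    if (u[si, sj] != 1L) return(NULL)
    grp <- if (is.null(bm@colGroups)) rep("all", J) else bm@colGroups
    groups <- unique(grp)
    gIdx <- lapply(groups, function(g) which(grp == g))  # contiguous blocks
    ## state: row interval, per-group column interval (NA = empty)
    rLo <- si; rHi <- si
    cLo <- cHi <- rep(NA_integer_, length(groups))
    sg <- which(vapply(gIdx, function(ix) sj %in% ix, logical(1)))
    cLo[sg] <- cHi[sg] <- sj
    lineFloor <- min(pAve, 0.5)
    selCols <- function() {
        out <- integer(0)
        for (k in seq_along(groups))
            if (!is.na(cLo[k])) out <- c(out, cLo[k]:cHi[k])
        out
    }
    repeat {
        cols <- selCols()
        nSel <- (rHi - rLo + 1L) * length(cols)
        ones <- sum(u[rLo:rHi, cols, drop = FALSE])
        ## --- row attempt ---
        addedRow <- FALSE
        cand <- c(if (rLo > 1L) rLo - 1L, if (rHi < I) rHi + 1L)
        if (length(cand)) {
            f <- vapply(cand, function(r) mean(u[r, cols]), numeric(1))
            best <- cand[order(-f, -cand)][1L]
            fBest <- max(f)
            newOnes <- ones + fBest * length(cols)
            if (fBest >= lineFloor &&
                newOnes / (nSel + length(cols)) >= pAve) {
                if (best < rLo) rLo <- best else rHi <- best
                addedRow <- TRUE
                ones <- as.integer(round(newOnes))
                nSel <- nSel + length(cols)
            }
        }
        ## --- column attempt ---
        addedCol <- FALSE
        nRows <- rHi - rLo + 1L
        candPos <- integer(0); candGrp <- integer(0)
        for (k in seq_along(groups)) {
            ix <- gIdx[[k]]
            if (is.na(cLo[k])) {
                candPos <- c(candPos, ix[length(ix)])  # group's densest column
                candGrp <- c(candGrp, k)
            } else {
                if (cLo[k] > ix[1L]) {
                    candPos <- c(candPos, cLo[k] - 1L); candGrp <- c(candGrp, k)
                }
                if (cHi[k] < ix[length(ix)]) {
                    candPos <- c(candPos, cHi[k] + 1L); candGrp <- c(candGrp, k)
                }
            }
        }
        if (length(candPos)) {
            f <- vapply(candPos, function(cc) mean(u[rLo:rHi, cc]), numeric(1))
            ord <- order(-f, -candPos)
            best <- candPos[ord[1L]]; bestG <- candGrp[ord[1L]]
            fBest <- f[ord[1L]]
            newOnes <- ones + fBest * nRows
            if (fBest >= lineFloor && newOnes / (nSel + nRows) >= pAve) {
                if (is.na(cLo[bestG])) {
                    cLo[bestG] <- cHi[bestG] <- best
                } else if (best < cLo[bestG]) cLo[bestG] <- best
                else cHi[bestG] <- best
                addedCol <- TRUE
            }
        }
        if (!addedRow && !addedCol) break
    }
    rows <- rLo:rHi
    cols <- selCols()
    sub <- u[rows, cols, drop = FALSE]
    origRows <- bm@rowOrder[rows]
    origCols <- bm@colOrder[cols]
    mm <- if (!is.null(gamma)) mean(gamma[origRows, origCols]) else NA_real_
    Bicluster(rows = rownames(u)[rows], cols = colnames(u)[cols],
              meanMembership = mm, onesFraction = mean(sub))
}

#' Extract biclusters from a fitted model
#'
#' Runs the full extraction pipeline: threshold the posterior membership
#' matrix at `ac` ([binarizeGamma()]), sort rows and columns toward the
#' dense corner ([sortMembership()]), and grow a bicluster from the seed
#' ([growFromSeed()]). For subsequent biclusters (up to `maxBiclusters`)
#' the cells of previously extracted biclusters are masked to 0, the
#' matrix is re-sorted, and the seed resets to the densest remaining cell;
#' extraction stops early when nothing qualifying remains.
#'
#' @param fit a [BicFit-class], or directly a posterior membership matrix
#'   (values in \[0,1\], with dimnames).
#' @param Y optional data matrix the fit was computed on. When given and
#'   `maxBiclusters > 1`, each subsequent round refits the mixture on the
#'   matrix with the rows and columns of previously extracted biclusters
#'   removed — the factorized row/column posterior of a single fit can
#'   only describe one block, so further biclusters live in the remaining
#'   data. Without `Y`, subsequent rounds reuse the same posterior with
#'   extracted cells masked.
#' @param ac membership probability threshold in (0,1); default 0.8.
#' @param pAve minimum fraction of 1s in a reported bicluster; default 0.95.
#' @param seed anchor for the first bicluster: `NULL` (automatic, the
#'   densest 1-cell), `c(geneId, sampleId)`, a single gene id (paired with
#'   that gene's highest-membership sample), or `c(rowIndex, colIndex)`.
#' @param maxBiclusters cap on sequential extractions; default 1.
#' @param colGroups optional sample group labels (sorting is then applied
#'   within each group separately; a warning is raised for a bicluster
#'   whose samples all come from one group).
#' @param maskLines if `TRUE`, whole rows and columns of an extracted
#'   bicluster are excluded from later rounds instead of only its cells.
#' @return A [BiclusterSet-class].
#' @examples
#' sim <- simConstantBicluster(1, nRow = 60, nCol = 80,
#'                             blockRows = 10, blockCols = 10)
#' fit <- fitBicMixture(simValues(sim))
#' extractBiclusters(fit, ac = 0.8, pAve = 0.95)
#' @export
extractBiclusters <- function(fit, Y = NULL, ac = 0.8, pAve = 0.95,
                              seed = NULL, maxBiclusters = 1L,
                              colGroups = NULL, maskLines = FALSE) {
    gamma <- if (is(fit, "BicFit")) posteriorGamma(fit) else fit
    stopifnot(is.matrix(gamma))
    if (is.null(rownames(gamma))) rownames(gamma) <- paste0("g", seq_len(nrow(gamma)))
    if (is.null(colnames(gamma))) colnames(gamma) <- paste0("s", seq_len(ncol(gamma)))
    if (!is.null(colGroups) && is.null(names(colGroups)))
        colGroups <- stats::setNames(colGroups, colnames(gamma))
    refit <- !is.null(Y) && maxBiclusters > 1L
    if (!is.null(Y)) {
        if (!identical(dim(Y), dim(gamma)))
            stop("'Y' dimensions do not match the fit")
        if (is.null(dimnames(Y))) dimnames(Y) <- dimnames(gamma)
    }
    gammaK <- gamma
    uWork <- binarizeGamma(gammaK, ac)@u
    found <- list()
    for (k in seq_len(maxBiclusters)) {
        if (!any(uWork == 1L)) break
        bmK <- new("BinaryMembership", u = uWork,
                   rowOrder = seq_len(nrow(uWork)),
                   colOrder = seq_len(ncol(uWork)), colGroups = NULL)
        grpK <- if (!is.null(colGroups)) colGroups[colnames(uWork)] else NULL
        bmK <- sortMembership(bmK, colGroups = grpK)
        b <- growFromSeed(bmK, seed = if (k == 1L) seed else NULL,
                          pAve = pAve, gamma = gammaK)
        if (is.null(b)) break
        found[[length(found) + 1L]] <- b
        if (!is.null(colGroups) && length(unique(colGroups[b@cols])) < 2L)
            warning("bicluster ", length(found),
                    " contains samples from a single group")
        if (length(found) == maxBiclusters) break
        if (refit) {
            ## the factorized posterior of one fit describes one block:
            ## look for the next bicluster in the remaining rows/columns
            usedR <- unique(unlist(lapply(found, biclusterRows)))
            usedC <- unique(unlist(lapply(found, biclusterCols)))
            keepR <- setdiff(rownames(Y), usedR)
            keepC <- setdiff(colnames(Y), usedC)
            if (length(keepR) < 2L || length(keepC) < 2L) break
            sub <- fitBicMixture(Y[keepR, keepC])
            gammaK <- posteriorGamma(sub)
            uWork <- binarizeGamma(gammaK, ac)@u
        } else {
            ri <- match(b@rows, rownames(gammaK))
            ci <- match(b@cols, colnames(gammaK))
            if (maskLines) {
                uWork[ri, ] <- 0L
                uWork[, ci] <- 0L
            } else {
                uWork[ri, ci] <- 0L
            }
        }
    }
    BiclusterSet(found, provenance = list(
        ac = ac, pAve = pAve, seed = seed, maxBiclusters = maxBiclusters,
        maskLines = maskLines, refit = refit,
        nIter = if (is(fit, "BicFit")) fit@nIter else NA_integer_,
        converged = if (is(fit, "BicFit")) fit@converged else NA))
}
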