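## Synthetic benchmark generators with known planted biclusters.
## Defaults reproduce the standard benchmark conditions: 200 x 300
## matrices with one embedded block (25 x 25 constant, or 70 x 70
## scale-shift). All draws happen inside a seed scope, so a given seed
## reproduces the matrix bit-exactly without touching the caller's RNG.

.simNames <- function(I, J) list(paste0("g", seq_len(I)), paste0("s", seq_len(J)))

## Seed-derived block position: the block offset is drawn first, so its
## placement is deterministic per seed but not always top-left.
.blockAt <- function(n, k) sample.int(n - k + 1L, 1L) + seq_len(k) - 1L

#' Constant-pattern benchmark: N(10,1) block in N(4,1) background
#'
#' A `nRow x nCol` matrix of i.i.d. `N(bgMean, bgSd^2)` background with a
#' `blockRows x blockCols` block overwritten by i.i.d.
#' `N(blockMean, blockSd^2)`, at a seed-derived position.
#'
#' @param seed integer RNG seed; same seed, same matrix, bit-exactly.
#' @param nRow,nCol matrix size (defaults 200 x 300).
#' @param blockRows,blockCols planted block size (defaults 25 x 25).
#' @param bgMean,bgSd background distribution (defaults 4, 1).
#' @param blockMean,blockSd block distribution (defaults 10, 1).
#' @return A [BicSimulation-class].
#' @examples
#' sim <- simConstantBicluster(7)
#' dim(simValues(sim))
#' @export
simConstantBicluster <- function(seed, nRow = 200L, nCol = 300L,
                                 blockRows = 25L, blockCols = 25L,
                                 bgMean = 4, bgSd = 1,
                                 blockMean = 10, blockSd = 1) {
    stopifnot(blockRows <= nRow, blockCols <= nCol)
    seed <- as.integer(seed)
    out <- withr::with_seed(seed, {
        rows <- .blockAt(nRow, blockRows)
        cols <- .blockAt(nCol, blockCols)
        Y <- matrix(stats::rnorm(nRow * nCol, bgMean, bgSd), nRow, nCol)
        Y[rows, cols] <- stats::rnorm(blockRows * blockCols, blockMean, blockSd)
        list(Y = Y, rows = rows, cols = cols)
    })
    dimnames(out$Y) <- .simNames(nRow, nCol)
    new("BicSimulation", values = out$Y, colGroups = NULL,
        trueRows = as.integer(out$rows), trueCols = as.integer(out$cols), regime = "constant",
        params = list(nRow = nRow, nCol = nCol, blockRows = blockRows,
                      blockCols = blockCols, bgMean = bgMean, bgSd = bgSd,
                      blockMean = blockMean, blockSd = blockSd),
        seed = seed)
}

#' Row scale-shift benchmark
#'
#' Background i.i.d. `N(0,1)`; a `blockRows x blockCols` block whose rows
#' are affine images `a_r + b_r * R` of one shared base row
#' `R ~ N(0,1)^blockCols`, with one shift `a_r ~ N(5,1)` and one scale
#' `b_r ~ N(5,1)` drawn per bicluster row. No independent cell noise is
#' added inside the block, so block rows are exactly collinear.
#'
#' @inheritParams simConstantBicluster
#' @param blockRows,blockCols planted block size (defaults 70 x 70).
#' @param shiftMean,shiftSd,scaleMean,scaleSd distributions of the per-row
#'   shift and scale draws (defaults N(5,1) for both).
#' @return A [BicSimulation-class].
#' @export
simRowScaleShift <- function(seed, nRow = 200L, nCol = 300L,
                             blockRows = 70L, blockCols = 70L,
                             shiftMean = 5, shiftSd = 1,
                             scaleMean = 5, scaleSd = 1) {
    stopifnot(blockRows <= nRow, blockCols <= nCol)
    seed <- as.integer(seed)
    out <- withr::with_seed(seed, {
        rows <- .blockAt(nRow, blockRows)
        cols <- .blockAt(nCol, blockCols)
        Y <- matrix(stats::rnorm(nRow * nCol), nRow, nCol)
        base <- stats::rnorm(blockCols)
        a <- stats::rnorm(blockRows, shiftMean, shiftSd)
        b <- stats::rnorm(blockRows, scaleMean, scaleSd)
        Y[rows, cols] <- a + outer(b, base)  # row r: a_r + b_r * R
        list(Y = Y, rows = rows, cols = cols)
    })
    dimnames(out$Y) <- .simNames(nRow, nCol)
    new("BicSimulation", values = out$Y, colGroups = NULL,
        trueRows = as.integer(out$rows), trueCols = as.integer(out$cols), regime = "row_scale_shift",
        params = list(nRow = nRow, nCol = nCol, blockRows = blockRows,
                      blockCols = blockCols, shiftMean = shiftMean,
                      shiftSd = shiftSd, scaleMean = scaleMean,
                      scaleSd = scaleSd),
        seed = seed)
}

#' Column scale-shift benchmark
#'
#' Transpose-symmetric to [simRowScaleShift()]: one shared base column,
#' and each bicluster column is `a_c + b_c * R`.
#'
#' @inheritParams simRowScaleShift
#' @return A [BicSimulation-class].
#' @export
simColScaleShift <- function(seed, nRow = 200L, nCol = 300L,
                             blockRows = 70L, blockCols = 70L,
                             shiftMean = 5, shiftSd = 1,
                             scaleMean = 5, scaleSd = 1) {
    stopifnot(blockRows <= nRow, blockCols <= nCol)
    seed <- as.integer(seed)
    out <- withr::with_seed(seed, {
        rows <- .blockAt(nRow, blockRows)
        cols <- .blockAt(nCol, blockCols)
        Y <- matrix(stats::rnorm(nRow * nCol), nRow, nCol)
        base <- stats::rnorm(blockRows)
        a <- stats::rnorm(blockCols, shiftMean, shiftSd)
        b <- stats::rnorm(blockCols, scaleMean, scaleSd)
        Y[rows, cols] <- outer(base, b) + rep(a, each = blockRows)
        list(Y = Y, rows = rows, cols = cols)
    })
    dimnames(out$Y) <- .simNames(nRow, nCol)
    new("BicSimulation", values = out$Y, colGroups = NULL,
        trueRows = as.integer(out$rows), trueCols = as.integer(out$cols), regime = "col_scale_shift",
        params = list(nRow = nRow, nCol = nCol, blockRows = blockRows,
                      blockCols = blockCols, shiftMean = shiftMean,
                      shiftSd = shiftSd, scaleMean = scaleMean,
                      scaleSd = scaleSd),
        seed = seed)
}

#' Two-group ratio fixture with a planted cross-group bicluster
#'
#' Emulates an mRNA/protein ratio matrix over two sample cohorts (e.g.
#' tumours and cell lines, groups "A" and "B"): a z-score-scale background
#' `N(0,1)` with a planted gene x sample block spanning columns from both
#' groups. Block cells are a grand elevation plus a per-gene effect, a
#' group offset (+`groupGap/2` in A, -`groupGap/2` in B, so the group-A
#' block mean exceeds the group-B block mean), and cell noise.
#'
#' @param seed integer RNG seed.
#' @param nGenes number of genes (default 150).
#' @param nGroupA,nGroupB samples per group (defaults 40, 40).
#' @param blockGenes planted module size in genes (default 20).
#' @param blockPerGroup planted columns taken from each group (default 12).
#' @param blockMean grand elevation of the module on the ratio scale
#'   (default 2.5).
#' @param geneSd,groupGap,noiseSd per-gene effect SD (0.5), A-minus-B
#'   offset (1), and cell noise SD (0.3).
#' @return A [BicSimulation-class] with `colGroups` set.
#' @export
simTwoGroupRatio <- function(seed, nGenes = 150L, nGroupA = 40L,
                             nGroupB = 40L, blockGenes = 20L,
                             blockPerGroup = 12L, blockMean = 2.5,
                             geneSd = 0.5, groupGap = 1, noiseSd = 0.3) {
    if (blockGenes >= nGenes || blockPerGroup >= min(nGroupA, nGroupB))
        stop("planted block dimensions must be smaller than the matrix")
    seed <- as.integer(seed)
    J <- nGroupA + nGroupB
    out <- withr::with_seed(seed, {
        rows <- .blockAt(nGenes, blockGenes)
        colsA <- .blockAt(nGroupA, blockPerGroup)
        colsB <- nGroupA + .blockAt(nGroupB, blockPerGroup)
        Y <- matrix(stats::rnorm(nGenes * J), nGenes, J)
        geneEff <- stats::rnorm(blockGenes, 0, geneSd)
        cols <- c(colsA, colsB)
        offs <- rep(c(groupGap / 2, -groupGap / 2), each = blockPerGroup)
        blk <- blockMean + geneEff +
            rep(offs, each = blockGenes) +
            stats::rnorm(blockGenes * length(cols), 0, noiseSd)
        Y[rows, cols] <- blk
        list(Y = Y, rows = rows, cols = cols)
    })
    dimnames(out$Y) <- .simNames(nGenes, J)
    groups <- stats::setNames(rep(c("A", "B"), c(nGroupA, nGroupB)),
                              colnames(out$Y))
    new("BicSimulation", values = out$Y, colGroups = groups,
        trueRows = as.integer(out$rows), trueCols = as.integer(sort(out$cols)),
        regime = "two_group_ratio",
        params = list(nGenes = nGenes, nGroupA = nGroupA, nGroupB = nGroupB,
                      blockGenes = blockGenes, blockPerGroup = blockPerGroup,
                      blockMean = blockMean, geneSd = geneSd,
                      groupGap = groupGap, noiseSd = noiseSd),
        seed = seed)
}

#' Write a simulated dataset to disk
#'
#' Writes the matrix as TSV plus a JSON ground-truth sidecar (regime,
#' parameters, true rows/columns, seed, and groups if any).
#'
#' @param sim a [BicSimulation-class].
#' @param matrixPath,truthPath output file paths.
#' @return Invisibly, the two paths.
#' @export
writeSimulation <- function(sim, matrixPath, truthPath) {
    writeExpressionMatrix(sim@values, matrixPath)
    truth <- list(regime = sim@regime, seed = sim@seed, params = sim@params,
                  true_rows = rownames(sim@values)[sim@trueRows],
                  true_cols = colnames(sim@values)[sim@trueCols],
                  col_groups = as.list(sim@colGroups))
    jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(c(matrixPath, truthPath))
}
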