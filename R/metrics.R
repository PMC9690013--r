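## Bicluster comparison scores: Jaccard overlap, recovery, relevance.
## "Elements" are cells (row, column) pairs, so a bicluster's cell set is
## the Cartesian product of its row and column sets.

.cellCount <- function(b) length(b@rows) * length(b@cols)

.cellIntersection <- function(b1, b2) {
    length(intersect(b1@rows, b2@rows)) * length(intersect(b1@cols, b2@cols))
}

#' Jaccard overlap of two biclusters
#'
#' \eqn{|cells(b_1) \cap cells(b_2)| / |cells(b_1) \cup cells(b_2)|}:
#' 1 iff the cell sets are identical, 0 iff they are disjoint.
#'
#' @param b1,b2 [Bicluster-class] objects over the same matrix id space.
#' @return A score in \[0,1\].
#' @examples
#' b1 <- Bicluster(c("g1", "g2"), c("s1", "s2"))
#' b2 <- Bicluster(c("g2", "g3"), c("s2", "s3"))
#' jaccardIndex(b1, b2)  # 1 cell shared of 7 -> 1/7
#' @export
jaccardIndex <- function(b1, b2) {
    n1 <- .cellCount(b1); n2 <- .cellCount(b2)
    if (n1 == 0L || n2 == 0L) stop("cannot score an empty bicluster")
    ix <- .cellIntersection(b1, b2)
    ix / (n1 + n2 - ix)
}

.setScore <- function(from, against) {
    ## mean over 'from' of the best Jaccard match in 'against'
    mean(vapply(biclusters(from), function(b1) {
        max(vapply(biclusters(against), function(b2) jaccardIndex(b1, b2),
                   numeric(1)))
    }, numeric(1)))
}

#' Recovery score of a result set against the truth
#'
#' The average, over true biclusters, of the best Jaccard match among the
#' reported biclusters: the fraction of the truth that was recovered. An
#' empty result set scores 0.
#'
#' @param truth a non-empty [BiclusterSet-class] of true biclusters.
#' @param result a [BiclusterSet-class] of reported biclusters.
#' @return A score in \[0,1\].
#' @export
recoveryScore <- function(truth, result) {
    if (length(truth) == 0L) stop("'truth' must be non-empty")
    if (length(result) == 0L) return(0)
    .setScore(truth, result)
}

#' Relevance score of a result set against the truth
#'
#' The average, over reported biclusters, of the best Jaccard match among
#' the true biclusters: a precision analogue. Identically equal to
#' `recoveryScore(result, truth)`. An empty result set scores 0.
#'
#' @inheritParams recoveryScore
#' @return A score in \[0,1\].
#' @export
relevanceScore <- function(truth, result) {
    if (length(truth) == 0L) stop("'truth' must be non-empty")
    if (length(result) == 0L) return(0)
    .setScore(result, truth)
}
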