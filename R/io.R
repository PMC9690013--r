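## Reading and writing matrices, group files and bicluster reports.

.delimFor <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the delimiter is chosen from the file extension (`.csv`
#' is comma, anything else tab). Empty cells become `NA` and are
#' reported; ragged rows and duplicate identifiers are errors.
#'
#' @param path input file.
#' @return A numeric matrix with dimnames.
#' @export
readExpressionMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- .delimFor(path)
    df <- tryCatch(
        utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "")),
        error = function(e) stop("parse error in '", path, "': ",
                                 conditionMessage(e)))
    ids <- as.character(df[[1L]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate gene id(s) in '", path, "': ",
             paste(dup, collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample id(s) in '", path, "'")
    nMiss <- sum(is.na(m))
    if (nMiss > 0L) message(nMiss, " missing cell(s) in '", path, "'")
    m
}

#' Write an expression matrix as TSV/CSV
#'
#' Inverse of [readExpressionMatrix()]; values are written with 17
#' significant digits so numeric round trips are exact.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file; extension selects the delimiter.
#' @param idColumn header for the identifier column (default `"gene"`).
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(m, path, idColumn = "gene") {
    stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
    sep <- .delimFor(path)
    chr <- format(m, digits = 17, trim = TRUE, scientific = FALSE)
    df <- data.frame(rownames(m), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c(idColumn, colnames(m))
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a two-column sample group file
#'
#' @param path TSV/CSV with columns sample id and group label (no header
#'   required; a header line is detected and skipped if its first field is
#'   `"sample"`).
#' @return A named character vector, sample id -> group.
#' @export
readSampleGroups <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, header = FALSE, sep = .delimFor(path),
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("group file needs two columns: sample, group")
    if (tolower(df[1L, 1L]) == "sample") df <- df[-1L, , drop = FALSE]
    stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a bicluster report
#'
#' Writes the extracted biclusters as JSON (rows, columns, summary
#' statistics, and the extraction configuration echo) and, optionally, as
#' a flat TSV with one line per bicluster member cell.
#'
#' @param bset a [BiclusterSet-class].
#' @param jsonPath output JSON path.
#' @param tsvPath optional output TSV path.
#' @return Invisibly, the JSON path.
#' @export
writeBiclusterReport <- function(bset, jsonPath, tsvPath = NULL) {
    report <- list(
        n_biclusters = length(bset),
        provenance = bset@provenance,
        biclusters = lapply(biclusters(bset), function(b) list(
            rows = b@rows, cols = b@cols,
            mean_membership = b@meanMembership,
            ones_fraction = b@onesFraction)))
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    if (!is.null(tsvPath)) {
        rows <- do.call(rbind, lapply(seq_len(length(bset)), function(k) {
            b <- bset[[k]]
            expand.grid(bicluster = k, gene = b@rows, sample = b@cols,
                        stringsAsFactors = FALSE)
        }))
        if (is.null(rows))
            rows <- data.frame(bicluster = integer(0), gene = character(0),
                               sample = character(0))
        utils::write.table(rows, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(jsonPath)
}

## Tiny polynomial rolling hash of a character representation; used to
## fingerprint a run configuration in output files.
.configHash <- function(x) {
    bytes <- utf8ToInt(paste(deparse(x), collapse = ";"))
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", as.integer(h))
}
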