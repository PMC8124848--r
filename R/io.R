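#' Write a features-by-samples matrix as TSV
#'
#' First column holds feature ids under \code{idColumn}; the header row
#' carries sample ids; numeric values keep full double precision.
#'
#' @param mat matrix with dimnames.
#' @param file output path.
#' @param idColumn name for the id column.
#' @export
writeMatrixTSV <- function(mat, file, idColumn = "feature") {
    df <- data.frame(rownames(mat), mat, check.names = FALSE,
                     row.names = NULL)
    names(df)[1L] <- idColumn
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read a features-by-samples TSV matrix
#'
#' @param file path; first column = feature ids, header = sample ids.
#' @param integer coerce values to integer counts.
#' @return numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(file, integer = FALSE) {
    df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) stop("duplicate feature ids in ", file)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (integer) storage.mode(m) <- "integer" else storage.mode(m) <- "double"
    rownames(m) <- ids
    m
}

#' Read a sample design TSV
#'
#' Columns \code{sample}, \code{genotype}, \code{condition} (and
#' optionally \code{replicate}) are required; genotype and condition
#' values are validated.
#'
#' @param file path.
#' @return data.frame.
#' @export
readDesignTSV <- function(file) {
    d <- read.delim(file, stringsAsFactors = FALSE)
    need <- c("sample", "genotype", "condition")
    if (!all(need %in% names(d)))
        stop("design file needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(d$sample)) stop("duplicate sample ids in design")
    if (!all(d$genotype %in% c("A", "B")))
        stop("genotype must be 'A' or 'B'")
    if (!all(d$condition %in% c("minusN", "plusN")))
        stop("condition must be 'minusN' or 'plusN'")
    d
}
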