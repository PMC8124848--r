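#' Counts per million
#'
#' \code{cpm[g, s] = counts[g, s] / libSize[s] * 1e6}, so every column sums
#' to one million.
#'
#' @param counts integer matrix (genes x samples) or a
#'   \linkS4class{SummarizedExperiment} with a \code{"counts"} assay.
#' @param libSizes per-sample library sizes; defaults to column sums.
#' @return matrix of CPM values with the input dimnames.
#' @examples
#' computeCPM(matrix(c(10, 90), 2, 1, dimnames = list(NULL, "s1")),
#'            libSizes = 100)
#' @export
computeCPM <- function(counts, libSizes = NULL) {
    counts <- asCountMatrix(counts)
    if (is.null(libSizes)) libSizes <- colSums(counts)
    if (length(libSizes) != ncol(counts))
        stop("one library size per sample is required")
    bad <- which(libSizes <= 0)
    if (length(bad))
        stop("zero or negative library size for sample(s): ",
             paste(colnames(counts)[bad], collapse = ", "))
    t(t(counts) / libSizes) * 1e6
}

asCountMatrix <- function(counts) {
    if (is(counts, "SummarizedExperiment"))
        counts <- assay(counts, "counts")
    if (!is.matrix(counts)) counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    if (anyDuplicated(rownames(counts)))
        stop("duplicate gene ids in count matrix")
    counts
}

#' Filter genes with negligible expression
#'
#' A gene is removed when both clauses hold: its CPM is below 1 in every
#' sample, and the sum of its CPMs across samples is below the number of
#' samples. CPM is computed on the raw library sizes (filtering precedes
#' normalization). Row order is preserved; the filter is idempotent.
#'
#' @inheritParams computeCPM
#' @return list with \code{counts} (the retained matrix) and
#'   \code{removed} (character vector of dropped gene ids).
#' @export
filterLowExpression <- function(counts) {
    counts <- asCountMatrix(counts)
    if (ncol(counts) < 1L) stop("at least one sample is required")
    cpm <- computeCPM(counts)
    drop <- apply(cpm, 1L, max) < 1 & rowSums(cpm) < ncol(counts)
    list(counts = counts[!drop, , drop = FALSE],
         removed = rownames(counts)[drop])
}

#' Trimmed mean of M-values normalization factors
#'
#' Composition-bias factors: each sample is compared to a reference sample
#' (the one whose CPM upper quartile is closest to the mean upper quartile)
#' through gene-wise log2 CPM ratios (M) and average log2 CPM abundances
#' (A); after discarding genes with a zero count in either sample and
#' trimming 30 percent of the M tails and 5 percent of the A tails, the
#' factor is 2 to the precision-weighted mean M (inverse asymptotic
#' binomial variance weights). Factors are rescaled to geometric mean 1.
#' Computation is delegated to the TMM implementation in edgeR.
#'
#' @inheritParams computeCPM
#' @param logratioTrim,sumTrim tail fractions trimmed from M and A.
#' @return numeric vector of per-sample factors, geometric mean 1.
#' @export
tmmFactors <- function(counts, libSizes = NULL, logratioTrim = 0.3,
                       sumTrim = 0.05) {
    counts <- asCountMatrix(counts)
    if (ncol(counts) < 2L) stop("TMM needs at least two samples")
    if (any(colSums(counts) == 0))
        stop("sample with all-zero counts: ",
             paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
    if (is.null(libSizes)) libSizes <- colSums(counts)
    f <- edgeR::calcNormFactors(counts, lib.size = libSizes, method = "TMM",
                                logratioTrim = logratioTrim,
                                sumTrim = sumTrim, doWeighting = TRUE)
    setNames(as.numeric(f), colnames(counts))
}

#' Voom transformation: log2-CPM with precision weights
#'
#' Computes \code{log2((count + 0.5) / (libSize * factor + 1) * 1e6)} and
#' per-observation precision weights from the lowess trend of residual
#' sqrt-standard-deviation against average log-count, evaluated at each
#' observation's fitted value (the limma voom procedure). Weights are
#' floored at a small positive value.
#'
#' @inheritParams computeCPM
#' @param factors per-sample TMM factors; computed when \code{NULL}.
#' @param design model matrix for the mean-variance fit; defaults to the
#'   genotype-by-condition cell means when \code{counts} is a
#'   \linkS4class{SummarizedExperiment} carrying that design, else an
#'   intercept.
#' @param span lowess span for the trend.
#' @param weightFloor lower clamp for weights.
#' @return a \linkS4class{NormalizedOmics} with assays \code{logcpm} and
#'   \code{weights}; TMM factors in \code{metadata()$tmmFactors}.
#' @export
voomTransform <- function(counts, factors = NULL, design = NULL,
                          span = 0.5, weightFloor = 1e-6) {
    cd <- NULL
    if (is(counts, "SummarizedExperiment")) {
        cd <- colData(counts)
        if (is.null(design) &&
            all(c("genotype", "condition") %in% names(cd))) {
            grp <- factor(paste(cd$genotype, cd$condition, sep = "."))
            design <- model.matrix(~ 0 + grp)
        }
    }
    mat <- asCountMatrix(counts)
    if (is.null(design)) design <- matrix(1, ncol(mat), 1)
    if (ncol(mat) < ncol(design))
        stop("fewer samples than model parameters")
    if (is.null(factors)) factors <- tmmFactors(mat)
    stopifnot(all(factors > 0), length(factors) == ncol(mat))
    lib <- colSums(mat) * factors
    v <- limma::voom(mat, design = design, lib.size = lib, span = span)
    w <- pmax(v$weights, weightFloor)
    dimnames(w) <- dimnames(v$E)
    se <- SummarizedExperiment(assays = list(logcpm = v$E, weights = w),
                               colData = if (is.null(cd))
                                   DataFrame(row.names = colnames(mat)) else cd)
    metadata(se)$tmmFactors <- factors / exp(mean(log(factors)))
    new("NormalizedOmics", se)
}

#' Full preprocessing: filter, TMM, voom
#'
#' @param counts \linkS4class{SummarizedExperiment} (assay \code{counts},
#'   colData with \code{genotype} and \code{condition}) or matrix.
#' @inheritParams voomTransform
#' @return list with \code{norm} (\linkS4class{NormalizedOmics}),
#'   \code{removed} gene ids and \code{tmm} factors.
#' @export
preprocessCounts <- function(counts, span = 0.5) {
    cd <- if (is(counts, "SummarizedExperiment")) colData(counts) else NULL
    flt <- filterLowExpression(counts)
    kept <- flt$counts
    se <- SummarizedExperiment(assays = list(counts = kept),
                               colData = if (is.null(cd))
                                   DataFrame(row.names = colnames(kept)) else cd)
    f <- tmmFactors(kept)
    norm <- voomTransform(se, factors = f, span = span)
    list(norm = norm, removed = flt$removed, tmm = f)
}
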