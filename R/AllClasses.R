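#' Normalized expression container
#'
#' A \linkS4class{SummarizedExperiment} holding voom-transformed expression:
#' assay \code{"logcpm"} (log2 counts-per-million computed with effective
#' library sizes) and assay \code{"weights"} (strictly positive per-observation
#' precision weights from the mean-variance trend). Per-sample TMM
#' normalization factors live in \code{metadata(x)$tmmFactors} and multiply
#' the raw library sizes to give effective library sizes.
#'
#' @slot .Data inherited \code{SummarizedExperiment} structure.
#' @seealso [voomTransform()], [tmmFactors()]
#' @export
setClass("NormalizedOmics", contains = "SummarizedExperiment")

setValidity("NormalizedOmics", function(object) {
    msg <- character()
    if (!all(c("logcpm", "weights") %in% assayNames(object)))
        msg <- c(msg, "assays 'logcpm' and 'weights' are required")
    else if (any(assay(object, "weights") <= 0))
        msg <- c(msg, "all precision weights must be > 0")
    f <- metadata(object)$tmmFactors
    if (is.null(f))
        msg <- c(msg, "metadata(object)$tmmFactors is required")
    else {
        if (length(f) != ncol(object))
            msg <- c(msg, "one TMM factor per sample is required")
        if (abs(exp(mean(log(f))) - 1) > 1e-9)
            msg <- c(msg, "TMM factors must have geometric mean 1")
    }
    if (length(msg)) msg else TRUE
})

#' Genotype-specific correlation network
#'
#' All-pairs Pearson correlation network over the combined gene and
#' metabolite profiles of one genotype. Edges are the unordered feature
#' pairs whose correlation is significant after Benjamini-Hochberg FDR
#' control across every tested pair of this network. The full similarity
#' matrix is retained for tau-threshold scoring.
#'
#' @slot genotype single genotype label (e.g. \code{"emmer"}).
#' @slot nodeKind named character vector, one entry per feature, values in
#'   \code{c("gene","metabolite")}; names are the feature ids (node set).
#' @slot edges data.frame with columns \code{i}, \code{j} (feature ids,
#'   \code{i < j} in node order), \code{r}, \code{p}, \code{q}.
#' @slot nSamples number of samples the correlations were computed over.
#' @slot simMatrix symmetric Pearson correlation matrix over all nodes.
#' @slot alpha FDR level used for edge calling.
#' @seealso [buildCorrelationNetwork()]
#' @export
setClass("CorrelationNetwork",
    slots = c(genotype = "character", nodeKind = "character",
              edges = "data.frame", nSamples = "integer",
              simMatrix = "matrix", alpha = "numeric"))

setValidity("CorrelationNetwork", function(object) {
    msg <- character()
    ids <- names(object@nodeKind)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "nodeKind must be named with unique feature ids")
    if (!all(object@nodeKind %in% c("gene", "metabolite")))
        msg <- c(msg, "node kinds must be 'gene' or 'metabolite'")
    e <- object@edges
    need <- c("i", "j", "r", "p", "q")
    if (!all(need %in% names(e)))
        msg <- c(msg, "edges needs columns i, j, r, p, q")
    else if (nrow(e)) {
        if (!all(e$i %in% ids) || !all(e$j %in% ids))
            msg <- c(msg, "edge endpoints must be known nodes")
        if (any(e$i == e$j)) msg <- c(msg, "self-edges are not allowed")
        if (any(abs(e$r) > 1)) msg <- c(msg, "|r| must be <= 1")
    }
    if (!identical(dim(object@simMatrix), c(length(ids), length(ids))))
        msg <- c(msg, "simMatrix must be square over the node set")
    if (length(msg)) msg else TRUE
})

#' Edge-wise network comparison report
#'
#' For every edge in the intersection of two genotype networks: the two
#' correlation coefficients, the Fisher z statistic for their difference,
#' its two-sided normal p-value, the BH-adjusted q over intersection edges,
#' and the resulting class: \code{"differential"} when q < alpha, otherwise
#' \code{"common"}. The common-class subgraph is the common network.
#'
#' @slot edges data.frame with columns \code{i}, \code{j}, \code{rA},
#'   \code{rB}, \code{z}, \code{p}, \code{q}, \code{class}.
#' @slot nA,nB sample sizes behind the two correlation estimates.
#' @slot alpha FDR level splitting common from differential edges.
#' @seealso [intersectAndClassify()], [fisherZEdgeTest()]
#' @export
setClass("DifferentialEdgeReport",
    slots = c(edges = "data.frame", nA = "integer", nB = "integer",
              alpha = "numeric"))

setValidity("DifferentialEdgeReport", function(object) {
    e <- object@edges
    need <- c("i", "j", "rA", "rB", "z", "p", "q", "class")
    if (!all(need %in% names(e)))
        return("edges needs columns i, j, rA, rB, z, p, q, class")
    if (nrow(e) && !all(e$class %in% c("common", "differential")))
        return("class must be 'common' or 'differential'")
    if (nrow(e) && !all((e$q < object@alpha) == (e$class == "differential")))
        return("class must equal 'differential' exactly when q < alpha")
    TRUE
})
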