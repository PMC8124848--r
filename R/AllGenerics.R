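#' @rdname CorrelationNetwork-class
#' @param x,object a \linkS4class{CorrelationNetwork} or
#'   \linkS4class{DifferentialEdgeReport}.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("nodeKinds", function(x) standardGeneric("nodeKinds"))

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("simMatrix", function(x) standardGeneric("simMatrix"))

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("genotypeLabel", function(x) standardGeneric("genotypeLabel"))

#' @rdname NormalizedOmics-class
#' @param object a \linkS4class{NormalizedOmics}.
#' @export
setGeneric("tmmFactorsOf", function(object) standardGeneric("tmmFactorsOf"))

#' @rdname CorrelationNetwork-class
setMethod("edges", "CorrelationNetwork", function(x) x@edges)

#' @rdname CorrelationNetwork-class
setMethod("nodeIds", "CorrelationNetwork", function(x) names(x@nodeKind))

#' @rdname CorrelationNetwork-class
setMethod("nodeKinds", "CorrelationNetwork", function(x) x@nodeKind)

#' @rdname CorrelationNetwork-class
setMethod("simMatrix", "CorrelationNetwork", function(x) x@simMatrix)

#' @rdname CorrelationNetwork-class
setMethod("nSamples", "CorrelationNetwork", function(x) x@nSamples)

#' @rdname CorrelationNetwork-class
setMethod("genotypeLabel", "CorrelationNetwork", function(x) x@genotype)

#' @rdname DifferentialEdgeReport-class
setMethod("edges", "DifferentialEdgeReport", function(x) x@edges)

#' @rdname NormalizedOmics-class
setMethod("tmmFactorsOf", "NormalizedOmics",
    function(object) metadata(object)$tmmFactors)

setMethod("show", "CorrelationNetwork", function(object) {
    k <- table(factor(object@nodeKind, c("gene", "metabolite")))
    cat("CorrelationNetwork for genotype '", object@genotype, "'\n",
        "  nodes: ", length(object@nodeKind), " (", k[["gene"]], " genes, ",
        k[["metabolite"]], " metabolites)\n",
        "  edges: ", nrow(object@edges), " significant at FDR ",
        object@alpha, " over n = ", object@nSamples, " samples\n", sep = "")
})

setMethod("show", "DifferentialEdgeReport", function(object) {
    tab <- table(factor(object@edges$class, c("common", "differential")))
    cat("DifferentialEdgeReport over ", nrow(object@edges),
        " intersection edges\n  common: ", tab[["common"]],
        "  differential: ", tab[["differential"]],
        "  (Fisher z, FDR ", object@alpha, "; nA = ", object@nA,
        ", nB = ", object@nB, ")\n", sep = "")
})
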