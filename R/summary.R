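#' Round half away from zero
#'
#' Decimal rounding with halves going up (the convention used for the
#' printed summary tables), unlike base round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Between-genotype ratio, printed-precision rounding
#'
#' Ratio \code{b / a}, rounded half-up to 1 decimal when it is at least 1
#' and to 2 decimals below 1. A zero denominator yields \code{NA}.
#'
#' @param a,b numerator is \code{b}, denominator \code{a}.
#' @examples
#' genotypeRatio(1249637, 3500971)  # 2.8
#' genotypeRatio(185, 157)          # 0.85
#' @export
genotypeRatio <- function(a, b) {
    if (length(a) != 1L || length(b) != 1L) stop("scalar inputs required")
    if (a == 0) return(NA_real_)
    r <- b / a
    roundHalfUp(r, if (r >= 1) 1L else 2L)
}

#' Percentage of a denominator, one decimal
#'
#' @param part,whole counts; \code{100 * part / whole} rounded half-up to
#'   one decimal. Zero denominator is an error.
#' @examples
#' percentOf(393779, 396571)  # 99.3
#' @export
percentOf <- function(part, whole) {
    if (any(whole == 0)) stop("empty denominator")
    roundHalfUp(100 * part / whole, 1L)
}

# per-class edge counts of an edge table given node kinds
edgeClassCounts <- function(edgeTab, kinds) {
    ki <- kinds[edgeTab$i]; kj <- kinds[edgeTab$j]
    gg <- sum(ki == "gene" & kj == "gene")
    mm <- sum(ki == "metabolite" & kj == "metabolite")
    gm <- nrow(edgeTab) - gg - mm
    c(total = nrow(edgeTab), geneGene = gg, metMet = mm, geneMet = gm)
}

# summary block for one edge set: class counts, nodes, central nodes,
# central-DEG / significant-metabolite edge count
summaryBlock <- function(edgeTab, kinds, sigMetabolites, vertexIds) {
    cls <- edgeClassCounts(edgeTab, kinds)
    ct <- centralities(edgeTab, vertexIds = vertexIds)
    connected <- unique(c(edgeTab$i, edgeTab$j))
    centralIds <- ct$node[ct$central]
    centralDegs <- centralIds[kinds[centralIds] == "gene"]
    ref <- refineNetwork(edgeTab, centralDegs, sigMetabolites)
    c(cls, nodes = length(connected), centralNodes = length(centralIds),
      centralDegMetEdges = ref$degMetEdges)
}

#' Summary table of the two genotype networks and their comparison
#'
#' A table in the style of the published network summary: per genotype,
#' intersection and common network, the edge counts in total and split by
#' endpoint kind (gene-gene, metabolite-metabolite, gene-metabolite), the
#' number of connected nodes, the number of central nodes, and the number
#' of edges linking central gene (DEG) nodes to significantly behaved
#' metabolites; plus the B/A ratio per row ([genotypeRatio()]) and the
#' common-network percentages of the intersection and of each genotype's
#' edge total.
#'
#' @param netA,netB \linkS4class{CorrelationNetwork}s for the two
#'   genotypes (A = emmer-like, B = durum-like).
#' @param report \linkS4class{DifferentialEdgeReport}; computed from the
#'   two networks when \code{NULL}.
#' @param sigMetabolites ids of metabolites significant for any of the
#'   G, N, or G x N ANOVA effects.
#' @return list with \code{table} (rows = summary quantities, columns
#'   \code{A}, \code{B}, \code{ratio}, \code{intersection},
#'   \code{common}) and \code{percentages} (common/intersection,
#'   common/A-total, common/B-total).
#' @export
summarizeNetworks <- function(netA, netB, report = NULL,
                              sigMetabolites = character()) {
    if (is.null(report)) report <- intersectAndClassify(netA, netB)
    kinds <- c(nodeKinds(netA),
               nodeKinds(netB)[setdiff(nodeIds(netB), nodeIds(netA))])
    ids <- names(kinds)
    rep <- edges(report)
    blocks <- list(
        A = summaryBlock(edges(netA), kinds, sigMetabolites, nodeIds(netA)),
        B = summaryBlock(edges(netB), kinds, sigMetabolites, nodeIds(netB)),
        intersection = summaryBlock(rep, kinds, sigMetabolites, ids),
        common = summaryBlock(rep[rep$class == "common", , drop = FALSE],
                              kinds, sigMetabolites, ids))
    tab <- data.frame(A = blocks$A, B = blocks$B,
                      ratio = vapply(seq_along(blocks$A), function(i)
                          genotypeRatio(blocks$A[i], blocks$B[i]), 0),
                      intersection = blocks$intersection,
                      common = blocks$common,
                      row.names = names(blocks$A))
    pct <- c(commonOfIntersection =
                 if (tab["total", "intersection"] > 0)
                     percentOf(tab["total", "common"],
                               tab["total", "intersection"]) else NA_real_,
             commonOfA = if (tab["total", "A"] > 0)
                 percentOf(tab["total", "common"], tab["total", "A"])
                 else NA_real_,
             commonOfB = if (tab["total", "B"] > 0)
                 percentOf(tab["total", "common"], tab["total", "B"])
                 else NA_real_)
    list(table = tab, percentages = pct)
}

#' Overlap (Venn) report for gene sets
#'
#' Counts every intersection region of the given sets and expresses
#' selected counts as percentages of a stated denominator set.
#'
#' @param sets named list of character vectors.
#' @param denominator character vector; percentages use its size.
#' @return list with \code{regions} (data.frame: membership pattern,
#'   count, percent of denominator) and \code{denominatorSize}.
#' @examples
#' overlapPercentages(list(x = letters[1:4], y = letters[3:6]),
#'                    denominator = letters[1:6])
#' @export
overlapPercentages <- function(sets, denominator) {
    stopifnot(length(sets) >= 1L, !is.null(names(sets)))
    if (!length(denominator)) stop("empty denominator set")
    all <- unique(unlist(sets))
    mem <- vapply(sets, function(s) all %in% s,
                  logical(length(all)))
    if (length(all) == 1L) mem <- matrix(mem, 1L,
                                         dimnames = list(NULL, names(sets)))
    pattern <- apply(mem, 1L, function(r)
        paste(names(sets)[r], collapse = "&"))
    counts <- table(pattern)
    regions <- data.frame(region = names(counts),
                          count = as.integer(counts), row.names = NULL)
    regions$percent <- percentOf(regions$count, length(denominator))
    regions <- regions[order(-regions$count), , drop = FALSE]
    list(regions = regions, denominatorSize = length(denominator))
}
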