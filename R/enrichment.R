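#' Hypergeometric term over-representation test
#'
#' For each annotation term, the upper-tail probability
#' \code{P(X >= k)} with \code{X ~ Hypergeometric(N, K, n)}: \code{N}
#' annotated universe genes, \code{K} of them carrying the term, \code{n}
#' genes in the test set, \code{k} of those carrying the term. BH
#' q-values are computed across the tested terms of this set; a term is
#' enriched at q < alpha. Terms annotating no universe gene are skipped.
#' The universe is restricted to annotated genes.
#'
#' @param degSet character vector of gene ids (must lie in the universe).
#' @param universe character vector of background gene ids (typically all
#'   expressed, filter-surviving genes).
#' @param annotation data.frame with columns \code{gene}, \code{term}.
#' @param termInfo optional data.frame \code{term}, \code{name},
#'   \code{category}.
#' @param alpha FDR level.
#' @return data.frame: \code{term}, \code{k}, \code{K}, \code{n},
#'   \code{N}, \code{p}, \code{q}, \code{enriched}, plus \code{name} and
#'   \code{category} when \code{termInfo} is given; sorted by p.
#' @examples
#' ann <- data.frame(gene = c("g1", "g2", "g3", "g4"),
#'                   term = c("T1", "T1", "T2", "T2"))
#' hypergeomEnrich(c("g1", "g2"), paste0("g", 1:4), ann)
#' @export
hypergeomEnrich <- function(degSet, universe, annotation, termInfo = NULL,
                            alpha = 0.05) {
    stopifnot(all(c("gene", "term") %in% names(annotation)))
    missing <- setdiff(degSet, universe)
    if (length(missing))
        stop("test-set gene(s) absent from the universe: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
    universe <- intersect(universe, unique(ann$gene))
    degSet <- intersect(degSet, universe)
    N <- length(universe); n <- length(degSet)
    byTerm <- split(ann$gene, ann$term)
    terms <- names(byTerm)
    K <- vapply(byTerm, function(g) length(unique(g)), 0L)
    k <- vapply(byTerm, function(g) length(intersect(unique(g), degSet)), 0L)
    keep <- K > 0L
    terms <- terms[keep]; K <- K[keep]; k <- k[keep]
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    q <- if (length(p)) bhFDR(p) else numeric()
    out <- data.frame(term = terms, k = k, K = K, n = n, N = N,
                      p = p, q = q, enriched = q < alpha, row.names = NULL)
    if (!is.null(termInfo))
        out <- merge(out, termInfo, by = "term", all.x = TRUE, sort = FALSE)
    out[order(out$p, out$term), , drop = FALSE]
}

#' Per-category counts of up- and downregulated genes
#'
#' Rolls annotation terms up to categories and counts, separately per
#' direction, the distinct test-set genes annotated to each category
#' (a gene with terms in two categories counts once in each). Terms
#' without a category go to \code{"unclassified"}.
#'
#' @param upGenes,downGenes character vectors of gene ids per direction.
#' @param annotation data.frame \code{gene}, \code{term}.
#' @param termInfo data.frame \code{term}, \code{category} (and optionally
#'   \code{name}).
#' @return data.frame: \code{category}, \code{up}, \code{down}.
#' @export
rollupCategories <- function(upGenes, downGenes, annotation, termInfo) {
    stopifnot(all(c("gene", "term") %in% names(annotation)),
              "term" %in% names(termInfo))
    cat <- setNames(as.character(termInfo$category), termInfo$term)
    ann <- annotation
    ann$category <- cat[ann$term]
    ann$category[is.na(ann$category)] <- "unclassified"
    countBy <- function(genes) {
        sub <- unique(ann[ann$gene %in% genes, c("gene", "category")])
        table(factor(sub$category, levels = sort(unique(ann$category))))
    }
    up <- countBy(upGenes); down <- countBy(downGenes)
    data.frame(category = names(up), up = as.integer(up),
               down = as.integer(down), row.names = NULL)
}
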