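#' Build a genotype-specific correlation network
#'
#' Pearson correlation of every unordered pair of feature profiles over
#' one genotype's samples; two-sided t-based p-values; BH FDR across all
#' tested pairs of this network; an edge is kept when q < alpha. Constant
#' features are excluded with a warning. The full similarity matrix is
#' retained for tau scoring.
#'
#' @param profiles numeric matrix, features x samples (genes as voom
#'   logcpm, metabolites as abundances; Pearson r is scale-invariant).
#' @param kind character vector (\code{"gene"}/\code{"metabolite"}) per
#'   feature; a single value is recycled.
#' @param genotype label stored on the network.
#' @param alpha FDR level for edge calling.
#' @return a \linkS4class{CorrelationNetwork}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("f", 1:5), NULL))
#' buildCorrelationNetwork(x, kind = "gene", genotype = "A")
#' @export
buildCorrelationNetwork <- function(profiles, kind = "gene",
                                    genotype = "A", alpha = 0.05) {
    stopifnot(is.matrix(profiles), ncol(profiles) >= 4L)
    ids <- rownames(profiles)
    if (is.null(ids) || anyDuplicated(ids))
        stop("profiles need unique rownames (feature ids)")
    if (length(kind) == 1L) kind <- rep(kind, nrow(profiles))
    names(kind) <- ids
    const <- apply(profiles, 1L, function(v) sd(v) == 0)
    if (any(const)) {
        warning("excluding ", sum(const), " constant feature(s)")
        profiles <- profiles[!const, , drop = FALSE]
        kind <- kind[!const]
        ids <- ids[!const]
    }
    n <- ncol(profiles)
    S <- cor(t(profiles))
    ut <- which(upper.tri(S), arr.ind = TRUE)
    r <- S[ut]
    p <- corPValue(r, n)
    q <- bhFDR(p)
    sig <- q < alpha
    edges <- data.frame(i = ids[ut[sig, 1L]], j = ids[ut[sig, 2L]],
                        r = r[sig], p = p[sig], q = q[sig])
    new("CorrelationNetwork", genotype = genotype, nodeKind = kind,
        edges = edges, nSamples = as.integer(n), simMatrix = S,
        alpha = alpha)
}

#' Fisher z test for the difference of two correlations
#'
#' \code{z = (atanh(rA) - atanh(rB)) / sqrt(1/(nA-3) + 1/(nB-3))} with a
#' two-sided standard-normal p-value. Correlations with |r| = 1 are
#' clamped to 1 - 1e-12 before the transform. Vectorized over edges.
#'
#' @param rA,rB correlation coefficients.
#' @param nA,nB sample sizes (>= 4).
#' @return list with \code{z} and \code{p}.
#' @examples
#' fisherZEdgeTest(0.9, 8, 0, 8)
#' @export
fisherZEdgeTest <- function(rA, nA, rB, nB) {
    stopifnot(nA >= 4L, nB >= 4L)
    clamp <- function(r) pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
    z <- (atanh(clamp(rA)) - atanh(clamp(rB))) /
        sqrt(1 / (nA - 3) + 1 / (nB - 3))
    list(z = z, p = 2 * pnorm(-abs(z)))
}

edgeKey <- function(e) paste(e$i, e$j, sep = "\r")

#' Intersect two genotype networks and classify shared edges
#'
#' The intersection network holds the edges significant in both genotype
#' networks. Each intersection edge receives a Fisher z p-value for the
#' difference of its two correlations; BH FDR runs over intersection edges
#' only. Edges with q < alpha are \code{"differential"}; the rest form the
#' common network.
#'
#' @param netA,netB \linkS4class{CorrelationNetwork}s over a shared
#'   feature universe (matched by feature id).
#' @param alpha FDR level of the edge-difference test.
#' @return a \linkS4class{DifferentialEdgeReport}.
#' @export
intersectAndClassify <- function(netA, netB, alpha = 0.05) {
    if (!length(intersect(nodeIds(netA), nodeIds(netB))))
        stop("the two networks share no nodes")
    eA <- edges(netA); eB <- edges(netB)
    shared <- merge(eA[, c("i", "j", "r")], eB[, c("i", "j", "r")],
                    by = c("i", "j"), suffixes = c("A", "B"))
    if (nrow(shared)) {
        ft <- fisherZEdgeTest(shared$rA, nSamples(netA),
                              shared$rB, nSamples(netB))
        q <- bhFDR(ft$p)
        out <- data.frame(i = shared$i, j = shared$j,
                          rA = shared$rA, rB = shared$rB,
                          z = ft$z, p = ft$p, q = q,
                          class = ifelse(q < alpha, "differential", "common"))
    } else {
        out <- data.frame(i = character(), j = character(), rA = numeric(),
                          rB = numeric(), z = numeric(), p = numeric(),
                          q = numeric(), class = character())
    }
    new("DifferentialEdgeReport", edges = out, nA = nSamples(netA),
        nB = nSamples(netB), alpha = alpha)
}

# igraph over an edge table, keeping isolated vertices
edgeGraph <- function(edgeTab, vertexIds) {
    igraph::graph_from_data_frame(edgeTab[, c("i", "j"), drop = FALSE],
                                  directed = FALSE,
                                  vertices = data.frame(name = vertexIds))
}

#' Degree and betweenness centralities with central-node flags
#'
#' Degree = number of incident significant edges; betweenness = Brandes
#' shortest-path betweenness on the unweighted graph (unnormalized,
#' igraph). A node is central when its degree and its betweenness both
#' strictly exceed the network means of those quantities.
#'
#' @param net a \linkS4class{CorrelationNetwork}, or a data.frame edge
#'   table with columns \code{i}, \code{j} (then supply \code{vertexIds}).
#' @param vertexIds node ids (isolated nodes included); taken from the
#'   network when omitted.
#' @return data.frame: \code{node}, \code{kind} (when available),
#'   \code{degree}, \code{betweenness}, \code{central}.
#' @examples
#' path <- data.frame(i = c("a", "b"), j = c("b", "c"))
#' centralities(path, vertexIds = c("a", "b", "c"))
#' @export
centralities <- function(net, vertexIds = NULL) {
    kind <- NULL
    if (is(net, "CorrelationNetwork")) {
        if (is.null(vertexIds)) vertexIds <- nodeIds(net)
        kind <- nodeKinds(net)[vertexIds]
        edgeTab <- edges(net)
    } else edgeTab <- net
    if (is.null(vertexIds))
        vertexIds <- sort(unique(c(edgeTab$i, edgeTab$j)))
    g <- edgeGraph(edgeTab, vertexIds)
    deg <- igraph::degree(g)
    btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    central <- deg > mean(deg) & btw > mean(btw)
    out <- data.frame(node = vertexIds, degree = as.integer(deg),
                      betweenness = as.numeric(btw),
                      central = as.logical(central), row.names = NULL)
    if (!is.null(kind)) out <- cbind(out[1L], kind = as.character(kind),
                                     out[-1L])
    out
}

#' Refine a network to central DEGs and significant metabolites
#'
#' Induced subgraph on the union of the given central gene (DEG) ids and
#' significantly behaved metabolite ids, plus the count of edges linking
#' one central DEG to one significant metabolite.
#'
#' @param net a \linkS4class{CorrelationNetwork} or edge table.
#' @param centralDegIds,sigMetaboliteIds node id vectors.
#' @return list with \code{edges} (induced edge table), \code{nodes}, and
#'   \code{degMetEdges} (central-DEG to significant-metabolite edge
#'   count).
#' @export
refineNetwork <- function(net, centralDegIds, sigMetaboliteIds) {
    edgeTab <- if (is(net, "CorrelationNetwork")) edges(net) else net
    keepNodes <- union(centralDegIds, sigMetaboliteIds)
    sub <- edgeTab[edgeTab$i %in% keepNodes & edgeTab$j %in% keepNodes, ,
                   drop = FALSE]
    cross <- (sub$i %in% centralDegIds & sub$j %in% sigMetaboliteIds) |
             (sub$j %in% centralDegIds & sub$i %in% sigMetaboliteIds)
    list(edges = sub, nodes = keepNodes, degMetEdges = sum(cross))
}

#' Genotype-specificity tau scores
#'
#' For threshold tau, a node's score in genotype A counts its network
#' neighbours j with |r_A(i,j)| >= tau whose counterpart in genotype B is
#' not an edge with |r_B(i,j)| >= tau (and vice versa). Absolute
#' correlation is used.
#'
#' @param netA,netB \linkS4class{CorrelationNetwork}s.
#' @param tau threshold in (0, 1).
#' @return data.frame: \code{node}, \code{tau}, \code{scoreA},
#'   \code{scoreB}.
#' @export
tauSpecificScore <- function(netA, netB, tau) {
    stopifnot(tau > 0, tau < 1)
    ids <- union(nodeIds(netA), nodeIds(netB))
    adj <- function(net) {
        m <- matrix(FALSE, length(ids), length(ids),
                    dimnames = list(ids, ids))
        e <- edges(net)
        e <- e[abs(e$r) >= tau, , drop = FALSE]
        if (nrow(e)) {
            m[cbind(e$i, e$j)] <- TRUE
            m[cbind(e$j, e$i)] <- TRUE
        }
        m
    }
    mA <- adj(netA); mB <- adj(netB)
    data.frame(node = ids, tau = tau,
               scoreA = as.integer(rowSums(mA & !mB)),
               scoreB = as.integer(rowSums(mB & !mA)), row.names = NULL)
}

#' Export a network to GraphML
#'
#' Nodes carry kind, degree, betweenness and central flags; edges carry r
#' and q.
#'
#' @param net a \linkS4class{CorrelationNetwork}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
exportGraphML <- function(net, file) {
    ct <- centralities(net)
    g <- edgeGraph(edges(net), nodeIds(net))
    igraph::V(g)$kind <- as.character(nodeKinds(net)[ct$node])
    igraph::V(g)$degree <- ct$degree
    igraph::V(g)$betweenness <- ct$betweenness
    igraph::V(g)$central <- ct$central
    igraph::E(g)$r <- edges(net)$r
    igraph::E(g)$q <- edges(net)$q
    igraph::write_graph(g, file, format = "graphml")
    invisible(file)
}
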