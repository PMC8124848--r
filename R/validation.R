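#' Planted-module recovery experiment
#'
#' Simulates one two-genotype study carrying a single genotype-A-only
#' correlation module (by default 20 genes among 220, with 40 metabolites,
#' target within-module correlation 0.95, 4 replicates per cell), runs the
#' preprocessing and network stages, and measures how much of the planted
#' structure the pipeline recovers:
#' \itemize{
#'   \item \code{recovery}: fraction of planted module pairs that appear as
#'     A-specific tau edges (significant edge in A with |r| >= tau, with no
#'     matching tau edge in B);
#'   \item \code{topDecileFraction}: fraction of module members ranking in
#'     the top decile of A-specific tau scores;
#'   \item \code{meanModuleCor}: realised mean within-module |r| in A.
#' }
#' Because a single study is one draw of the latent module factor at n = 8,
#' recovery should be averaged over several seeds when used as an estimate.
#'
#' @param seed RNG seed for the simulated study.
#' @param nGenes,nMetabolites simulated feature counts.
#' @param moduleSize module gene count.
#' @param targetCor floor for planted within-module correlation.
#' @param tau threshold for genotype-specific edges.
#' @return named numeric vector with the three measures.
#' @export
moduleRecoveryExperiment <- function(seed, nGenes = 220, nMetabolites = 40,
                                     moduleSize = 20, targetCor = 0.95,
                                     tau = 0.8) {
    cfg <- simulationConfig(nGenes = nGenes, nMetabolites = nMetabolites,
        seed = seed,
        moduleSpecs = list(moduleSpec("A", nGenes = moduleSize,
                                      targetCor = targetCor)))
    sim <- simulateDualOmics(cfg)
    pre <- preprocessCounts(sim$counts)
    lc <- assay(pre$norm, "logcpm")
    kinds <- c(rep("gene", nrow(lc)), rep("metabolite", nrow(sim$metabolites)))
    nets <- lapply(c(A = "A", B = "B"), function(g) {
        sel <- sim$design$genotype == g
        buildCorrelationNetwork(rbind(lc[, sel],
                                      sim$metabolites[, sel, drop = FALSE]),
                                kind = kinds, genotype = g)
    })
    eA <- edges(nets$A); eB <- edges(nets$B)
    keyA <- paste(eA$i, eA$j)[abs(eA$r) >= tau]
    keyB <- paste(eB$i, eB$j)[abs(eB$r) >= tau]
    planted <- sim$truth$moduleEdges$A
    recovery <- mean(paste(planted$i, planted$j) %in% setdiff(keyA, keyB))

    ts <- tauSpecificScore(nets$A, nets$B, tau)
    topN <- ceiling(nrow(ts) / 10)
    top <- ts$node[order(-ts$scoreA)][seq_len(topN)]
    mem <- sim$truth$moduleMembers[[1L]]
    selA <- sim$design$genotype == "A"
    C <- cor(t(lc[mem, selA]))
    c(recovery = recovery,
      topDecileFraction = mean(mem %in% top),
      meanModuleCor = mean(abs(C[upper.tri(C)])))
}
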