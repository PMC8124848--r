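#' Simulation configuration for the two-genotype dual-omics design
#'
#' Describes a synthetic study with two genotypes (labelled \code{"A"}, an
#' emmer-like accession, and \code{"B"}, a durum-like accession) grown under
#' nitrogen starvation (\code{minusN}) and optimal nitrogen (\code{plusN}),
#' with \code{nReplicates} biological replicates per genotype-by-condition
#' cell (default 4, i.e. 8 samples per genotype and 16 in total).
#'
#' Counts are negative binomial around log-normal gene base abundances, with
#' condition effects planted on a random \code{degFraction} of genes per
#' genotype at log2 fold change \code{+/- logfcScale}. Correlation modules
#' are planted through a latent factor per module and genotype: member genes
#' receive a log2-scale shift \code{amplitude * (lambda * z + sqrt(1 -
#' lambda^2) * e)} where \code{z} varies over the genotype's samples, so
#' that realised pairwise correlations of members exceed \code{targetCor}
#' (the internal latent correlation is set above the target to absorb
#' counting noise and the voom transform).
#'
#' @param nGenes,nMetabolites,nTraits numbers of features.
#' @param nReplicates replicates per genotype-by-condition cell (>= 2).
#' @param degFraction fraction of genes given a condition effect, per
#'   genotype.
#' @param logfcScale magnitude (log2) of planted condition effects.
#' @param nbDispersion negative binomial dispersion (> 0).
#' @param libSize expected library size; per-sample sizes are jittered
#'   uniformly within +/- 20 percent.
#' @param moduleSpecs list of [moduleSpec()] entries.
#' @param metaboliteEffects data.frame with columns \code{metabolite}
#'   (id or 1-based index), \code{G}, \code{N}, \code{GxN}: additive cell
#'   shifts in within-cell SD units.
#' @param seed integer RNG seed; all stages derive substreams from it.
#' @return a list of class \code{"SimulationConfig"}.
#' @examples
#' cfg <- simulationConfig(nGenes = 100, nMetabolites = 10, seed = 1)
#' @export
simulationConfig <- function(nGenes = 2000, nMetabolites = 45, nTraits = 13,
                             nReplicates = 4, degFraction = 0.1,
                             logfcScale = 2, nbDispersion = 0.1,
                             libSize = 2e6, moduleSpecs = list(),
                             metaboliteEffects = NULL, seed = 1L) {
    stopifnot(nGenes >= 1, nMetabolites >= 0, nTraits >= 0,
              nReplicates >= 2, degFraction >= 0, degFraction <= 1,
              nbDispersion > 0, libSize > 0)
    for (m in moduleSpecs)
        if (!inherits(m, "moduleSpec"))
            stop("moduleSpecs must be a list of moduleSpec() entries")
    cfg <- list(nGenes = as.integer(nGenes),
                nMetabolites = as.integer(nMetabolites),
                nTraits = as.integer(nTraits),
                nReplicates = as.integer(nReplicates),
                degFraction = degFraction, logfcScale = logfcScale,
                nbDispersion = nbDispersion, libSize = libSize,
                moduleSpecs = moduleSpecs,
                metaboliteEffects = metaboliteEffects,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Planted correlation module specification
#'
#' @param genotype which genotype carries the module: \code{"A"},
#'   \code{"B"} or \code{"both"} (independent latent factors per genotype,
#'   same loading, so the module appears in both networks).
#' @param nGenes number of member genes (assigned deterministically from
#'   the gene pool, disjoint across modules).
#' @param targetCor floor for realised within-module Pearson correlation.
#' @param amplitude log2-scale amplitude of the module signal.
#' @param nMetabolites number of metabolites coupled to the module factor.
#' @param metLambda loading of coupled metabolites on the factor.
#' @export
moduleSpec <- function(genotype = c("A", "B", "both"), nGenes = 20,
                       targetCor = 0.95, amplitude = 4,
                       nMetabolites = 0, metLambda = 0.9) {
    genotype <- match.arg(genotype)
    stopifnot(nGenes >= 2, targetCor > 0, targetCor < 1, amplitude > 0,
              nMetabolites >= 0, metLambda > 0, metLambda <= 1)
    structure(list(genotype = genotype, nGenes = as.integer(nGenes),
                   targetCor = targetCor, amplitude = amplitude,
                   nMetabolites = as.integer(nMetabolites),
                   metLambda = metLambda),
              class = "moduleSpec")
}

# deterministic per-stage substream of the global seed (kept < 2^31)
stageSeed <- function(seed, stage) {
    as.integer((as.numeric(seed) * 48271 + stage * 10007) %% 2147483647L)
}

# sample design shared by all generated matrices
makeDesign <- function(nReplicates) {
    d <- expand.grid(replicate = seq_len(nReplicates),
                     condition = c("minusN", "plusN"),
                     genotype = c("A", "B"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d <- d[, c("genotype", "condition", "replicate")]
    d$sample <- sprintf("%s_%s_r%d", d$genotype,
                        ifelse(d$condition == "minusN", "mN", "pN"),
                        d$replicate)
    d[, c("sample", "genotype", "condition", "replicate")]
}

# latent factors per module x genotype; loading set above the target so
# realised correlations exceed it after counting noise
moduleLatents <- function(cfg, design) {
    lapply(seq_along(cfg$moduleSpecs), function(k) {
        spec <- cfg$moduleSpecs[[k]]
        genos <- if (spec$genotype == "both") c("A", "B") else spec$genotype
        z <- matrix(0, nrow(design), 1L)
        rownames(z) <- design$sample
        for (g in genos) {
            sel <- design$genotype == g
            # unit sample variance so the planted signal never collapses
            z[sel, 1L] <- as.numeric(scale(rnorm(sum(sel))))
        }
        list(spec = spec, z = z[, 1L], genos = genos)
    })
}

latentLoading <- function(targetCor) sqrt(1 - (1 - targetCor) / 6)

#' Simulate gene-level RNA-seq counts with planted ground truth
#'
#' @param config a [simulationConfig()].
#' @return list with \code{counts} (a
#'   \linkS4class{SummarizedExperiment}: assay \code{"counts"}, colData =
#'   design), \code{design} (data.frame), and \code{truth}: planted DEG ids
#'   and log fold changes per genotype, module membership and the expected
#'   within-module edges per genotype.
#' @examples
#' sim <- simulateCounts(simulationConfig(nGenes = 50, seed = 7))
#' dim(SummarizedExperiment::assay(sim$counts))
#' @export
simulateCounts <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(stageSeed(config$seed, 1L))
    design <- makeDesign(config$nReplicates)
    nS <- nrow(design)
    geneIds <- sprintf("g%04d", seq_len(config$nGenes))

    # latents first so moduleLatentsFromConfig() can replay this substream
    lat <- moduleLatents(config, design)

    # base relative abundances and library sizes
    pi0 <- exp(rnorm(config$nGenes, 0, 1.2))
    pi0 <- pi0 / sum(pi0)
    libs <- config$libSize * runif(nS, 0.8, 1.2)

    # planted condition effects, independent per genotype
    logFC <- matrix(0, config$nGenes, 2, dimnames = list(geneIds, c("A", "B")))
    degIds <- list(A = character(), B = character())
    nDeg <- round(config$degFraction * config$nGenes)
    for (g in c("A", "B")) {
        idx <- sample.int(config$nGenes, nDeg)
        logFC[idx, g] <- sample(c(-1, 1), nDeg, replace = TRUE) *
            config$logfcScale
        degIds[[g]] <- geneIds[idx]
    }

    # module membership: disjoint blocks from the start of the gene pool
    shift <- matrix(0, config$nGenes, nS, dimnames = list(geneIds, design$sample))
    members <- list()
    nextGene <- 1L
    for (k in seq_along(lat)) {
        spec <- lat[[k]]$spec
        if (nextGene + spec$nGenes - 1L > config$nGenes)
            stop("not enough genes to host all module members")
        mem <- geneIds[seq(nextGene, length.out = spec$nGenes)]
        nextGene <- nextGene + spec$nGenes
        members[[k]] <- mem
        lam <- latentLoading(spec$targetCor)
        sel <- design$genotype %in% lat[[k]]$genos
        for (gene in mem) {
            e <- rnorm(sum(sel))
            shift[gene, sel] <- spec$amplitude *
                (lam * lat[[k]]$z[sel] + sqrt(1 - lam^2) * e)
        }
    }

    condInd <- as.numeric(design$condition == "minusN")
    genoCol <- match(design$genotype, c("A", "B"))
    mu <- matrix(0, config$nGenes, nS)
    for (s in seq_len(nS))
        mu[, s] <- libs[s] * pi0 * 2^(condInd[s] * logFC[, genoCol[s]] +
                                      shift[, s])
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nbDispersion),
                     config$nGenes, nS, dimnames = list(geneIds, design$sample))

    moduleEdges <- list(A = NULL, B = NULL)
    for (g in c("A", "B")) {
        ed <- list()
        for (k in seq_along(lat))
            if (g %in% lat[[k]]$genos && length(members[[k]]) >= 2) {
                pr <- t(combn(members[[k]], 2))
                ed[[length(ed) + 1L]] <- data.frame(i = pr[, 1], j = pr[, 2],
                                                   module = k)
            }
        moduleEdges[[g]] <- if (length(ed)) do.call(rbind, ed) else
            data.frame(i = character(), j = character(), module = integer())
    }

    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = DataFrame(design, row.names = design$sample))
    truth <- list(degIds = degIds, logFC = logFC,
                  moduleMembers = members, moduleEdges = moduleEdges,
                  latents = lat)
    list(counts = se, design = design, truth = truth)
}

#' Simulate Gaussian feature matrices (metabolites or traits) with planted
#' two-way effects
#'
#' Each feature is unit-SD Gaussian noise around a baseline of 10, plus
#' additive genotype, nitrogen and interaction cell shifts (in SD units)
#' from \code{config$metaboliteEffects}. Metabolites listed by module specs
#' are coupled to the corresponding gene-module latent factor (loading
#' \code{metLambda}) in the module's genotype(s), planting gene-metabolite
#' edges in that genotype's network.
#'
#' @param config a [simulationConfig()].
#' @param latents optional \code{truth$latents} from [simulateCounts()] run
#'   on the same config; required when module specs couple metabolites.
#' @param what \code{"metabolite"} or \code{"trait"} (traits get ids
#'   \code{t01...} and no module coupling).
#' @return list with \code{values} (features x samples matrix),
#'   \code{design}, \code{truth} (planted effect table, coupled ids).
#' @export
simulateMetabolites <- function(config, latents = NULL,
                                what = c("metabolite", "trait")) {
    stopifnot(inherits(config, "SimulationConfig"))
    what <- match.arg(what)
    design <- makeDesign(config$nReplicates)
    nS <- nrow(design)
    n <- if (what == "metabolite") config$nMetabolites else config$nTraits
    ids <- sprintf(if (what == "metabolite") "m%03d" else "t%02d", seq_len(n))
    set.seed(stageSeed(config$seed, if (what == "metabolite") 2L else 3L))

    vals <- matrix(rnorm(n * nS, 10, 1), n, nS,
                   dimnames = list(ids, design$sample))

    eff <- config$metaboliteEffects
    if (what == "trait") eff <- NULL
    effTab <- data.frame(feature = character(), G = numeric(),
                         N = numeric(), GxN = numeric())
    if (!is.null(eff)) {
        idx <- if (is.numeric(eff$metabolite)) as.integer(eff$metabolite)
               else match(as.character(eff$metabolite), ids)
        if (anyNA(idx) || any(idx < 1L) || any(idx > n))
            stop("metabolite effect spec references an unknown metabolite")
        gI <- as.numeric(design$genotype == "B")
        nI <- as.numeric(design$condition == "plusN")
        for (r in seq_along(idx))
            vals[idx[r], ] <- vals[idx[r], ] + eff$G[r] * gI +
                eff$N[r] * nI + eff$GxN[r] * gI * nI
        effTab <- data.frame(feature = ids[idx], G = eff$G, N = eff$N,
                             GxN = eff$GxN)
    }

    coupled <- data.frame(feature = character(), module = integer())
    if (what == "metabolite" && length(config$moduleSpecs)) {
        if (is.null(latents))
            latents <- moduleLatentsFromConfig(config)
        nextMet <- 1L
        for (k in seq_along(latents)) {
            spec <- latents[[k]]$spec
            if (spec$nMetabolites == 0L) next
            if (nextMet + spec$nMetabolites - 1L > n)
                stop("not enough metabolites to couple to modules")
            sel <- design$genotype %in% latents[[k]]$genos
            for (m in seq_len(spec$nMetabolites)) {
                id <- ids[nextMet]
                nextMet <- nextMet + 1L
                vals[id, sel] <- 10 + spec$metLambda * latents[[k]]$z[sel] +
                    sqrt(1 - spec$metLambda^2) * rnorm(sum(sel))
                coupled <- rbind(coupled,
                                 data.frame(feature = id, module = k))
            }
        }
    }
    list(values = vals, design = design,
         truth = list(effects = effTab, coupled = coupled))
}

# regenerate the same latent factors simulateCounts() would draw
moduleLatentsFromConfig <- function(config) {
    set.seed(stageSeed(config$seed, 1L))
    design <- makeDesign(config$nReplicates)
    moduleLatents(config, design)
}

#' Simulate a complete dual-omics study
#'
#' Runs [simulateCounts()] and [simulateMetabolites()] (metabolites and
#' traits) on one configuration, sharing module latent factors so planted
#' gene-metabolite coupling is consistent.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{counts}, \code{design}, \code{metabolites},
#'   \code{traits} and merged \code{truth}.
#' @examples
#' sim <- simulateDualOmics(simulationConfig(nGenes = 60, nMetabolites = 8,
#'                                           seed = 3))
#' names(sim)
#' @export
simulateDualOmics <- function(config) {
    cg <- simulateCounts(config)
    # latents are drawn inside simulateCounts' substream; reuse them
    met <- simulateMetabolites(config, latents = cg$truth$latents,
                               what = "metabolite")
    trt <- simulateMetabolites(config, what = "trait")
    list(counts = cg$counts, design = cg$design,
         metabolites = met$values, traits = trt$values,
         truth = c(cg$truth[c("degIds", "logFC", "moduleMembers",
                              "moduleEdges")],
                   list(metaboliteEffects = met$truth$effects,
                        coupledMetabolites = met$truth$coupled)))
}

#' Write a simulated study to TSV/JSON files
#'
#' @param sim result of [simulateDualOmics()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(counts = file.path(outdir, "counts.tsv"),
               design = file.path(outdir, "design.tsv"),
               metabolites = file.path(outdir, "metabolites.tsv"),
               traits = file.path(outdir, "traits.tsv"),
               truth = file.path(outdir, "truth.json"))
    writeMatrixTSV(assay(sim$counts, "counts"), paths["counts"], "gene")
    write.table(sim$design, paths["design"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeMatrixTSV(sim$metabolites, paths["metabolites"], "metabolite")
    writeMatrixTSV(sim$traits, paths["traits"], "trait")
    truth <- sim$truth
    truth$logFC <- NULL  # large; DEG ids and effects carry the usable truth
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA)
    invisible(paths)
}
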