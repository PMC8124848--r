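#' Run the full dual-omics comparison pipeline
#'
#' Sequences preprocessing, differential expression (all four contrasts),
#' metabolite/trait two-way ANOVA, optional GO enrichment, per-genotype
#' correlation networks over combined gene + metabolite profiles, the
#' edge-wise Fisher z comparison, centralities, tau-specificity scores and
#' the summary table. Genotype networks pool both nitrogen conditions
#' (n = 8 samples per genotype in the reference design). Deterministic:
#' no stage draws random numbers; \code{seed} is recorded in the manifest
#' for provenance.
#'
#' @param counts \linkS4class{SummarizedExperiment} (assay
#'   \code{"counts"}) or matrix of gene counts.
#' @param design data.frame (\code{sample}, \code{genotype},
#'   \code{condition}); taken from \code{colData(counts)} when omitted.
#' @param metabolites matrix, metabolites x samples (same samples).
#' @param traits optional matrix, traits x samples.
#' @param annotation,termInfo optional gene-term map and term metadata for
#'   enrichment (see [hypergeomEnrich()]).
#' @param alpha named or single numeric: significance levels for
#'   \code{edge}, \code{de}, \code{anova}, \code{enrich} (default all
#'   0.05).
#' @param tau thresholds for [tauSpecificScore()].
#' @param networkFeatures \code{"degs"} (network gene nodes are the
#'   genotype's DEGs, as in the reference analysis) or \code{"all"}
#'   (every filter-surviving gene).
#' @param outdir optional directory; when given, all artifacts are
#'   written (TSV/JSON/GraphML) together with a manifest.
#' @param seed integer recorded in the manifest.
#' @return list with \code{norm}, \code{de} (per contrast),
#'   \code{degLists}, \code{anova} (\code{metabolites}, \code{traits}),
#'   \code{sigMetabolites}, \code{enrichment}, \code{networks},
#'   \code{report}, \code{centralities}, \code{tauScores},
#'   \code{summary}, \code{manifest}.
#' @export
runPipeline <- function(counts, design = NULL, metabolites,
                        traits = NULL, annotation = NULL, termInfo = NULL,
                        alpha = 0.05, tau = c(0.6, 0.8),
                        networkFeatures = c("degs", "all"),
                        outdir = NULL, seed = 1L) {
    networkFeatures <- match.arg(networkFeatures)
    al <- resolveAlpha(alpha)
    stage <- function(label, expr)
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", label, "' failed: ",
                 conditionMessage(e), call. = FALSE))

    if (is.null(design)) {
        stopifnot(is(counts, "SummarizedExperiment"))
        design <- as.data.frame(colData(counts))
    }
    stopifnot(all(c("sample", "genotype", "condition") %in% names(design)))

    pre <- stage("preprocess", {
        se <- if (is(counts, "SummarizedExperiment")) counts else
            SummarizedExperiment(assays = list(counts = asCountMatrix(counts)),
                                 colData = DataFrame(design,
                                                     row.names = design$sample))
        preprocessCounts(se)
    })
    norm <- pre$norm

    contrasts <- c("withinA", "withinB", "betweenAtMinusN", "betweenAtPlusN")
    de <- stage("differential", {
        out <- lapply(contrasts, function(ct)
            fitGeneContrast(norm, design, ct, alpha = al["de"]))
        names(out) <- contrasts
        out
    })
    degLists <- lapply(de, function(d) d$gene[!is.na(d$direction)])

    anova <- stage("anova", {
        list(metabolites = twowayAnova(metabolites, design,
                                       alpha = al["anova"]),
             traits = if (is.null(traits)) NULL else
                 twowayAnova(traits, design, alpha = al["anova"]))
    })
    sigMetabolites <- anova$metabolites$feature[anova$metabolites$significant]

    enrichment <- NULL
    if (!is.null(annotation)) enrichment <- stage("enrichment", {
        universe <- rownames(norm)
        lapply(c(A = "withinA", B = "withinB"), function(ct) {
            d <- de[[ct]]
            list(up = hypergeomEnrich(
                     intersect(d$gene[!is.na(d$direction) &
                                      d$direction == "up"], universe),
                     universe, annotation, termInfo, alpha = al["enrich"]),
                 down = hypergeomEnrich(
                     intersect(d$gene[!is.na(d$direction) &
                                      d$direction == "down"], universe),
                     universe, annotation, termInfo, alpha = al["enrich"]))
        })
    })

    networks <- stage("network", {
        lapply(c(A = "A", B = "B"), function(g) {
            sel <- design$genotype == g
            genes <- if (networkFeatures == "degs")
                degLists[[paste0("within", g)]] else rownames(norm)
            prof <- rbind(assay(norm, "logcpm")[genes, sel, drop = FALSE],
                          metabolites[, sel, drop = FALSE])
            buildCorrelationNetwork(
                prof, kind = c(rep("gene", length(genes)),
                               rep("metabolite", nrow(metabolites))),
                genotype = g, alpha = al["edge"])
        })
    })

    report <- stage("compare",
                    intersectAndClassify(networks$A, networks$B,
                                         alpha = al["edge"]))
    cent <- stage("centrality", lapply(networks, centralities))
    tauScores <- stage("tau", do.call(rbind, lapply(tau, function(t)
        tauSpecificScore(networks$A, networks$B, t))))
    summary <- stage("summary",
                     summarizeNetworks(networks$A, networks$B, report,
                                       sigMetabolites = sigMetabolites))

    manifest <- list(
        package = "diffOmicsNet",
        version = as.character(packageVersion("diffOmicsNet")),
        seed = seed, alpha = as.list(al), tau = tau,
        networkFeatures = networkFeatures,
        nGenesInput = nrow(if (is(counts, "SummarizedExperiment"))
            assay(counts, "counts") else counts),
        nGenesKept = nrow(norm), nRemoved = length(pre$removed),
        nMetabolites = nrow(metabolites),
        samples = design$sample)

    result <- list(norm = norm, removed = pre$removed, de = de,
                   degLists = degLists, anova = anova,
                   sigMetabolites = sigMetabolites,
                   enrichment = enrichment, networks = networks,
                   report = report, centralities = cent,
                   tauScores = tauScores, summary = summary,
                   manifest = manifest)
    if (!is.null(outdir)) stage("write", writeArtifacts(result, outdir))
    result
}

resolveAlpha <- function(alpha) {
    keys <- c("edge", "de", "anova", "enrich")
    if (length(alpha) == 1L && is.null(names(alpha)))
        alpha <- setNames(rep(alpha, 4L), keys)
    out <- setNames(rep(0.05, 4L), keys)
    out[names(alpha)] <- alpha
    stopifnot(all(out > 0), all(out < 1))
    out
}

writeArtifacts <- function(result, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (ct in names(result$de))
        write.table(result$de[[ct]], file.path(outdir, paste0("de_", ct, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(result$anova$metabolites,
                file.path(outdir, "anova_metabolites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(result$anova$traits))
        write.table(result$anova$traits, file.path(outdir, "anova_traits.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in names(result$networks)) {
        write.table(edges(result$networks[[g]]),
                    file.path(outdir, paste0("network_", g, "_edges.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        exportGraphML(result$networks[[g]],
                      file.path(outdir, paste0("network_", g, ".graphml")))
        write.table(result$centralities[[g]],
                    file.path(outdir, paste0("centrality_", g, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(edges(result$report),
                file.path(outdir, "differential_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(result$tauScores, file.path(outdir, "tau_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(table = cbind(quantity = rownames(result$summary$table),
                           result$summary$table),
             percentages = as.list(result$summary$percentages)),
        file.path(outdir, "network_summary.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(outdir)
}
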