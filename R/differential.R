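#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, order-preserving with respect to the input:
#' \code{q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j}, capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values on the same indexing.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFDR <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Moderated differential expression for one contrast
#'
#' Per gene, weighted least squares of logcpm on a two-group indicator
#' using the voom precision weights; residual variances are shrunk by
#' empirical-Bayes moderation, giving moderated t-statistics with
#' augmented degrees of freedom (limma lmFit/eBayes). BH q-values are
#' computed across genes; a gene is differentially expressed at q < alpha.
#'
#' Contrasts (positive log fold change means higher in the first-named
#' group):
#' \describe{
#'   \item{withinA / withinB}{minusN vs plusN inside genotype A / B.}
#'   \item{betweenAtMinusN / betweenAtPlusN}{genotype B vs A at the given
#'     nitrogen condition.}
#' }
#'
#' @param norm a \linkS4class{NormalizedOmics}.
#' @param design data.frame with columns \code{sample}, \code{genotype}
#'   (\code{"A"}/\code{"B"}), \code{condition}
#'   (\code{"minusN"}/\code{"plusN"}); defaults to \code{colData(norm)}.
#' @param contrast one of the four contrast labels above.
#' @param alpha FDR level for the DEG call.
#' @return data.frame: \code{gene}, \code{contrast}, \code{logFC},
#'   \code{t}, \code{p}, \code{q}, \code{direction} (\code{"up"} /
#'   \code{"down"} when q < alpha, else \code{NA}).
#' @export
fitGeneContrast <- function(norm, design = NULL,
                            contrast = c("withinA", "withinB",
                                         "betweenAtMinusN", "betweenAtPlusN"),
                            alpha = 0.05) {
    contrast <- match.arg(contrast)
    if (is.null(design)) design <- as.data.frame(colData(norm))
    stopifnot(all(c("genotype", "condition") %in% names(design)),
              nrow(design) == ncol(norm))
    sel <- switch(contrast,
        withinA = design$genotype == "A",
        withinB = design$genotype == "B",
        betweenAtMinusN = design$condition == "minusN",
        betweenAtPlusN = design$condition == "plusN")
    # first level = reference, so the coefficient is (first-named - reference)
    grp <- switch(contrast,
        withinA = , withinB =
            factor(design$condition[sel], levels = c("plusN", "minusN")),
        factor(design$genotype[sel], levels = c("A", "B")))
    if (nlevels(droplevels(grp)) < 2L || min(table(grp)) < 2L)
        stop("contrast '", contrast, "' needs >= 2 samples per group")
    X <- model.matrix(~ grp)
    fit <- limma::lmFit(assay(norm, "logcpm")[, sel, drop = FALSE], X,
                        weights = assay(norm, "weights")[, sel, drop = FALSE])
    fit <- limma::eBayes(fit)
    tt <- limma::topTable(fit, coef = 2L, number = Inf, sort.by = "none")
    q <- bhFDR(tt$P.Value)
    data.frame(gene = rownames(tt), contrast = contrast,
               logFC = tt$logFC, t = tt$t, p = tt$P.Value, q = q,
               direction = ifelse(q < alpha,
                                  ifelse(tt$logFC > 0, "up", "down"), NA),
               row.names = NULL)
}

#' Balanced two-way ANOVA for metabolite / trait features
#'
#' Fixed-effects genotype x nitrogen decomposition with the standard
#' balanced-design sums of squares; F = MS_effect / MS_error with p from
#' the F distribution. Cell means with standard errors and Tukey letters
#' are attached. Unbalanced input is an error.
#'
#' @param values numeric matrix (features x samples) or a single vector.
#' @param design data.frame with \code{genotype}, \code{condition} aligned
#'   to the columns of \code{values}.
#' @param alpha significance level for effects and Tukey letters.
#' @return data.frame, one row per feature: F and p for \code{G},
#'   \code{N}, \code{GxN}, per-cell means/SEs, Tukey letters (cells ordered
#'   A.minusN, A.plusN, B.minusN, B.plusN), \code{significant} (any effect
#'   p < alpha) and a \code{degenerate} flag for zero residual variance.
#' @export
twowayAnova <- function(values, design, alpha = 0.05) {
    if (is.null(dim(values)))
        values <- matrix(values, 1L, dimnames = list("feature", NULL))
    stopifnot(ncol(values) == nrow(design),
              all(c("genotype", "condition") %in% names(design)))
    G <- factor(design$genotype)
    N <- factor(design$condition, levels = c("minusN", "plusN"))
    cell <- interaction(G, N, lex.order = TRUE)  # A.minusN A.plusN B.minusN B.plusN
    tab <- table(cell)
    if (any(tab == 0L)) stop("empty genotype x condition cell")
    if (length(unique(tab)) != 1L)
        stop("unbalanced design: equal replication per cell is required")
    if (min(tab) < 2L) stop("at least two replicates per cell are required")
    n <- as.integer(tab[1L]); a <- nlevels(G); b <- nlevels(N)
    dfE <- a * b * (n - 1L)

    res <- lapply(rownames(values), function(f) {
        y <- values[f, ]
        cm <- tapply(y, cell, mean)
        gm <- tapply(y, G, mean); nm <- tapply(y, N, mean); mu <- mean(y)
        ssG <- b * n * sum((gm - mu)^2)
        ssN <- a * n * sum((nm - mu)^2)
        ssCell <- n * sum((cm - mu)^2)
        ssGN <- ssCell - ssG - ssN
        ssE <- sum((y - cm[cell])^2)
        msE <- ssE / dfE
        degenerate <- msE <= 0
        Fv <- c(G = ssG / (a - 1L), N = ssN / (b - 1L),
                GxN = ssGN / ((a - 1L) * (b - 1L))) / msE
        if (degenerate) {
            Fv <- ifelse(c(ssG, ssN, ssGN) > 0, Inf, 0)
            names(Fv) <- c("G", "N", "GxN")
        }
        pv <- pf(Fv, c(a - 1L, b - 1L, (a - 1L) * (b - 1L)), dfE,
                 lower.tail = FALSE)
        se <- sqrt(tapply(y, cell, function(z) var(z) / length(z)))
        letters <- if (degenerate) rep(NA_character_, a * b)
                   else tukeyLetters(cm, msE, dfE, n, alpha = alpha)
        data.frame(feature = f,
                   F_G = Fv[["G"]], p_G = pv[[1L]],
                   F_N = Fv[["N"]], p_N = pv[[2L]],
                   F_GxN = Fv[["GxN"]], p_GxN = pv[[3L]],
                   SS_G = ssG, SS_N = ssN, SS_GxN = ssGN, SS_E = ssE,
                   t(setNames(as.numeric(cm), paste0("mean_", names(cm)))),
                   t(setNames(as.numeric(se), paste0("se_", names(cm)))),
                   letters = paste(letters, collapse = "/"),
                   significant = any(pv < alpha, na.rm = TRUE),
                   degenerate = degenerate, row.names = NULL)
    })
    do.call(rbind, res)
}

#' Tukey HSD compact letter display
#'
#' All pairwise comparisons of cell means at level \code{alpha} using the
#' studentized range distribution; letters are assigned by the
#' insert-and-absorb algorithm: groups sharing a letter are not
#' significantly different, and the cell with the largest mean gets
#' \code{"a"}.
#'
#' @param means named vector of cell means.
#' @param msE,dfE residual mean square and its degrees of freedom.
#' @param n replicates per cell (balanced).
#' @param alpha significance level.
#' @return character vector of letter strings, aligned to \code{means}.
#' @export
tukeyLetters <- function(means, msE, dfE, n, alpha = 0.05) {
    stopifnot(dfE > 0, n >= 1, msE >= 0)
    k <- length(means)
    if (k == 1L) return("a")
    se <- sqrt(msE / n)
    sig <- matrix(FALSE, k, k)
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
        d <- abs(means[i] - means[j])
        if (d == 0) next  # equal means always share a letter
        qstat <- if (se == 0) Inf else d / se
        sig[i, j] <- sig[j, i] <-
            ptukey(qstat, k, dfE, lower.tail = FALSE) < alpha
    }
    # maximal cliques of the "not significantly different" graph
    cliques <- list()
    for (m in seq_len(2^k - 1L)) {
        mem <- which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0)
        ok <- TRUE
        if (length(mem) > 1L)
            for (i in seq_along(mem)[-1L]) for (j in seq_len(i - 1L))
                if (sig[mem[i], mem[j]]) { ok <- FALSE; break }
        if (!ok) next
        maximal <- TRUE
        for (extra in setdiff(seq_len(k), mem))
            if (!any(sig[extra, mem])) { maximal <- FALSE; break }
        if (maximal) cliques[[length(cliques) + 1L]] <- mem
    }
    # order cliques by their largest mean so the top cell letters first
    ord <- order(vapply(cliques, function(cl) max(means[cl]), 0),
                 decreasing = TRUE)
    cliques <- cliques[ord]
    out <- rep("", k)
    for (ci in seq_along(cliques))
        out[cliques[[ci]]] <- paste0(out[cliques[[ci]]], letters[ci])
    setNames(out, names(means))
}

#' Pearson correlation with an exact t-based p-value
#'
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} on \code{n - 2} degrees of
#' freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @examples
#' correlationTest(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
correlationTest <- function(x, y) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (n < 3L) stop("at least three paired observations are required")
    if (sd(x) == 0 || sd(y) == 0)
        stop("correlation undefined for a constant input")
    r <- cor(x, y)
    p <- corPValue(r, n)
    list(r = r, p = p, n = n)
}

# vectorized two-sided p for Pearson r at sample size n
corPValue <- function(r, n) {
    r <- pmin(1, pmax(-1, r))
    t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * pt(t, n - 2, lower.tail = FALSE)
}
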