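# Independent oracle implementations used to cross-check the package.
# These deliberately use different code paths from the implementation.

# --- TMM: literal trimmed weighted mean of M-values ----------------------
oracleTMM <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
    lib <- colSums(counts)
    uq <- vapply(seq_len(ncol(counts)), function(j)
        unname(quantile(counts[, j], 0.75)) / lib[j], 0)
    ref <- which.min(abs(uq - mean(uq)))
    oneFactor <- function(s) {
        keep <- counts[, s] > 0 & counts[, ref] > 0
        obs <- counts[keep, s]; rf <- counts[keep, ref]
        pO <- obs / lib[s]; pR <- rf / lib[ref]
        M <- log2(pO / pR)
        A <- (log2(pO) + log2(pR)) / 2
        v <- (lib[s] - obs) / (lib[s] * obs) + (lib[ref] - rf) / (lib[ref] * rf)
        if (max(abs(M)) < 1e-6) return(1)
        n <- length(M)
        loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
        loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
        keep2 <- rank(M) >= loM & rank(M) <= hiM &
                 rank(A) >= loA & rank(A) <= hiA
        2^(sum(M[keep2] / v[keep2], na.rm = TRUE) /
           sum(1 / v[keep2], na.rm = TRUE))
    }
    f <- vapply(seq_len(ncol(counts)), oneFactor, 0)
    f / exp(mean(log(f)))
}

# --- betweenness: exhaustive shortest-path enumeration -------------------
oracleBetweenness <- function(adj) {
    n <- nrow(adj)
    bfsDist <- function(s) {
        d <- rep(Inf, n); d[s] <- 0; frontier <- s
        while (length(frontier)) {
            nxt <- integer()
            for (v in frontier) for (w in which(adj[v, ]))
                if (d[w] == Inf) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
            frontier <- unique(nxt)
        }
        d
    }
    btw <- numeric(n)
    for (s in seq_len(n - 1)) {
        d <- bfsDist(s)
        for (t in seq(s + 1, n)) {
            if (!is.finite(d[t])) next
            paths <- list()
            grow <- function(path) {
                v <- path[length(path)]
                if (v == t) { paths[[length(paths) + 1]] <<- path; return() }
                for (w in which(adj[v, ] & d == d[v] + 1))
                    if (d[w] <= d[t]) grow(c(path, w))
            }
            grow(s)
            if (!length(paths)) next
            inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
            if (length(inner))
                for (v in inner) btw[v] <- btw[v] + 1 / length(paths)
        }
    }
    btw
}

randomGraph <- function(nNodes, pEdge = 0.35) {
    adj <- matrix(FALSE, nNodes, nNodes)
    for (i in seq_len(nNodes - 1)) for (j in seq(i + 1, nNodes))
        if (runif(1) < pEdge) adj[i, j] <- adj[j, i] <- TRUE
    adj
}

adjToEdges <- function(adj) {
    idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    data.frame(i = as.character(idx[, 1]), j = as.character(idx[, 2]))
}

# --- hypergeometric upper tail by direct enumeration ---------------------
oracleHyperTail <- function(k, N, K, n) {
    js <- k:min(n, K)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# --- balanced two-way ANOVA via R's linear-model machinery ---------------
oracleAnovaSS <- function(y, design) {
    G <- factor(design$genotype)
    N <- factor(design$condition)
    a <- anova(lm(y ~ G * N))
    c(G = a["G", "Sum Sq"], N = a["N", "Sum Sq"],
      GxN = a["G:N", "Sum Sq"], E = a["Residuals", "Sum Sq"])
}

# --- small fixtures -------------------------------------------------------
toyDesign <- function(nRep = 4) {
    d <- expand.grid(replicate = seq_len(nRep),
                     condition = c("minusN", "plusN"),
                     genotype = c("A", "B"), stringsAsFactors = FALSE)
    d$sample <- sprintf("%s_%s_%d", d$genotype, d$condition, d$replicate)
    d[, c("sample", "genotype", "condition", "replicate")]
}

# NormalizedOmics with prescribed logcpm and unit weights
makeNorm <- function(logcpm, design) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(logcpm = logcpm,
                      weights = matrix(1, nrow(logcpm), ncol(logcpm),
                                       dimnames = dimnames(logcpm))),
        colData = S4Vectors::DataFrame(design, row.names = design$sample))
    S4Vectors::metadata(se)$tmmFactors <- rep(1, ncol(logcpm))
    new("NormalizedOmics", se)
}
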