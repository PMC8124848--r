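test_that("CPM follows the counts-per-million formula and sums to 1e6", {
    m <- matrix(c(10L, 90L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
    expect_equal(as.numeric(computeCPM(m, libSizes = 100)),
                 c(1e5, 9e5))

    set.seed(11)
    m <- matrix(rpois(20, 50), 5, 4,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
    m[2, ] <- 0L  # all-zero gene stays all-zero
    cpm <- computeCPM(m)
    lib <- colSums(m)
    for (g in 1:5) for (s in 1:4)
        expect_equal(cpm[g, s], unname(m[g, s] / lib[s] * 1e6))
    expect_equal(unname(colSums(cpm)), rep(1e6, 4), tolerance = 1e-6)
    expect_equal(unname(cpm[2, ]), rep(0, 4))

    m0 <- m; m0[, 2] <- 0L
    expect_error(computeCPM(m0), "s2")
})

test_that("low-expression filter removes genes failing both clauses", {
    # libraries of ~1e6: "edge1" has cpm (2, 0) - one sample >= 1, kept;
    # "lowlow" has cpm (0, 0) - removed
    counts <- matrix(c(2L, 999998L, 0L,
                       0L, 1000000L, 0L),
                     3, 2, dimnames = list(c("edge1", "big", "lowlow"),
                                           c("s1", "s2")))
    flt <- filterLowExpression(counts)
    expect_identical(flt$removed, "lowlow")
    expect_identical(rownames(flt$counts), c("edge1", "big"))

    # oracle loop on a random toy matrix
    set.seed(21)
    m <- matrix(rpois(40, 2), 10, 4,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
    m[1, ] <- 1000L
    flt <- filterLowExpression(m)
    cpm <- computeCPM(m)
    manual <- rownames(m)[apply(cpm, 1, max) < 1 & rowSums(cpm) < ncol(m)]
    expect_identical(flt$removed, manual)
    expect_identical(rownames(flt$counts), setdiff(rownames(m), manual))

    # idempotence
    again <- filterLowExpression(flt$counts)
    expect_length(again$removed, 0)
    expect_identical(again$counts, flt$counts)
})

test_that("half-below-one CPM genes obey the conjunction rule", {
    # cpm (0.5, 0.5): below 1 everywhere and sum 1 < 2 samples -> removed
    counts <- matrix(c(1L, 1999999L, 1L, 1999999L), 2, 2,
                     dimnames = list(c("g", "rest"), c("s1", "s2")))
    cpm <- computeCPM(counts)
    expect_equal(unname(cpm["g", ]), c(0.5, 0.5))
    expect_identical(filterLowExpression(counts)$removed, "g")
})

test_that("TMM factors match the trimmed weighted-mean oracle", {
    # identical columns -> all factors 1
    m <- matrix(rep(c(5L, 10L, 50L, 100L, 7L), 3), 5, 3,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
    expect_equal(unname(tmmFactors(m)), rep(1, 3))

    # doubling a library is not composition bias
    m2 <- cbind(a = m[, 1], b = m[, 1] * 2L)
    expect_equal(unname(tmmFactors(m2)), c(1, 1))

    # random matrices with 30% of genes 4-fold inflated in sample 2
    set.seed(31)
    for (rep in 1:3) {
        cnt <- matrix(rnbinom(200 * 4, mu = 200, size = 5), 200, 4,
                      dimnames = list(sprintf("g%03d", 1:200),
                                      paste0("s", 1:4)))
        infl <- sample(200, 60)
        cnt[infl, 2] <- cnt[infl, 2] * 4L
        expect_equal(unname(tmmFactors(cnt)), unname(oracleTMM(cnt)),
                     tolerance = 1e-10)
    }

    expect_error(tmmFactors(matrix(c(0L, 0L, 1L, 2L), 2, 2,
        dimnames = list(c("g1", "g2"), c("z", "ok")))), "z")
})

test_that("TMM is invariant to rescaling one library", {
    set.seed(32)
    cnt <- matrix(rnbinom(300 * 4, mu = 150, size = 8), 300, 4,
                  dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:4)))
    f1 <- tmmFactors(cnt)
    cnt2 <- cnt; cnt2[, 3] <- cnt2[, 3] * 2L
    f2 <- tmmFactors(cnt2)
    # M and A are CPM-scale so the trim set is unchanged; only the
    # count-level precision weights move, a sub-percent effect
    expect_equal(unname(f1), unname(f2), tolerance = 0.005)
})

test_that("voom logcpm follows its formula, weights are positive", {
    set.seed(41)
    cnt <- matrix(rnbinom(200 * 8, mu = 300, size = 10), 200, 8,
                  dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
    cnt[1, 1] <- 0L
    f <- tmmFactors(cnt)
    norm <- voomTransform(cnt, factors = f)
    lib <- colSums(cnt) * f
    expected <- t(t(cnt + 0.5) / (lib + 1)) * 1e6
    expect_equal(SummarizedExperiment::assay(norm, "logcpm"),
                 log2(expected), tolerance = 1e-12)
    expect_true(all(SummarizedExperiment::assay(norm, "weights") > 0))

    # zero count at effective library size ~1e6 -> logcpm ~ -1
    lc0 <- log2((0 + 0.5) / (1e6 + 1) * 1e6)
    expect_equal(lc0, -1, tolerance = 1e-5)
})

test_that("voom logcpm is monotone in counts within a sample", {
    set.seed(42)
    cnt <- matrix(rnbinom(100 * 4, mu = 100, size = 5), 100, 4,
                  dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
    f <- rep(1, 4)
    n1 <- voomTransform(cnt, factors = f)
    cnt2 <- cnt; cnt2[7, 2] <- cnt2[7, 2] + 25L
    # keep library size fixed by compensating another gene
    cnt2[8, 2] <- cnt2[8, 2] - 25L
    n2 <- voomTransform(cnt2, factors = f)
    expect_gt(SummarizedExperiment::assay(n2, "logcpm")[7, 2],
              SummarizedExperiment::assay(n1, "logcpm")[7, 2])
})

test_that("voom precision weights track the mean-variance trend on NB data", {
    set.seed(43)
    base <- exp(rnorm(500, log(300), 1.5))
    cnt <- matrix(rnbinom(500 * 8, mu = rep(base, 8), size = 10), 500, 8,
                  dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:8)))
    norm <- voomTransform(cnt, factors = rep(1, 8))
    w <- rowMeans(SummarizedExperiment::assay(norm, "weights"))
    lc <- SummarizedExperiment::assay(norm, "logcpm")
    mu <- rowMeans(lc)
    # where shot noise dominates (low counts) weights rise with abundance
    lower <- mu <= median(mu)
    expect_gt(cor(mu[lower], w[lower], method = "spearman"), 0.3)
    # the fitted sqrt-sd trend is non-increasing over the upper half of the
    # mean range (up to lowess wiggle)
    lib <- colSums(cnt)
    sx <- mu + mean(log2(lib + 1)) - log2(1e6)
    sy <- sqrt(limma::lmFit(lc, matrix(1, 8, 1))$sigma)
    trend <- lowess(sx, sy, f = 0.5)
    up <- trend$x >= median(trend$x)
    expect_lt(max(diff(trend$y[up])), 0.01)
})

test_that("preprocessCounts chains filter, TMM and voom", {
    set.seed(44)
    d <- toyDesign()
    cnt <- matrix(rnbinom(300 * 16, mu = 200, size = 5), 300, 16,
                  dimnames = list(sprintf("g%03d", 1:300), d$sample))
    cnt[5, ] <- 0L
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = cnt),
        colData = S4Vectors::DataFrame(d, row.names = d$sample))
    pre <- preprocessCounts(se)
    expect_s4_class(pre$norm, "NormalizedOmics")
    expect_true("g005" %in% pre$removed)
    expect_equal(exp(mean(log(tmmFactorsOf(pre$norm)))), 1, tolerance = 1e-9)
})
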