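test_that("correlation network edges match a brute-force loop", {
    set.seed(10)
    prof <- matrix(rnorm(10 * 8), 10, 8,
                   dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
    prof[2, ] <- prof[1, ]  # identical profiles -> r = 1 edge
    prof[3, ] <- prof[1, ] + rnorm(8, sd = 0.05)
    net <- buildCorrelationNetwork(prof, kind = "gene", genotype = "A")
    e <- edges(net)
    expect_true(any(e$i == "f1" & e$j == "f2" & abs(e$r - 1) < 1e-12))

    # oracle: cor.test over all pairs + BH
    pairs <- t(combn(rownames(prof), 2))
    op <- apply(pairs, 1, function(pr)
        cor.test(prof[pr[1], ], prof[pr[2], ])$p.value)
    oq <- p.adjust(op, "BH")
    oracleEdges <- paste(pairs[oq < 0.05, 1], pairs[oq < 0.05, 2])
    expect_setequal(paste(e$i, e$j), oracleEdges)
    # r and p agree with cor.test per edge
    for (k in seq_len(nrow(e))) {
        ctst <- cor.test(prof[e$i[k], ], prof[e$j[k], ])
        expect_equal(e$r[k], unname(ctst$estimate), tolerance = 1e-12)
        expect_equal(e$p[k], ctst$p.value, tolerance = 1e-9)
    }
})

test_that("null profiles give an essentially empty network", {
    set.seed(11)
    prof <- matrix(rnorm(60 * 8), 60, 8,
                   dimnames = list(sprintf("f%02d", 1:60), paste0("s", 1:8)))
    net <- buildCorrelationNetwork(prof, kind = "gene", genotype = "A")
    expect_lte(nrow(edges(net)), 0.05 * choose(60, 2))
})

test_that("constant features are dropped with a warning", {
    set.seed(12)
    prof <- matrix(rnorm(5 * 8), 5, 8,
                   dimnames = list(paste0("f", 1:5), paste0("s", 1:8)))
    prof[4, ] <- 3
    expect_warning(net <- buildCorrelationNetwork(prof, "gene", "A"),
                   "constant")
    expect_false("f4" %in% nodeIds(net))
})

test_that("Fisher z edge test matches its closed form", {
    ft <- fisherZEdgeTest(0.9, 8, 0, 8)
    expect_equal(ft$z, atanh(0.9) / sqrt(2 / 5), tolerance = 1e-12)
    expect_equal(ft$z, 2.328, tolerance = 1e-3)
    expect_equal(ft$p, 0.0199, tolerance = 1e-2)

    same <- fisherZEdgeTest(0.42, 10, 0.42, 12)
    expect_equal(same$z, 0)
    expect_equal(same$p, 1)

    a <- fisherZEdgeTest(0.7, 8, -0.2, 9)
    b <- fisherZEdgeTest(-0.2, 9, 0.7, 8)
    expect_equal(a$z, -b$z)
    expect_equal(a$p, b$p)

    # |r| = 1 is clamped, not an error
    expect_true(is.finite(fisherZEdgeTest(1, 8, 0, 8)$z))
    expect_error(fisherZEdgeTest(0.5, 3, 0.5, 8), "nA")
})

test_that("identical genotype data makes every intersection edge common", {
    set.seed(13)
    prof <- matrix(rnorm(12 * 8), 12, 8,
                   dimnames = list(paste0("f", 1:12), paste0("s", 1:8)))
    prof[2, ] <- prof[1, ] + rnorm(8, sd = 0.02)
    netA <- buildCorrelationNetwork(prof, "gene", "A")
    netB <- buildCorrelationNetwork(prof, "gene", "B")
    rep <- intersectAndClassify(netA, netB)
    expect_gt(nrow(edges(rep)), 0)
    expect_true(all(edges(rep)$class == "common"))
    expect_true(all(edges(rep)$z == 0))
})

test_that("empty intersection yields an empty report", {
    set.seed(14)
    p1 <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(paste0("f", 1:6), NULL))
    p2 <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(paste0("f", 1:6), NULL))
    p1[2, ] <- p1[1, ]  # edge only in A
    netA <- buildCorrelationNetwork(p1, "gene", "A")
    netB <- buildCorrelationNetwork(p2, "gene", "B")
    rep <- intersectAndClassify(netA, netB)
    expect_equal(nrow(edges(rep)), sum(paste(edges(netA)$i, edges(netA)$j) %in%
                                       paste(edges(netB)$i, edges(netB)$j)))
})

test_that("centralities match hand values on canonical graphs", {
    path <- data.frame(i = c("a", "b"), j = c("b", "c"))
    ct <- centralities(path, vertexIds = c("a", "b", "c"))
    expect_equal(ct$degree, c(1L, 2L, 1L))
    expect_equal(ct$betweenness, c(0, 1, 0))

    k4 <- as.data.frame(t(combn(letters[1:4], 2)))
    names(k4) <- c("i", "j")
    ct4 <- centralities(k4, vertexIds = letters[1:4])
    expect_equal(ct4$degree, rep(3L, 4))
    expect_equal(ct4$betweenness, rep(0, 4))
    expect_false(any(ct4$central))  # strict > on equal means
})

test_that("betweenness equals exhaustive path enumeration on small graphs", {
    set.seed(15)
    for (rep in 1:20) {
        n <- sample(4:8, 1)
        adj <- randomGraph(n)
        e <- adjToEdges(adj)
        ct <- centralities(e, vertexIds = as.character(seq_len(n)))
        expect_equal(ct$betweenness, oracleBetweenness(adj),
                     tolerance = 1e-10)
    }
})

test_that("central flags are invariant to betweenness normalization", {
    set.seed(16)
    adj <- randomGraph(7, 0.4)
    e <- adjToEdges(adj)
    ct <- centralities(e, vertexIds = as.character(1:7))
    b <- ct$betweenness * 2 / ((7 - 1) * (7 - 2))  # normalized variant
    centralNorm <- ct$degree > mean(ct$degree) & b > mean(b)
    expect_equal(ct$central, centralNorm)
})

test_that("network refinement induces the right subgraph", {
    e <- data.frame(i = c("d1", "d1", "d2", "m1"),
                    j = c("d2", "m1", "m2", "m2"))
    ref <- refineNetwork(e, centralDegIds = c("d1"),
                         sigMetaboliteIds = c("m1", "m2"))
    expect_equal(nrow(ref$edges), 2)  # d1-m1 and m1-m2
    expect_equal(ref$degMetEdges, 1)  # only d1-m1 crosses
    # refined edges are a subset of the input
    expect_true(all(paste(ref$edges$i, ref$edges$j) %in% paste(e$i, e$j)))
    none <- refineNetwork(e, character(), c("m1", "m2"))
    expect_equal(none$degMetEdges, 0)
})

test_that("tau scores are zero for identical networks and antimonotone in tau", {
    set.seed(17)
    prof <- matrix(rnorm(10 * 8), 10, 8,
                   dimnames = list(paste0("f", 1:10), NULL))
    prof[2, ] <- prof[1, ] + rnorm(8, 0.02)
    net <- buildCorrelationNetwork(prof, "gene", "A")
    ts <- tauSpecificScore(net, net, 0.6)
    expect_true(all(ts$scoreA == 0) && all(ts$scoreB == 0))

    profB <- matrix(rnorm(10 * 8), 10, 8,
                    dimnames = list(paste0("f", 1:10), NULL))
    netB <- buildCorrelationNetwork(profB, "gene", "B")
    s6 <- tauSpecificScore(net, netB, 0.6)
    s8 <- tauSpecificScore(net, netB, 0.8)
    s99 <- tauSpecificScore(net, netB, 0.99)
    expect_true(all(s8$scoreA <= s6$scoreA))
    expect_true(all(s99$scoreA <= s8$scoreA))
    # scores never exceed the node's degree
    ct <- centralities(net)
    expect_true(all(s6$scoreA[match(ct$node, s6$node)] <= ct$degree))
})

test_that("network summary satisfies the class-additivity invariants", {
    set.seed(18)
    nG <- 15; nM <- 5
    mk <- function(shift) {
        m <- matrix(rnorm((nG + nM) * 8), nG + nM, 8,
                    dimnames = list(c(sprintf("g%02d", 1:nG),
                                      sprintf("m%02d", 1:nM)), NULL))
        m[2, ] <- m[1, ] + rnorm(8, sd = 0.1)
        m[nG + 2, ] <- m[nG + 1, ] + rnorm(8, sd = 0.1)
        m[3, ] <- m[nG + 1, ] + rnorm(8, sd = shift)
        m
    }
    kinds <- c(rep("gene", nG), rep("metabolite", nM))
    netA <- buildCorrelationNetwork(mk(0.1), kinds, "A")
    netB <- buildCorrelationNetwork(mk(0.1), kinds, "B")
    sm <- summarizeNetworks(netA, netB, sigMetabolites = "m01")
    tab <- sm$table
    for (col in c("A", "B", "intersection", "common"))
        expect_equal(tab["total", col],
                     tab["geneGene", col] + tab["metMet", col] +
                     tab["geneMet", col])
    expect_lte(tab["total", "common"], tab["total", "intersection"])
    expect_lte(tab["total", "intersection"],
               min(tab["total", "A"], tab["total", "B"]))
})
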