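test_that("normalization scales to the median total and logs", {
    m <- matrix(c(1, 2, 3, 2, 4, 6, 10, 0, 0), 3,
                dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
    norm <- normalizeCounts(m)
    # totals 6, 12, 10; median 10; hand-computed values for c1
    expect_equal(norm[, "c1"],
                 log2(1 + c(1, 2, 3) * 10 / 6), ignore_attr = TRUE)
    # doubled cell has an identical normalized profile
    expect_equal(norm[, "c1"], norm[, "c2"], ignore_attr = TRUE)
    # all-zero cells are flagged and excluded
    z <- cbind(m, c4 = c(0, 0, 0))
    nz <- normalizeCounts(z)
    expect_equal(attr(nz, "excluded_cells"), "c4")
    expect_equal(ncol(nz), 3)
    expect_error(normalizeCounts(matrix(0, 2, 2,
        dimnames = list(c("a", "b"), c("x", "y")))), "all-zero")
})

test_that("signature scores are means over present genes", {
    norm <- matrix(c(2, 4, 6, 0, 0, 0), 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
    sc <- signatureScore(norm, c("g1", "g2"))
    expect_equal(sc$score, c(3, 0))
    expect_equal(attr(sc, "n_missing"), 0)
    sc2 <- suppressWarnings(signatureScore(norm, c("g1", "missA", "missB")))
    expect_equal(attr(sc2, "n_missing"), 2)
    expect_error(signatureScore(norm, c("nope"), name = "molo"), "molo")
    # permutation invariance in gene order and linearity
    expect_equal(signatureScore(norm, c("g2", "g1"))$score, sc$score)
    expect_equal(signatureScore(2 * norm, c("g1", "g2"))$score, 2 * sc$score)
})

test_that("BH adjustment matches hand examples and stays in order", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_error(bhAdjust(c(0.5, 1.2)), "input error")
    p <- c(0.9, 0.001, 0.5, NA, 0.04)
    q <- bhAdjust(p)
    expect_true(is.na(q[4]))
    expect_equal(q[!is.na(p)], p.adjust(p[!is.na(p)], "BH"))
})

test_that("BH equals the independent oracle on 1,000 random vectors", {
    set.seed(101)
    for (i in 1:1000) {
        p <- runif(sample(1:60, 1))^sample(1:3, 1)
        expect_equal(bhAdjust(p), p.adjust(p, "BH"))
    }
    # q is monotone in the rank of p
    set.seed(5)
    p <- runif(200)
    q <- bhAdjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p))
})

test_that("self-comparison finds nothing and planted effects are found", {
    cfg <- tinySimConfig(seed = 2, genes = 700,
                         cells = c("HSC" = 100, "hibHSC" = 100))
    hx <- simulateExpression(cfg)
    counts <- SummarizedExperiment::assay(hx, "counts")
    # same cells in both groups: all log2FC exactly 0
    half <- counts[, cellCondition(hx) == "HSC"]
    de0 <- differentialExpression(cbind(half, half),
        condition = rep(c("a", "b"), each = ncol(half)),
        group_a = "a", group_b = "b")
    expect_true(all(abs(de0$log2fc[de0$tested]) < 1e-12))
    expect_equal(sum(de0$qvalue < 0.05, na.rm = TRUE), 0)
    # planted 2-fold effects at n=100 vs 100 are significant at q<0.05
    de <- differentialExpression(hx, group_a = "HSC", group_b = "hibHSC")
    planted <- S4Vectors::metadata(hx)$truth$planted_up_hsc_vs_hib
    qs <- de$qvalue[match(planted, de$gene)]
    expect_gt(mean(qs < 0.05, na.rm = TRUE), 0.95)
    expect_error(differentialExpression(hx, group_a = "HSC",
                                        group_b = "bogus"), "bogus")
})

test_that("the NB Wald test is calibrated under the null", {
    # two identically-distributed groups: type-I error near nominal
    cfg <- tinySimConfig(seed = 3, genes = 1200,
                         cells = c("HSC" = 200))
    hx <- simulateExpression(cfg)
    counts <- SummarizedExperiment::assay(hx, "counts")
    null_genes <- grepl("^Gene", rownames(counts))
    g <- rep(c("a", "b"), length.out = ncol(counts))
    de <- differentialExpression(counts[null_genes, ], condition = g,
                                 group_a = "a", group_b = "b")
    rate <- mean(de$pvalue < 0.05, na.rm = TRUE)
    n <- sum(!is.na(de$pvalue))
    ci <- qbinom(c(0.005, 0.995), n, 0.05) / n
    expect_gte(rate, ci[1])
    expect_lte(rate, ci[2])
})

test_that("DE intersection is direction-aware", {
    tab <- function(genes, q, dir)
        data.frame(gene = genes, qvalue = q, direction = dir)
    t1 <- tab(c("a", "b", "c"), c(0.01, 0.01, 0.5), c("up", "down", "up"))
    t2 <- tab(c("a", "b", "c"), c(0.02, 0.01, 0.01), c("up", "up", "up"))
    ix <- intersectDE(t1, t2)
    expect_equal(ix$common_up, "a")
    expect_equal(ix$common_down, character(0))   # b flips direction
    # disjoint significant sets
    t3 <- tab(c("a", "b"), c(0.9, 0.9), c("up", "up"))
    expect_equal(lengths(intersectDE(t1, t3)), c(common_up = 0L,
                                                 common_down = 0L))
    expect_error(intersectDE(t1, t2, q_cut = 1.5), "q_cut")
})

test_that("hypergeometric enrichment matches exact combinatorics", {
    uni <- sprintf("u%02d", 1:20)
    hit <- uni[1:5]
    e <- enrichmentTest(hit, list(s = hit), uni)
    expect_equal(e$pvalue, 1 / choose(20, 5))
    # zero overlap: upper tail includes 0, p = 1
    e0 <- enrichmentTest(uni[6:8], list(s = hit), uni)
    expect_equal(e0$pvalue, 1)
    expect_error(enrichmentTest(c("zz"), list(s = hit), uni), "universe")
    # empty-intersection sets are skipped with a note
    e2 <- enrichmentTest(hit, list(s = hit, gone = c("xx")), uni)
    expect_equal(attr(e2, "skipped"), "gone")
})

test_that("enrichment p equals a pmf-summation oracle to 1e-12", {
    set.seed(7)
    for (i in 1:50) {
        N <- sample(20:200, 1)
        uni <- sprintf("g%03d", seq_len(N))
        K <- sample(3:15, 1)
        n <- sample(3:min(30, N - 1), 1)
        set_ <- sample(uni, K)
        query <- sample(uni, n)
        p <- enrichmentTest(query, list(s = set_), uni)$pvalue
        k <- length(intersect(set_, query))
        oracle <- sum(vapply(k:min(K, n), function(j)
            choose(K, j) * choose(N - K, n - j) / choose(N, n), 0))
        expect_lt(abs(p - oracle), 1e-12)
    }
})

test_that("cell-cycle assignment handles edge cases and forced cells", {
    set.seed(31)
    norm <- matrix(abs(rnorm(100 * 20)), 100, 20,
                   dimnames = list(sprintf("g%03d", 1:100),
                                   sprintf("c%02d", 1:20)))
    s_genes <- rownames(norm)[1:5]
    g2m_genes <- rownames(norm)[6:10]
    # an all-zero cell has both scores 0 -> G1(G0)
    norm[, 1] <- 0
    ph <- assignCellCycle(norm, s_genes, g2m_genes, n_control_bins = 5,
                          seed = 1)
    expect_equal(ph$phase[1], "G1(G0)")
    # a cell expressing only G2M genes far above background -> G2M
    norm[, 2] <- 0
    norm[g2m_genes, 2] <- 50
    ph2 <- assignCellCycle(norm, s_genes, g2m_genes, n_control_bins = 5,
                           seed = 1)
    expect_equal(ph2$phase[2], "G2M")
    # phases are exhaustive and exclusive
    expect_true(all(ph2$phase %in% c("G1(G0)", "S", "G2M")))
    expect_error(assignCellCycle(norm[1:3, ], s_genes, g2m_genes,
                                 n_control_bins = 10), "control bins")
})

test_that("proliferation summary orders conditions and matches hand math", {
    norm <- matrix(c(1, 2, 3, 4), 2,
                   dimnames = list(c("p1", "p2"), c("c1", "c2")))
    ps <- proliferationSummary(norm, c("HSC", "HSC+SCF"), c("p1", "p2"))
    expect_equal(ps$mean_score[ps$condition == "HSC"], 1.5)
    expect_equal(ps$mean_score[ps$condition == "HSC+SCF"], 3.5)
    expect_true(attr(ps, "stimulated_exceed_unstimulated"))
    # identical expression in all conditions: equal means, no ordering
    norm2 <- matrix(2, 2, 4, dimnames = list(c("p1", "p2"),
                                             sprintf("c%d", 1:4)))
    ps2 <- proliferationSummary(norm2, c("HSC", "hibHSC", "HSC+SCF",
                                         "hibHSC+SCF"), c("p1", "p2"))
    expect_true(all(ps2$mean_score == 2))
    expect_false(isTRUE(attr(ps2, "stimulated_exceed_unstimulated")))
})

test_that("signature recovery: MolO ordering and proliferation pattern", {
    hx <- simulateExpression(simConfig(seed = 8))
    norm <- normalizeCounts(hx)
    gm <- S4Vectors::metadata(hx)$gene_map
    cond <- as.character(cellCondition(hx))
    molo <- signatureScore(norm, gm$molo, "molo")
    mm <- tapply(molo$score, cond, mean)
    expect_gt(mm[["HSC"]], mm[["hibHSC"]])
    expect_gt(mm[["hibHSC"]], mm[["HSC+SCF"]])
    expect_gt(mm[["hibHSC"]], mm[["hibHSC+SCF"]])
    ps <- proliferationSummary(norm, cond, gm$proliferation)
    expect_true(attr(ps, "stimulated_exceed_unstimulated"))
})
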