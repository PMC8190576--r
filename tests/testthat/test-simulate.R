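test_that("generators are bit-reproducible under a fixed seed", {
    cfg <- tinySimConfig(seed = 42)
    cfg$wells_per_arm <- 30L
    w1 <- simulateClonalCultures(cfg)
    w2 <- simulateClonalCultures(cfg)
    expect_identical(wellTracks(w1), wellTracks(w2))
    expect_identical(indexData(w1), indexData(w2))
    c1 <- simulateTransplants(cfg)
    c2 <- simulateTransplants(cfg)
    expect_identical(chimerismRecords(c1), chimerismRecords(c2))
    e1 <- simulateExpression(cfg)
    e2 <- simulateExpression(cfg)
    expect_identical(SummarizedExperiment::assay(e1, "counts"),
                     SummarizedExperiment::assay(e2, "counts"))
    f1 <- simulateColonyFlow(40, seed = 7)
    f2 <- simulateColonyFlow(40, seed = 7)
    expect_identical(colonyRecords(f1), colonyRecords(f2))
})

test_that("generator calls do not disturb the caller's RNG stream", {
    set.seed(99)
    a <- runif(2)
    set.seed(99)
    invisible(simulateColonyFlow(10, seed = 3))
    b <- runif(2)
    expect_identical(a, b)
})

test_that("degenerate configurations give empty outputs", {
    cfg <- simConfig(seed = 1, wells_per_arm = 0)
    wts <- simulateClonalCultures(cfg)
    expect_equal(nWells(wts), 0)
    expect_equal(nrow(S4Vectors::metadata(wts)$truth), 0)
    cfg2 <- simConfig(seed = 1, mice_per_arm = 0L)
    expect_equal(nrow(chimerismRecords(simulateTransplants(cfg2))), 0)
    expect_equal(nrow(colonyRecords(simulateColonyFlow(0))), 0)
})

test_that("invalid configurations raise configuration errors", {
    expect_error(simConfig(seed = 1,
        arms = within(defaultArms(), survival_prob <- survival_prob - 2)),
        "configuration error")
    expect_error(simConfig(seed = 1,
        subtype_probs = c(alpha = 0.5, beta = 0.5, gamma = 0.5,
                          delta = 0.5)), "sum to 1")
    expect_error(simConfig(seed = 1, division_hazard = -1),
                 "configuration error")
    expect_error(simulateColonyFlow(5, c(BOGUS = 1)), "unknown")
    pc <- rbind("HSC" = c(0.5, 0.2, 0.2), "hibHSC" = c(0.9, 0.05, 0.05),
                "HSC+SCF" = c(0.2, 0.4, 0.4), "hibHSC+SCF" = c(0.2, 0.4, 0.4))
    expect_error(simConfig(seed = 1, phase_composition = pc), "sum to 1")
})

test_that("certain survival without divisions leaves single live cells", {
    arms <- defaultArms()[2, ]
    arms$survival_prob <- 1
    arms$division_leak <- 0
    cfg <- simConfig(seed = 3, wells_per_arm = 50, arms = arms,
                     first_division_delay = c(meanlog = log(1e6),
                                              sdlog = 0.01))
    wts <- simulateClonalCultures(cfg)
    day7 <- wellTracks(wts)[wellTracks(wts)$day == 7, ]
    expect_true(all(day7$cell_count == 1))
})

test_that("hibernation wells do not divide before day 7 beyond the leak", {
    cfg <- simConfig(seed = 13, wells_per_arm = 2000,
                     arms = defaultArms()[c(2, 4), ])
    wts <- simulateClonalCultures(cfg)
    uf <- undividedFraction(wts, 7)
    # leak 0.008: undivided fraction among survivors stays near 99.2%
    expect_true(all(uf$pct_undivided > 97.5))
    expect_true(all(uf$pct_undivided < 100))
})

test_that("zero repopulation probability yields zero classified mice", {
    tarms <- data.frame(arm = "null", mice = 40L, repopulation_prob = 0)
    cfg <- simConfig(seed = 2, transplant_arms = tarms)
    cs <- simulateTransplants(cfg)
    expect_equal(summarizeCohort(cs)$repopulated, 0)
})

test_that("default serum-free arm recovers 62.5% repopulation on average", {
    tarms <- defaultTransplantArms()
    tarms <- tarms[tarms$arm == "hib_serumfree", ]
    fr <- vapply(1:200, function(s) {
        cs <- simulateTransplants(simConfig(seed = s,
                                            transplant_arms = tarms))
        summarizeCohort(cs)$pct_repopulated / 100
    }, numeric(1))
    se <- sqrt(0.625 * 0.375 / (24 * 200))
    expect_lt(abs(mean(fr) - 0.625), 3 * se)
})

test_that("colony generator round-trips its class labels", {
    cf <- simulateColonyFlow(50, c(GEMM = 1), seed = 5)
    expect_true(all(classifyColony(cf)$class == "GEMM"))
    # multipotent mass recovery inside the exact binomial interval
    probs <- c(MK = 0.1, GM = 0.1, GEM = 0.2, GMM = 0.3, GEMM = 0.3)
    cf2 <- simulateColonyFlow(5000, probs, seed = 6)
    mp <- sum(countLineages(cf2)$multipotent)
    ci <- qbinom(c(0.005, 0.995), 5000, 0.8)
    expect_gte(mp, ci[1])
    expect_lte(mp, ci[2])
})

test_that("null-gene NB counts match the configured moments", {
    cfg <- tinySimConfig(seed = 4, genes = 700,
                         cells = c("HSC" = 150, "hibHSC" = 150))
    hx <- simulateExpression(cfg)
    counts <- SummarizedExperiment::assay(hx, "counts")
    rd <- SummarizedExperiment::rowData(hx)
    sf <- SummarizedExperiment::colData(hx)$size_factor
    null_genes <- rownames(hx)[grepl("^Gene", rownames(hx))]
    # compare realized mean against mu0 * mean(sf) across >= 10,000 draws
    scaled <- sweep(counts[null_genes, ], 2, sf, "/")
    ratio <- rowMeans(scaled) / rd[null_genes, "base_mean"]
    expect_gt(length(scaled), 10000)
    expect_lt(abs(mean(ratio) - 1), 0.05)
    # dispersion: pooled moment estimate near the configured value
    mu <- outer(rd[null_genes, "base_mean"], sf)
    alpha <- sum((counts[null_genes, ] - mu)^2 - mu) / sum(mu^2)
    expect_lt(abs(alpha - cfg$nb_dispersion), 0.05)
})

test_that("truth labels cover every simulated unit exactly once", {
    cfg <- tinySimConfig(seed = 9)
    cfg$wells_per_arm <- 25L
    wts <- simulateClonalCultures(cfg)
    tw <- S4Vectors::metadata(wts)$truth
    expect_setequal(tw$well_id, wellData(wts)$well_id)
    expect_false(anyDuplicated(tw$well_id) > 0)
    cs <- simulateTransplants(cfg)
    tm <- S4Vectors::metadata(cs)$truth
    expect_setequal(tm$mouse_id, unique(chimerismRecords(cs)$mouse_id))
    hx <- simulateExpression(cfg)
    expect_identical(names(S4Vectors::metadata(hx)$truth$phase),
                     colnames(hx))
})

test_that("the human arm divides more but still mostly hibernates", {
    cfg <- simConfig(seed = 31, wells_per_arm = 3000, arms = humanArms())
    uf <- undividedFraction(simulateClonalCultures(cfg), 7)
    hib <- uf[uf$arm == "human_hib", ]
    # leak 0.256: about a quarter of survivors divide by day 7
    ci <- qbinom(c(0.005, 0.995), hib$n_alive, 0.256) / hib$n_alive
    div_frac <- 1 - hib$pct_undivided / 100
    expect_gte(div_frac, ci[1])
    expect_lte(div_frac, ci[2])
})
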