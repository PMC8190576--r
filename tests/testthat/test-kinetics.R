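test_that("scoreSurvival computes per-arm fractions and handles death", {
    wts <- makePlate(1000, 300, 0)
    sv <- scoreSurvival(wts, at_day = 7)
    expect_equal(sv$fraction, 0.30)
    expect_equal(sv$alive, 300)
    # all wells dead at day 1 stay dead at day 7 (absorbing)
    dead <- WellTrackSet(
        wells = data.frame(well_id = c("a", "b"), arm = "x"),
        tracks = data.frame(well_id = rep(c("a", "b"), each = 2),
                            day = rep(0:1, 2), cell_count = c(1, 0, 1, 0)))
    expect_equal(scoreSurvival(dead, 7)$fraction, 0)
    # querying before any observation is an input error naming the well
    late <- WellTrackSet(
        wells = data.frame(well_id = "w9", arm = "x"),
        tracks = data.frame(well_id = "w9", day = 5, cell_count = 1))
    expect_error(scoreSurvival(late, 2), "w9")
})

test_that("simulated survival lands inside the exact binomial interval", {
    cfg <- simConfig(seed = 11, wells_per_arm = 10000,
                     arms = within(defaultArms()[2, ],
                                   survival_prob <- 0.3))
    sv <- scoreSurvival(simulateClonalCultures(cfg), 7)
    ci <- qbinom(c(0.005, 0.995), 10000, 0.3) / 10000
    expect_gte(sv$fraction, ci[1])
    expect_lte(sv$fraction, ci[2])
})

test_that("survival fraction is non-increasing in the scoring day", {
    wts <- simulateClonalCultures(simConfig(seed = 5, wells_per_arm = 150))
    for (arm in unique(wellData(wts)$arm)) {
        fr <- vapply(0:7, function(d)
            scoreSurvival(wts, d)$fraction[scoreSurvival(wts, d)$arm == arm],
            numeric(1))
        expect_true(all(diff(fr) <= 1e-12))
    }
})

test_that("detectDivisions applies the count thresholds", {
    one <- WellTrackSet(
        wells = data.frame(well_id = "u", arm = "x"),
        tracks = data.frame(well_id = "u", day = 0:7,
                            cell_count = rep(1, 8)))
    expect_false(detectDivisions(one)$divided)
    two <- WellTrackSet(
        wells = data.frame(well_id = "v", arm = "x"),
        tracks = data.frame(well_id = "v", day = 0:3,
                            cell_count = c(1, 1, 2, 4)))
    dd <- detectDivisions(two)
    expect_true(dd$divided)
    expect_equal(dd$first_division_day, 2)
    expect_equal(dd$second_division_day, 3)
})

test_that("detectDivisions agrees with a scan-all-observations oracle", {
    for (seed in c(3, 17)) {
        wts <- makeRandomTracks(60, seed)
        dd <- detectDivisions(wts)
        tr <- wellTracks(wts)
        for (i in seq_len(nrow(dd))) {
            obs <- tr[tr$well_id == dd$well_id[i], ]
            obs <- obs[order(obs$day), ]
            f <- obs$day[obs$cell_count >= 2][1]
            s <- obs$day[obs$cell_count >= 3][1]
            expect_identical(dd$divided[i], !is.na(f))
            expect_identical(dd$first_division_day[i], as.numeric(f))
            expect_identical(dd$second_division_day[i], as.numeric(s))
        }
    }
})

test_that("division calls ignore appended post-division observations", {
    base <- data.frame(well_id = "w", day = 0:3, cell_count = c(1, 1, 2, 4))
    ext <- rbind(base, data.frame(well_id = "w", day = 4:6,
                                  cell_count = c(8, 16, 32)))
    w1 <- WellTrackSet(data.frame(well_id = "w", arm = "x"), base)
    w2 <- WellTrackSet(data.frame(well_id = "w", arm = "x"), ext)
    expect_identical(detectDivisions(w1), detectDivisions(w2))
})

test_that("clone size distribution bins alive wells", {
    wts <- WellTrackSet(
        wells = data.frame(well_id = c("a", "b", "c", "d"), arm = "x"),
        tracks = data.frame(well_id = c("a", "b", "c", "d"), day = 0,
                            cell_count = c(1, 5, 20, 100)))
    h <- cloneSizeDistribution(wts, 0, bins = c(1, 2, 10, 50, 1000))
    expect_equal(h$count, c(1, 1, 1, 1))
    expect_equal(sum(h$count), 4)
    none <- WellTrackSet(
        wells = data.frame(well_id = "a", arm = "x"),
        tracks = data.frame(well_id = "a", day = 0:1, cell_count = c(1, 0)))
    expect_equal(sum(cloneSizeDistribution(none, 1, c(1, 10))$count), 0)
    expect_error(cloneSizeDistribution(wts, 0, bins = 5), "bins")
    # identically-seeded simulations give identical histograms
    cfg <- simConfig(seed = 21, wells_per_arm = 80)
    h1 <- cloneSizeDistribution(simulateClonalCultures(cfg), 10,
                                c(1, 2, 10, 50, 1000))
    h2 <- cloneSizeDistribution(simulateClonalCultures(cfg), 10,
                                c(1, 2, 10, 50, 1000))
    expect_identical(h1, h2)
})

test_that("tertile stratification partitions wells with stable ties", {
    ix <- data.frame(well_id = sprintf("w%02d", 1:9), marker = "CD150",
                     intensity = c(9, 8, 7, 6, 5, 4, 3, 2, 1))
    st <- stratifyByIndex(ix, "CD150")
    expect_equal(as.integer(table(st$stratum)[c("high", "mid", "low")]),
                 c(3L, 3L, 3L))
    expect_equal(st$stratum[1:3], rep("high", 3))
    # equal intensities: assignment by stable well_id order
    ix$intensity <- 5
    st2 <- stratifyByIndex(ix, "CD150")
    expect_equal(st2$stratum, rep(c("high", "mid", "low"), each = 3))
    # permuting rows does not change labels
    perm <- ix[sample(nrow(ix)), ]
    st3 <- stratifyByIndex(perm, "CD150")
    expect_equal(st3$stratum[match(st2$well_id, st3$well_id)], st2$stratum)
    # 300 random intensities -> 100/100/100
    set.seed(8)
    big <- data.frame(well_id = sprintf("w%03d", 1:300), marker = "CD150",
                      intensity = runif(300))
    expect_equal(as.integer(table(stratifyByIndex(big, "CD150")$stratum)),
                 rep(100L, 3))
    # missing marker values are an input error listing wells
    ix$intensity[2] <- NA
    expect_error(stratifyByIndex(ix, "CD150"), "w02")
})

test_that("survival fold change follows the ratio rules", {
    expect_equal(survivalFoldChange(0.42, 0.10), 4.2)
    expect_equal(survivalFoldChange(0.3, 0.3), 1.0)
    expect_equal(survivalFoldChange(0, 0.2), 0)
    expect_error(survivalFoldChange(0.2, 0), "undefined")
    expect_error(survivalFoldChange(NA_real_, 0.1), "undefined")
})

test_that("undivided fraction counts surviving single cells", {
    wts <- makePlate(800, 639, 5)
    uf <- undividedFraction(wts, 7)
    expect_equal(uf$n_alive, 639)
    expect_equal(uf$n_undivided, 634)
    expect_equal(round(uf$pct_undivided, 1), 99.2)
})
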