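# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# A plate in which `n_alive` wells survive to day 7 and, of those,
# `n_divided` reach >= 2 cells; the rest of `n_total` die on day 3.
makePlate <- function(n_total, n_alive, n_divided, arm = "hib") {
    stopifnot(n_divided <= n_alive, n_alive <= n_total)
    ids <- sprintf("w%04d", seq_len(n_total))
    status <- rep(c("divided", "single", "dead"),
                  c(n_divided, n_alive - n_divided, n_total - n_alive))
    tracks <- do.call(rbind, lapply(seq_len(n_total), function(i) {
        cc <- switch(status[i],
                     divided = c(1, 1, 1, 1, 2, 2, 3, 4),
                     single = rep(1, 8),
                     dead = c(1, 1, 1, 0, 0, 0, 0, 0))
        data.frame(well_id = ids[i], day = 0:7, cell_count = cc)
    }))
    WellTrackSet(wells = data.frame(well_id = ids, arm = arm),
                 tracks = tracks)
}

# Random but invariant-respecting tracks for oracle comparisons: monotone
# growth after a division day, possible absorbing death for undivided wells.
makeRandomTracks <- function(n_wells, seed) {
    set.seed(seed)
    ids <- sprintf("r%03d", seq_len(n_wells))
    tracks <- do.call(rbind, lapply(seq_len(n_wells), function(i) {
        days <- 0:7
        fate <- sample(c("dead", "single", "grow"), 1)
        cc <- switch(fate,
            dead = { dd <- sample(1:7, 1); ifelse(days < dd, 1, 0) },
            single = rep(1, 8),
            grow = { t1 <- sample(1:6, 1)
                     pmax(1, ifelse(days < t1, 1,
                                    2^pmin(6, (days - t1 + 1)))) })
        data.frame(well_id = ids[i], day = days, cell_count = as.integer(cc))
    }))
    WellTrackSet(wells = data.frame(well_id = ids, arm = "x"),
                 tracks = tracks)
}

# One mouse's weekly chimerism rows
mouseRows <- function(id, weeks, donor, gm, b, t, arm = "armA")
    data.frame(mouse_id = id, arm = arm, week = weeks, donor_pct = donor,
               gm_pct = gm, b_pct = b, t_pct = t)

# A cohort in which exactly `n_repop` of `n` mice meet the repopulation
# criterion at week 16
makeCohort <- function(n, n_repop, arm = "armA") {
    if (n == 0)
        return(data.frame(mouse_id = character(), arm = character(),
                          week = integer(), donor_pct = numeric(),
                          gm_pct = numeric(), b_pct = numeric(),
                          t_pct = numeric()))
    do.call(rbind, lapply(seq_len(n), function(i) {
        if (i <= n_repop)
            mouseRows(sprintf("m%03d", i), c(16, 20, 24), donor = 5,
                      gm = 1, b = 2, t = 1, arm = arm)
        else
            mouseRows(sprintf("m%03d", i), c(16, 20, 24), donor = 0.4,
                      gm = 0.1, b = 0.2, t = 0.1, arm = arm)
    }))
}

# All 16 colony marker-positivity patterns at a clear margin around the
# default threshold
colonyPatterns <- function(threshold = 0.01) {
    g <- expand.grid(CD41 = c(FALSE, TRUE), Gr1 = c(FALSE, TRUE),
                     CD11b = c(FALSE, TRUE), Ter119 = c(FALSE, TRUE))
    rec <- data.frame(colony_id = sprintf("p%02d", seq_len(nrow(g))),
                      CD41 = ifelse(g$CD41, 0.3, 0.001),
                      Gr1 = ifelse(g$Gr1, 0.3, 0.001),
                      CD11b = ifelse(g$CD11b, 0.3, 0.001),
                      Ter119 = ifelse(g$Ter119, 0.3, 0.001))
    attr(rec, "pattern") <- g
    rec
}

# Hand-enumerated class oracle over a logical pattern row
colonyClassOracle <- function(cd41, gr1, cd11b, ter119) {
    gm <- gr1 && cd11b
    if (gm && cd41 && ter119) "GEMM"
    else if (gm && cd41) "GMM"
    else if (gm && ter119) "GEM"
    else if (gm) "GM"
    else if (cd41 && !gr1 && !cd11b && !ter119) "MK"
    else "other"
}

# Tiny expression config for fast tests
tinySimConfig <- function(seed = 1, genes = 700,
                          cells = c("HSC" = 40, "hibHSC" = 40,
                                    "HSC+SCF" = 25, "hibHSC+SCF" = 25), ...)
    simConfig(seed = seed, genes = genes, cells_per_condition = cells, ...)
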