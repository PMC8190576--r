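# Synthetic-data generators. Every generator draws all randomness inside
# withSeed() from the config seed (plus a fixed stream offset per generator
# so that the four simulators are independent but jointly reproducible).

#' Simulate single-HSC clonal cultures
#'
#' Generates daily cell counts for plates of single-cell cultures under the
#' configured arms. Wells hold exactly 1 cell until death (absorbing, count
#' 0) or first division; hibernation arms (\code{scf_schedule} \code{day7}
#' or \code{never}) never divide before day 7 except for the configured
#' division leak. After the first division, clone size follows a pure-birth
#' exponential \code{2*exp(24*division_hazard*t)} rounded to integer cells.
#' CD150 (and an uninformative cKit) index-sort intensity is recorded per
#' well.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return A \code{\linkS4class{WellTrackSet}}; simulation truth (per-well
#'   survival, division times, stratum) is in \code{metadata(x)$truth}.
#' @examples
#' wts <- simulateClonalCultures(simConfig(seed = 1, wells_per_arm = 12))
#' scoreSurvival(wts, at_day = 7)
#' @export
simulateClonalCultures <- function(config) {
    validateSimConfig(config)
    arms <- config$arms
    n <- config$wells_per_arm
    if (n == 0 || nrow(arms) == 0) {
        empty <- WellTrackSet(
            wells = data.frame(well_id = character(), arm = character()),
            tracks = data.frame(well_id = character(), day = integer(),
                                cell_count = integer()),
            metadata = list(truth = data.frame()))
        return(empty)
    }
    withSeed(config$seed + 101L, {
        wl <- vector("list", nrow(arms)); trl <- wl; ixl <- wl
        for (a in seq_len(nrow(arms))) {
            arm <- arms[a, ]
            ids <- sprintf("%s_w%05d", arm$arm, seq_len(n))
            survived <- stats::runif(n) < arm$survival_prob
            death_day <- ifelse(survived, NA_integer_,
                                sample.int(7L, n, replace = TRUE))
            scf_day <- switch(arm$scf_schedule,
                              day0 = 0, day7 = 7, never = Inf,
                              stop("configuration error: unknown scf_schedule '",
                                   arm$scf_schedule, "'"))
            last_day <- if (is.finite(scf_day))
                scf_day + config$follow_days_post_scf else 7
            # first division: post-SCF log-normal delay; hibernation wells
            # may divide early with the leak probability
            delay_h <- stats::rlnorm(n, config$first_division_delay[["meanlog"]],
                                     config$first_division_delay[["sdlog"]])
            t1 <- rep(Inf, n)
            if (is.finite(scf_day)) t1 <- scf_day + delay_h / 24
            if (!is.na(arm$division_leak) && arm$division_leak > 0 &&
                scf_day > 0) {
                leak <- stats::runif(n) < arm$division_leak
                t1[leak] <- pmin(t1[leak], stats::runif(sum(leak), 1, 6.5))
            }
            t1[!survived] <- Inf   # non-survivors never divide
            days <- 0:last_day
            cnt <- vapply(days, function(d) {
                x <- integer(n)
                alive <- survived | d < death_day | d == 0
                x[alive] <- 1L
                grown <- alive & d >= t1
                x[grown] <- pmax(2L, as.integer(round(
                    2 * exp(24 * config$division_hazard * (d - t1[grown])))))
                x
            }, integer(n))
            trl[[a]] <- data.frame(
                well_id = rep(ids, times = length(days)),
                day = rep(days, each = n),
                cell_count = as.vector(cnt))
            cd150 <- stats::rlnorm(n, arm$cd150_meanlog, arm$cd150_sdlog)
            ckit <- stats::rlnorm(n, log(200), 0.5)
            ixl[[a]] <- data.frame(
                well_id = rep(ids, 2),
                marker = rep(c("CD150", "cKit"), each = n),
                intensity = c(cd150, ckit))
            w <- data.frame(well_id = ids, arm = arm$arm,
                            stringsAsFactors = FALSE)
            if ("cd150_stratum" %in% names(arms))
                w$cd150_stratum <- arm$cd150_stratum
            if (!is.na(arm$gfp_prob))
                w$gfp <- stats::runif(n) < arm$gfp_prob
            w$true_survived <- survived
            w$true_first_division_day <- ifelse(is.finite(t1), t1, NA_real_)
            w$true_death_day <- death_day
            wl[[a]] <- w
        }
        wells <- do.call(rbindFill, wl)
        tracks <- do.call(rbind, trl)
        index <- do.call(rbind, ixl)
        WellTrackSet(wells = wells, tracks = tracks, index = index,
                     metadata = list(truth = wells[grep(
                         "^well_id$|^arm$|^true_", names(wells))],
                         config_seed = config$seed))
    })
}

# rbind for data.frames that may differ in optional columns
rbindFill <- function(...) {
    dfs <- list(...)
    cols <- unique(unlist(lapply(dfs, names)))
    dfs <- lapply(dfs, function(d) {
        for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
        d[cols]
    })
    do.call(rbind, dfs)
}

#' Simulate transplantation cohorts
#'
#' Draws per-mouse repopulation outcomes, donor chimerism trajectories and
#' GM/B/T lineage fractions at the configured bleed weeks. Chimerism noise
#' is Gaussian on the logit scale (a modelling choice; the measurement noise
#' law is not otherwise constrained). Non-repopulated mice stay below the
#' 1\% criterion at all weeks; delta-subtype mice lose myeloid output after
#' week 16; delayed mice first meet the criterion at weeks 20--24.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return A \code{\linkS4class{ChimerismSet}} with per-mouse truth
#'   (repopulated, subtype, delayed) in \code{metadata(x)$truth}.
#' @examples
#' cs <- simulateTransplants(simConfig(seed = 1))
#' summarizeCohort(cs)
#' @export
simulateTransplants <- function(config) {
    validateSimConfig(config)
    tarms <- config$transplant_arms
    if (!is.null(config$mice_per_arm)) tarms$mice <- config$mice_per_arm
    if (nrow(tarms) == 0 || all(tarms$mice == 0)) {
        return(ChimerismSet(
            records = data.frame(mouse_id = character(), arm = character(),
                                 week = integer(), donor_pct = numeric(),
                                 gm_pct = numeric(), b_pct = numeric(),
                                 t_pct = numeric()),
            metadata = list(truth = data.frame())))
    }
    weeks <- config$weeks
    subtypes <- names(config$subtype_probs)
    withSeed(config$seed + 202L, {
        recs <- list(); truths <- list()
        for (a in seq_len(nrow(tarms))) {
            arm <- tarms[a, ]
            if (arm$mice == 0) next
            ids <- sprintf("%s_m%04d", arm$arm, seq_len(arm$mice))
            rep_ <- stats::runif(arm$mice) < arm$repopulation_prob
            subtype <- ifelse(rep_, sample(subtypes, arm$mice, replace = TRUE,
                                           prob = config$subtype_probs),
                              NA_character_)
            delayed <- rep_ & stats::runif(arm$mice) < config$delayed_prob &
                subtype != "delta"   # delta mice lose the myeloid criterion
            delayed[is.na(delayed)] <- FALSE
            # M:L ratio ranges per subtype keep every lineage above the 0.5%
            # threshold at the configured donor levels
            ml <- rep(NA_real_, arm$mice)
            ml[which(subtype == "alpha")] <-
                exp(stats::runif(sum(subtype == "alpha", na.rm = TRUE),
                                 log(2.2), log(6)))
            ml[which(subtype == "beta")] <-
                exp(stats::runif(sum(subtype == "beta", na.rm = TRUE),
                                 log(0.3), log(2)))
            gd <- which(subtype %in% c("gamma", "delta"))
            ml[gd] <- exp(stats::runif(length(gd), log(0.08), log(0.24)))
            base_logit <- stats::qlogis(config$chimerism_level[["mean"]] / 100)
            donor0 <- 100 * stats::plogis(stats::rnorm(
                arm$mice, base_logit, config$chimerism_level[["sd"]]))
            donor0 <- pmax(10, donor0)   # repopulated mice are robustly >1%
            for (i in seq_len(arm$mice)) {
                if (rep_[i]) {
                    jitter <- stats::rnorm(length(weeks), 0, 0.15)
                    donor <- 100 * stats::plogis(
                        stats::qlogis(donor0[i] / 100) + jitter)
                    if (delayed[i]) donor[weeks <= 16] <-
                        stats::runif(sum(weeks <= 16), 0.1, 0.9)
                    mlw <- ml[i] * exp(stats::rnorm(length(weeks), 0, 0.1))
                    m_frac <- mlw / (1 + mlw)
                    gm <- donor * m_frac
                    b <- donor * (1 - m_frac) * 0.6
                    t <- donor * (1 - m_frac) * 0.4
                    if (!is.na(subtype[i]) && subtype[i] == "delta")
                        gm[weeks > 16] <- stats::runif(sum(weeks > 16), 0, 0.3)
                } else {
                    donor <- stats::runif(length(weeks), 0, 0.8)
                    gm <- donor * 0.3; b <- donor * 0.4; t <- donor * 0.3
                }
                recs[[length(recs) + 1L]] <- data.frame(
                    mouse_id = ids[i], arm = arm$arm, week = weeks,
                    donor_pct = donor, gm_pct = gm, b_pct = b, t_pct = t)
            }
            truths[[length(truths) + 1L]] <- data.frame(
                mouse_id = ids, arm = arm$arm, true_repopulated = rep_,
                true_subtype = subtype, true_delayed = delayed,
                true_ml_ratio = ml, stringsAsFactors = FALSE)
        }
        ChimerismSet(records = do.call(rbind, recs),
                     metadata = list(truth = do.call(rbind, truths),
                                     config_seed = config$seed))
    })
}

#' Simulate colony flow-marker records
#'
#' Samples a lineage class per colony and draws marker positivity fractions
#' consistent with it: class markers uniformly above the positivity
#' threshold, the rest uniformly below half the threshold.
#'
#' @param n_colonies number of colonies.
#' @param class_probs named probabilities over \code{MK}, \code{GM},
#'   \code{GEM}, \code{GMM}, \code{GEMM}; must sum to 1.
#' @param seed integer seed.
#' @param threshold positivity threshold (default 0.01).
#' @return A \code{\linkS4class{ColonyFlowSet}} with true classes in
#'   \code{metadata(x)$truth}.
#' @examples
#' cf <- simulateColonyFlow(20, c(GM = 0.5, GEMM = 0.5), seed = 1)
#' table(classifyColony(cf)$class)
#' @export
simulateColonyFlow <- function(n_colonies,
                               class_probs = c(MK = 0.05, GM = 0.15,
                                               GEM = 0.15, GMM = 0.25,
                                               GEMM = 0.40),
                               seed = 1L, threshold = 0.01) {
    classes <- c("MK", "GM", "GEM", "GMM", "GEMM")
    if (!all(names(class_probs) %in% classes))
        stop("configuration error: unknown colony class label: ",
             paste(setdiff(names(class_probs), classes), collapse = ", "))
    if (abs(sum(class_probs) - 1) > 1e-8)
        stop("configuration error: class_probs must sum to 1")
    marker_sets <- list(
        MK = "CD41", GM = c("Gr1", "CD11b"),
        GEM = c("Gr1", "CD11b", "Ter119"), GMM = c("Gr1", "CD11b", "CD41"),
        GEMM = c("Gr1", "CD11b", "CD41", "Ter119"))
    if (n_colonies == 0) {
        rec <- data.frame(colony_id = character(), CD41 = numeric(),
                          Gr1 = numeric(), CD11b = numeric(),
                          Ter119 = numeric())
        return(ColonyFlowSet(rec, threshold,
                             metadata = list(truth = data.frame())))
    }
    withSeed(seed + 303L, {
        cls <- sample(names(class_probs), n_colonies, replace = TRUE,
                      prob = class_probs)
        ids <- sprintf("col%05d", seq_len(n_colonies))
        m <- matrix(stats::runif(n_colonies * 4, 0, threshold / 2),
                    n_colonies, 4, dimnames = list(NULL, .COLONY_MARKERS))
        for (i in seq_len(n_colonies)) {
            pos <- marker_sets[[cls[i]]]
            m[i, pos] <- stats::runif(length(pos), 0.05, 0.6)
        }
        rec <- data.frame(colony_id = ids, as.data.frame(m))
        ColonyFlowSet(rec, threshold,
                      metadata = list(
                          truth = data.frame(colony_id = ids,
                                             true_class = cls)))
    })
}

#' Simulate the four-condition single-cell expression experiment
#'
#' Draws gene x cell negative-binomial counts for the four culture
#' conditions. Per-gene baseline means are log-normal; condition effects are
#' applied multiplicatively from the planted-effect design (hibernation
#' program, shared and arm-specific SCF responses, MolO-style identity
#' gradient); each cell is assigned a true cell-cycle phase from the
#' per-condition composition and phase-marker genes (S, G2M lists) are
#' boosted \code{2^phase_log2_boost}-fold in cells of the matching phase.
#' Cell-specific size factors are log-normal.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return A \code{\linkS4class{HibExperiment}}; \code{rowData} carries the
#'   per-gene planted log2 effects per comparison, \code{colData} the true
#'   phase, and \code{metadata(x)$gene_map} the gene map.
#' @examples
#' hx <- simulateExpression(simConfig(seed = 1, genes = 600,
#'     cells_per_condition = c("HSC" = 20, "hibHSC" = 20,
#'                             "HSC+SCF" = 10, "hibHSC+SCF" = 10)))
#' hx
#' @export
simulateExpression <- function(config) {
    validateSimConfig(config)
    gm <- config$gene_map
    genes <- gm$gene_names
    G <- length(genes)
    cpc <- config$cells_per_condition
    conds <- rep(names(cpc), times = cpc)
    n_cells <- length(conds)
    if (n_cells == 0) stop("no cells configured")
    e <- config$planted_log2fc
    L <- matrix(0, G, 4, dimnames = list(genes, HIB_CONDITIONS))
    L[gm$hib_up, c("hibHSC", "hibHSC+SCF")] <- e
    L[gm$hib_down, c("hibHSC", "hibHSC+SCF")] <-
        L[gm$hib_down, c("hibHSC", "hibHSC+SCF")] - e
    L[gm$scf_common_down, c("HSC+SCF", "hibHSC+SCF")] <-
        L[gm$scf_common_down, c("HSC+SCF", "hibHSC+SCF")] - e
    L[gm$scf_up_hsc_only, "HSC+SCF"] <- L[gm$scf_up_hsc_only, "HSC+SCF"] + e
    L[gm$scf_up_hib_only, "hibHSC+SCF"] <-
        L[gm$scf_up_hib_only, "hibHSC+SCF"] + e
    # MolO identity gradient: small per-gene decrements that shift the
    # 40-gene average score (HSC > hibHSC > stimulated) while staying below
    # per-gene significance
    molo_grad <- c("HSC" = 0, "hibHSC" = -0.05, "HSC+SCF" = -0.20,
                   "hibHSC+SCF" = -0.30)
    L[gm$molo, ] <- sweep(L[gm$molo, , drop = FALSE], 2,
                          molo_grad[colnames(L)], "+")
    special <- unique(c(gm$scf_common_up, gm$scf_common_down, gm$hib_up,
                        gm$hib_down, gm$scf_up_hsc_only, gm$scf_up_hib_only,
                        gm$molo))
    withSeed(config$seed + 404L, {
        mu0 <- stats::rlnorm(G, log(config$nb_mean_baseline), 1.0)
        names(mu0) <- genes
        # planted/signature genes represent well-detected transcripts
        mu0[special] <- stats::rlnorm(length(special), log(10), 0.5)
        phases <- colnames(config$phase_composition)
        phase <- character(n_cells)
        for (cd in unique(conds)) {
            i <- conds == cd
            phase[i] <- sample(phases, sum(i), replace = TRUE,
                               prob = config$phase_composition[cd, ])
        }
        sf <- stats::rlnorm(n_cells, 0, 0.3)
        cond_idx <- match(conds, HIB_CONDITIONS)
        mu <- mu0 * 2^L[, cond_idx, drop = FALSE]
        boost <- 2^config$phase_log2_boost
        s_idx <- match(gm$s_genes, genes)
        g2m_idx <- match(gm$g2m_genes, genes)
        mu[s_idx, phase == "S"] <- mu[s_idx, phase == "S"] * boost
        mu[g2m_idx, phase == "G2M"] <- mu[g2m_idx, phase == "G2M"] * boost
        mu <- sweep(mu, 2, sf, "*")
        counts <- matrix(stats::rnbinom(G * n_cells, mu = mu,
                                        size = 1 / config$nb_dispersion),
                         G, n_cells)
        dimnames(counts) <- list(genes, sprintf("cell%04d", seq_len(n_cells)))
        rd <- S4Vectors::DataFrame(
            gene = genes,
            base_mean = mu0,
            in_molo = genes %in% gm$molo,
            in_s = genes %in% gm$s_genes,
            in_g2m = genes %in% gm$g2m_genes,
            planted_lfc_hsc_vs_hib = L[, "hibHSC"] - L[, "HSC"],
            planted_lfc_hsc_vs_hscscf = L[, "HSC+SCF"] - L[, "HSC"],
            planted_lfc_hib_vs_hibscf = L[, "hibHSC+SCF"] - L[, "hibHSC"],
            row.names = genes)
        hx <- HibExperiment(counts, conds, rowData = rd)
        SummarizedExperiment::colData(hx)$true_phase <- phase
        SummarizedExperiment::colData(hx)$size_factor <- sf
        S4Vectors::metadata(hx) <- list(
            gene_map = gm, config_seed = config$seed,
            truth = list(
                planted_up_hsc_vs_hib = gm$hib_up,
                planted_down_hsc_vs_hib = gm$hib_down,
                planted_common_up_scf = gm$scf_common_up,
                planted_common_down_scf = gm$scf_common_down,
                phase = stats::setNames(phase, colnames(counts))))
        hx
    })
}
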