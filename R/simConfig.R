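# Simulation configuration and the default gene map.

#' Default culture arms for the clonal simulation
#'
#' Four mouse arms crossing serum supplementation with SCF schedule, the
#' standard design of the hibernation experiment: SCF either present from
#' day 0 or added on day 7 after a 7-day hibernation period in IL-11 alone.
#' Day-7 survival probabilities reflect the observed resilience ordering
#' (20--40\% survival without SCF, higher with SCF); hibernation arms carry a
#' small "division leak" -- the rare fraction of wells that divide before any
#' SCF exposure.
#'
#' @return data.frame with one row per arm: \code{arm}, \code{serum},
#'   \code{scf_schedule} (\code{day0}/\code{day7}/\code{never}),
#'   \code{species}, \code{survival_prob}, \code{division_leak},
#'   \code{cd150_meanlog}, \code{cd150_sdlog}, \code{gfp_prob}.
#' @export
defaultArms <- function() {
    data.frame(
        arm = c("serum_scf", "serum_hib", "serumfree_scf", "serumfree_hib"),
        serum = c(TRUE, TRUE, FALSE, FALSE),
        scf_schedule = c("day0", "day7", "day0", "day7"),
        species = "mouse",
        survival_prob = c(0.65, 0.30, 0.60, 0.25),
        division_leak = c(NA, 0.008, NA, 0.008),
        cd150_meanlog = log(300), cd150_sdlog = 0.5,
        gfp_prob = NA_real_,
        stringsAsFactors = FALSE)
}

#' CD150-stratified culture arms
#'
#' Two serum-free hibernation arms in which wells are prospectively sorted as
#' CD150-high or CD150-mid, with day-7 survival probabilities 0.42 and 0.10
#' (the observed 4.2-fold survival advantage of CD150-high cells). Index
#' intensities are drawn from well-separated log-normals so that a simple
#' threshold on recorded CD150 intensity recovers the sorted stratum.
#'
#' @return data.frame in the format of \code{\link{defaultArms}}, plus a
#'   \code{cd150_stratum} column.
#' @export
cd150StratumArms <- function() {
    data.frame(
        arm = c("cd150_high", "cd150_mid"),
        serum = FALSE,
        scf_schedule = "day7",
        species = "mouse",
        survival_prob = c(0.42, 0.10),
        division_leak = 0.008,
        cd150_meanlog = c(log(1200), log(250)),
        cd150_sdlog = 0.3,
        gfp_prob = NA_real_,
        cd150_stratum = c("high", "mid"),
        stringsAsFactors = FALSE)
}

#' Human cord-blood arms
#'
#' Human HSCs hibernate less tightly than mouse LT-HSCs: lower day-7
#' survival and a substantial division leak (about a quarter of surviving
#' wells divide by day 5--7 even without SCF). Species is a parameter of the
#' same machinery, not a separate code path.
#'
#' @return data.frame in the format of \code{\link{defaultArms}}.
#' @export
humanArms <- function() {
    data.frame(
        arm = c("human_scf", "human_hib"),
        serum = FALSE,
        scf_schedule = c("day0", "never"),
        species = "human",
        survival_prob = c(0.60, 0.40),
        division_leak = c(NA, 0.256),
        cd150_meanlog = log(300), cd150_sdlog = 0.5,
        gfp_prob = NA_real_,
        stringsAsFactors = FALSE)
}

#' Default transplantation arms
#'
#' Repopulation probabilities follow the observed cohort outcomes: 15/24
#' serum-free hibernation recipients, 13/29 serum hibernation recipients and
#' 33/69 fresh-HSC recipients met the repopulation criterion.
#'
#' @return data.frame with columns \code{arm}, \code{mice},
#'   \code{repopulation_prob}.
#' @export
defaultTransplantArms <- function() {
    data.frame(
        arm = c("fresh", "hib_serum", "hib_serumfree"),
        mice = c(69L, 29L, 24L),
        repopulation_prob = c(33 / 69, 13 / 29, 0.625),
        stringsAsFactors = FALSE)
}

#' Default gene map for the expression simulator
#'
#' Lays out named marker genes, planted differential-expression sets and
#' signature gene lists over a transcriptome of \code{genes} genes:
#' \itemize{
#'   \item \code{scf_common_up}: 13 cell-cycle entry genes shared by both
#'     SCF responses -- the union of the S-phase (6) and G2/M (7) marker
#'     lists, including Mcm2/Mcm4/Mcm10/Rad51/Rad51ap1.
#'   \item \code{scf_common_down}: 14 genes down-regulated upon SCF in both
#'     arms (immediate-early / developmental signalling).
#'   \item \code{hib_up} (116) and \code{hib_down} (138): the
#'     hibernation-specific program relative to fresh HSCs, including the
#'     named stress-response (Ier3, Pdcd1lg2, Lyz1, Lrrc8a) and AP-1 / MolO
#'     members (Jun, Fos, Ncor2, Cish, Vwf, Sult1a1, Gimap1).
#'   \item \code{scf_up_hsc_only} (Mif, Txn1, ...): SCF targets induced only
#'     in fresh HSCs; \code{scf_up_hib_only}: hibernation-specific SCF
#'     responders.
#'   \item \code{molo}: 40-gene HSC-identity (MolO-style) signature; the
#'     packaged list is a synthetic reconstruction (see the methods
#'     vignette) and user-overridable.
#' }
#'
#' @param genes total number of genes (default 5000); must exceed the number
#'   of special genes.
#' @return list with \code{gene_names} and one character vector per set,
#'   plus \code{s_genes}, \code{g2m_genes}, \code{proliferation}.
#' @export
defaultGeneMap <- function(genes = 5000L) {
    s_genes <- c("Mcm2", "Mcm4", "Mcm10", "Rad51", "Rad51ap1", "Pcna")
    g2m_genes <- c("Ccnb1", "Cdk1", "Top2a", "Mki67", "Aurka", "Bub1", "Plk1")
    scf_common_down <- c("Dusp1", "Egr1", "Fosb", "Klf2", "Klf4", "Socs3",
                         "Btg2", "Ier2", "Nr4a1", "Zfp36", "Sfrp1", "Mecom",
                         "Pbx1", "Msi2")
    hib_up <- c("Ier3", "Pdcd1lg2", "Lyz1", "Lrrc8a",
                sprintf("HibUp%03d", seq_len(112)))
    hib_down <- c("Jun", "Fos", "Ncor2", "Cish", "Vwf", "Sult1a1", "Gimap1",
                  sprintf("HibDn%03d", seq_len(131)))
    scf_up_hsc_only <- c("Mif", "Txn1", sprintf("HscScf%02d", seq_len(4)))
    scf_up_hib_only <- sprintf("HibScf%02d", seq_len(6))
    molo <- c("Procr", "Slamf1", "Hlf", "Meis1", "Fgd5", "Mllt3", "Pdzk1ip1",
              "Gata2", "Mycn", "Ltb", "Sult1a1", "Gimap1", "Vwf",
              sprintf("Molo%02d", seq_len(27)))
    special <- unique(c(s_genes, g2m_genes, scf_common_down, hib_up, hib_down,
                        scf_up_hsc_only, scf_up_hib_only, molo))
    if (genes <= length(special))
        stop("'genes' must exceed the ", length(special), " mapped genes")
    gene_names <- c(special,
                    sprintf("Gene%04d", seq_len(genes - length(special))))
    list(gene_names = gene_names,
         s_genes = s_genes, g2m_genes = g2m_genes,
         scf_common_up = c(s_genes, g2m_genes),
         scf_common_down = scf_common_down,
         hib_up = hib_up, hib_down = hib_down,
         scf_up_hsc_only = scf_up_hsc_only,
         scf_up_hib_only = scf_up_hib_only,
         molo = molo,
         proliferation = c(s_genes, g2m_genes))
}

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic-data generator. The
#' defaults are the study conditions of the hibernation experiment: arm
#' survival probabilities, the 0.8\% hibernation division leak, the cohort
#' repopulation probabilities, the four-condition cell numbers
#' (165/106/63/127), and the planted expression program.
#'
#' @param seed integer seed; every generator call derives its randomness
#'   from it.
#' @param wells_per_arm wells per culture arm.
#' @param arms culture arm table, see \code{\link{defaultArms}}.
#' @param division_hazard per-cell per-hour division rate after the first
#'   division; clone counts grow as \code{2*exp(24*division_hazard*days)}.
#' @param first_division_delay \code{c(meanlog, sdlog)} of the log-normal
#'   delay (hours) from SCF exposure to the first division.
#' @param follow_days_post_scf days of daily counting after SCF addition.
#' @param mice_per_arm if not \code{NULL}, overrides the per-arm mouse
#'   numbers in \code{transplant_arms}.
#' @param transplant_arms transplant arm table, see
#'   \code{\link{defaultTransplantArms}}.
#' @param weeks bleed weeks post-transplant.
#' @param chimerism_level \code{c(mean, sd)}: mean donor fraction (on the
#'   percent scale) among repopulated mice and the SD of its logit.
#' @param subtype_probs probabilities over the alpha/beta/gamma/delta HSC
#'   subtypes (must sum to 1).
#' @param delayed_prob probability that a repopulated mouse first meets the
#'   criterion only at weeks 20--24.
#' @param genes number of genes in the expression simulation.
#' @param cells_per_condition named integer vector over the four conditions.
#' @param nb_mean_baseline median of the per-gene baseline negative-binomial
#'   mean.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param phase_composition 4 x 3 matrix of per-condition G1(G0)/S/G2M
#'   probabilities; rows must sum to 1.
#' @param phase_log2_boost log2 expression boost of S (G2M) marker genes in
#'   S (G2M) cells.
#' @param planted_log2fc log2 fold change planted on the hibernation-program
#'   and SCF-response gene sets.
#' @param gene_map gene map, see \code{\link{defaultGeneMap}}.
#' @return A validated list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, wells_per_arm = 10)
#' cfg$arms$survival_prob
#' @export
simConfig <- function(seed = 1L,
                      wells_per_arm = 96L,
                      arms = defaultArms(),
                      division_hazard = 0.03,
                      first_division_delay = c(meanlog = log(30),
                                               sdlog = 0.35),
                      follow_days_post_scf = 10L,
                      mice_per_arm = NULL,
                      transplant_arms = defaultTransplantArms(),
                      weeks = c(4L, 8L, 16L, 20L, 24L),
                      chimerism_level = c(mean = 30, sd = 0.8),
                      subtype_probs = c(alpha = 0.25, beta = 0.45,
                                        gamma = 0.20, delta = 0.10),
                      delayed_prob = 0.08,
                      genes = 5000L,
                      cells_per_condition = c("HSC" = 165L, "hibHSC" = 106L,
                                              "HSC+SCF" = 63L,
                                              "hibHSC+SCF" = 127L),
                      nb_mean_baseline = 8,
                      nb_dispersion = 0.25,
                      phase_composition = NULL,
                      phase_log2_boost = 5,
                      planted_log2fc = 1,
                      gene_map = NULL) {
    # tolerate YAML-parsed lists for the vector-valued fields
    cells_per_condition <- unlist(cells_per_condition)
    chimerism_level <- unlist(chimerism_level)
    first_division_delay <- unlist(first_division_delay)
    subtype_probs <- unlist(subtype_probs)
    weeks <- unlist(weeks)
    if (is.null(phase_composition)) {
        phase_composition <- rbind(
            "HSC"        = c(0.92, 0.04, 0.04),
            "hibHSC"     = c(0.92, 0.04, 0.04),
            "HSC+SCF"    = c(0.20, 0.42, 0.38),
            "hibHSC+SCF" = c(0.20, 0.42, 0.38))
        colnames(phase_composition) <- c("G1(G0)", "S", "G2M")
    }
    if (is.null(gene_map)) gene_map <- defaultGeneMap(genes)
    cfg <- list(seed = as.integer(seed), wells_per_arm = as.integer(wells_per_arm),
        arms = arms, division_hazard = division_hazard,
        first_division_delay = first_division_delay,
        follow_days_post_scf = as.integer(follow_days_post_scf),
        mice_per_arm = mice_per_arm, transplant_arms = transplant_arms,
        weeks = as.integer(weeks), chimerism_level = chimerism_level,
        subtype_probs = subtype_probs, delayed_prob = delayed_prob,
        genes = as.integer(genes),
        cells_per_condition = cells_per_condition,
        nb_mean_baseline = nb_mean_baseline, nb_dispersion = nb_dispersion,
        phase_composition = phase_composition,
        phase_log2_boost = phase_log2_boost,
        planted_log2fc = planted_log2fc, gene_map = gene_map)
    class(cfg) <- "SimConfig"
    validateSimConfig(cfg)
    cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a \code{SimConfig} list.
#' @return \code{cfg}, invisibly; stops with a configuration error otherwise.
#' @export
validateSimConfig <- function(cfg) {
    stopifnot(is.list(cfg))
    probs <- c(cfg$arms$survival_prob,
               cfg$arms$division_leak[!is.na(cfg$arms$division_leak)],
               cfg$transplant_arms$repopulation_prob,
               cfg$subtype_probs, cfg$delayed_prob)
    if (any(probs < 0 | probs > 1))
        stop("configuration error: probabilities must lie in [0,1]")
    if (cfg$wells_per_arm < 0 || any(cfg$transplant_arms$mice < 0))
        stop("configuration error: negative unit counts")
    if (cfg$division_hazard < 0)
        stop("configuration error: negative division hazard")
    if (abs(sum(cfg$subtype_probs) - 1) > 1e-8)
        stop("configuration error: subtype_probs must sum to 1")
    pc <- cfg$phase_composition
    if (any(pc < 0) || any(abs(rowSums(pc) - 1) > 1e-8))
        stop("configuration error: phase_composition rows must sum to 1")
    if (!all(rownames(pc) %in% HIB_CONDITIONS))
        stop("configuration error: phase_composition rows must be conditions")
    if (cfg$nb_mean_baseline <= 0 || cfg$nb_dispersion <= 0)
        stop("configuration error: NB parameters must be positive")
    if (!all(names(cfg$cells_per_condition) %in% HIB_CONDITIONS))
        stop("configuration error: unknown condition in cells_per_condition")
    # planted sets must not carry contradictory effects on one gene for the
    # same comparison
    gm <- cfg$gene_map
    if (length(intersect(gm$hib_up, gm$hib_down)))
        stop("configuration error: gene planted both up and down (HSC vs hibHSC)")
    if (length(intersect(gm$scf_common_up, gm$scf_common_down)))
        stop("configuration error: gene planted both up and down (SCF response)")
    invisible(cfg)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All generator randomness flows through this.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
    expr
}
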