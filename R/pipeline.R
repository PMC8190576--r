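# End-to-end orchestration: simulate -> analyze -> report from one config.

.defaultRunConfig <- function() {
    list(seed = 1L,
         stages = c("simulate", "kinetics", "transplant", "colonies",
                    "expression"),
         q_cut = 0.05,
         positivity_threshold = 0.01,
         repopulation_window = c(16, 24),
         survival_day = 7,
         stratify_marker = "CD150",
         stratify_scheme = "tertile",
         n_colonies = 200L,
         simulation = list())
}

#' Run the full hibernation-culture analysis pipeline
#'
#' Orchestrates simulation and every analysis stage from one configuration
#' (an R list or a YAML file) and writes all stage outputs plus a run
#' manifest (package version, seed, config hash, file checksums) to
#' \code{outdir}. Identical config and seed reproduce byte-identical
#' outputs.
#'
#' @param config list or path to a YAML file; unspecified entries take the
#'   documented defaults (seed 1, q_cut 0.05, positivity 0.01, repopulation
#'   window 16--24, survival day 7, tertile CD150 stratification). Entries
#'   under \code{simulation} are passed to \code{\link{simConfig}}.
#' @param outdir output directory (created if needed).
#' @return list with the per-stage results, invisibly; side effect: TSV/MTX
#'   outputs and \code{manifest.json} in \code{outdir}.
#' @examples
#' \donttest{
#' out <- runPipeline(list(seed = 7,
#'     simulation = list(wells_per_arm = 24, genes = 800,
#'         cells_per_condition = c("HSC" = 30, "hibHSC" = 30,
#'                                 "HSC+SCF" = 20, "hibHSC+SCF" = 20))),
#'     outdir = tempfile("hibrun"))
#' }
#' @export
runPipeline <- function(config = list(), outdir) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(.defaultRunConfig(), config)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    res <- list(config = cfg)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    scfg <- do.call(simConfig, c(list(seed = cfg$seed), cfg$simulation))

    if ("simulate" %in% cfg$stages) stage("simulate", {
        res$tracks <- simulateClonalCultures(scfg)
        res$chimerism <- simulateTransplants(scfg)
        res$colonies <- simulateColonyFlow(cfg$n_colonies, seed = cfg$seed,
                                           threshold = cfg$positivity_threshold)
        res$expression <- simulateExpression(scfg)
        writeWellTracks(res$tracks, outdir)
        writeChimerism(res$chimerism, outdir)
        writeColonies(res$colonies, outdir)
        writeCounts(res$expression, outdir)
        jsonlite::write_json(list(
            wells = metadata(res$tracks)$truth,
            mice = metadata(res$chimerism)$truth,
            colonies = metadata(res$colonies)$truth),
            file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }) else stage("load", {
        res$tracks <- readWellTracks(outdir)
        res$chimerism <- readChimerism(outdir)
        res$colonies <- readColonies(outdir, cfg$positivity_threshold)
        res$expression <- readCounts(outdir)
    })

    if ("kinetics" %in% cfg$stages) stage("kinetics", {
        surv <- scoreSurvival(res$tracks, cfg$survival_day)
        undiv <- undividedFraction(res$tracks, cfg$survival_day)
        .writeTsv(merge(surv, undiv, by = "arm"),
                  file.path(outdir, "survival_summary.tsv"))
        div <- detectDivisions(res$tracks)
        .writeTsv(div, file.path(outdir, "divisions.tsv"))
        sizes <- cloneSizeDistribution(res$tracks,
            max(wellTracks(res$tracks)$day), bins = c(1, 2, 10, 50, 1000))
        .writeTsv(sizes, file.path(outdir, "clone_sizes.tsv"))
        strata <- stratifyByIndex(res$tracks, cfg$stratify_marker,
                                  cfg$stratify_scheme)
        .writeTsv(strata, file.path(outdir, "strata.tsv"))
        res$survival <- surv
    })

    if ("transplant" %in% cfg$stages) stage("transplant", {
        rp <- classifyRepopulation(res$chimerism, cfg$repopulation_window)
        .writeTsv(rp, file.path(outdir, "repopulation.tsv"))
        st <- callSubtypes(res$chimerism, cfg$repopulation_window)
        .writeTsv(st, file.path(outdir, "subtypes.tsv"))
        cs <- summarizeCohort(res$chimerism, cfg$repopulation_window)
        .writeTsv(cs, file.path(outdir, "cohort_summary.tsv"))
        res$cohort <- cs
    })

    if ("colonies" %in% cfg$stages) stage("colonies", {
        cls <- classifyColony(res$colonies, cfg$positivity_threshold)
        lin <- countLineages(res$colonies, cfg$positivity_threshold)
        .writeTsv(merge(cls, lin, by = "colony_id"),
                  file.path(outdir, "colony_classes.tsv"))
    })

    if ("expression" %in% cfg$stages) stage("expression", {
        hx <- res$expression
        norm <- normalizeCounts(hx)
        gm <- metadata(hx)$gene_map
        if (is.null(gm)) gm <- scfg$gene_map
        molo <- signatureScore(norm, gm$molo, "molo")
        prol <- signatureScore(norm, gm$proliferation, "proliferation")
        .writeTsv(data.frame(cell_id = molo$cell_id, molo = molo$score,
                             proliferation = prol$score),
                  file.path(outdir, "scores.tsv"))
        ph <- assignCellCycle(norm, gm$s_genes, gm$g2m_genes,
                              seed = cfg$seed)
        .writeTsv(ph, file.path(outdir, "phases.tsv"))
        cond <- as.character(cellCondition(hx))
        de1 <- differentialExpression(hx, group_a = "HSC",
                                      group_b = "HSC+SCF")
        de2 <- differentialExpression(hx, group_a = "hibHSC",
                                      group_b = "hibHSC+SCF")
        de3 <- differentialExpression(hx, group_a = "HSC",
                                      group_b = "hibHSC")
        .writeTsv(de1, file.path(outdir, "de_HSC_vs_HSC+SCF.tsv"))
        .writeTsv(de2, file.path(outdir, "de_hibHSC_vs_hibHSC+SCF.tsv"))
        .writeTsv(de3, file.path(outdir, "de_HSC_vs_hibHSC.tsv"))
        ix <- intersectDE(de1, de2, cfg$q_cut)
        .writeTsv(data.frame(
            gene = c(ix$common_up, ix$common_down),
            direction = rep(c("up", "down"),
                            c(length(ix$common_up), length(ix$common_down)))),
            file.path(outdir, "de_intersection.tsv"))
        universe <- de3$gene[de3$tested]
        query <- intersect(de3$gene[!is.na(de3$qvalue) &
                                    de3$qvalue < cfg$q_cut], universe)
        colls <- list(molo_synthetic = gm$molo,
                      proliferation = gm$proliferation)
        enr <- enrichmentTest(query, colls, universe)
        .writeTsv(enr, file.path(outdir, "enrichment.tsv"))
        res$de <- list(hsc_vs_scf = de1, hib_vs_scf = de2,
                       hsc_vs_hib = de3, intersection = ix)
        res$phases <- ph
    })

    files <- setdiff(list.files(outdir), "manifest.json")
    manifest <- list(
        package = "hibHSC",
        version = as.character(utils::packageVersion("hibHSC")),
        seed = cfg$seed,
        config = cfg[setdiff(names(cfg), "simulation")],
        files = as.list(tools::md5sum(file.path(outdir, sort(files)))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(res)
}
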