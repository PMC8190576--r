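# Single-cell expression analysis: normalization, signature scoring,
# cell-cycle phase assignment, NB differential expression with BH
# correction, direction-aware DE intersection and hypergeometric gene-set
# enrichment.

.countsOf <- function(x) {
    if (is(x, "SummarizedExperiment"))
        as.matrix(SummarizedExperiment::assay(x, "counts"))
    else as.matrix(x)
}

#' Median-total normalization with log transform
#'
#' Scales each cell's counts so that its total matches the median cell
#' total, then applies \code{log2(1 + scaled)}. Cells with zero total are
#' excluded and recorded in \code{attr(, "excluded_cells")}.
#'
#' @param x a \code{\linkS4class{HibExperiment}}, count matrix or other
#'   object with a \code{counts} assay (genes x cells).
#' @return normalized gene x cell matrix (real-valued).
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 0, 6), 3,
#'             dimnames = list(c("a", "b", "c"), c("c1", "c2")))
#' normalizeCounts(m)  # c2 is c1 doubled: identical profiles
#' @export
normalizeCounts <- function(x) {
    counts <- .countsOf(x)
    totals <- colSums(counts)
    if (all(totals == 0)) stop("input error: all-zero count matrix")
    excluded <- colnames(counts)[totals == 0]
    if (length(excluded)) {
        counts <- counts[, totals > 0, drop = FALSE]
        totals <- totals[totals > 0]
    }
    target <- stats::median(totals)
    norm <- log2(1 + sweep(counts, 2, target / totals, "*"))
    attr(norm, "excluded_cells") <- excluded
    norm
}

#' Average-expression signature score
#'
#' The score of a cell is the arithmetic mean of its normalized expression
#' over the signature genes present in the matrix. Missing signature genes
#' are reported in \code{attr(, "n_missing")}; an empty intersection is an
#' error. A score cannot be computed from fewer than half the signature
#' (missing genes are reported, never silently dropped past that floor).
#'
#' @param norm normalized matrix from \code{\link{normalizeCounts}}.
#' @param signature character vector of gene identifiers.
#' @param name signature name used in messages (default "signature").
#' @return data.frame: \code{cell_id}, \code{score}.
#' @export
signatureScore <- function(norm, signature, name = "signature") {
    present <- intersect(signature, rownames(norm))
    if (!length(present))
        stop("input error: no genes of signature '", name,
             "' found in the matrix")
    if (length(present) < length(signature) / 2)
        warning("signature '", name, "': only ", length(present), " of ",
                length(signature), " genes present")
    score <- colMeans(norm[present, , drop = FALSE])
    out <- data.frame(cell_id = colnames(norm), score = unname(score))
    attr(out, "n_missing") <- length(signature) - length(present)
    out
}

#' Assign cell-cycle phase from S and G2M marker scores
#'
#' Phase scores follow the expression-matched control scheme: genes are
#' binned by their average normalized expression across cells
#' (\code{n_control_bins} bins); for every signature gene,
#' \code{n_controls} control genes are drawn from its bin, and the score is
#' the mean signature expression minus the mean control expression in each
#' cell. A cell is G2M if its G2M score is positive and exceeds the S
#' score, S if its S score is positive and at least the G2M score, and
#' G1(G0) otherwise.
#'
#' @param norm normalized matrix from \code{\link{normalizeCounts}}.
#' @param s_genes,g2m_genes phase marker gene lists.
#' @param n_control_bins number of average-expression bins (default 25).
#' @param n_controls control genes drawn per signature gene (default 50).
#' @param seed seed for the control draws.
#' @return data.frame: \code{cell_id}, \code{phase} (\code{G1(G0)},
#'   \code{S}, \code{G2M}), \code{s_score}, \code{g2m_score}.
#' @export
assignCellCycle <- function(norm, s_genes, g2m_genes, n_control_bins = 25,
                            n_controls = 50, seed = 0) {
    if (nrow(norm) < n_control_bins)
        stop("configuration error: fewer genes than control bins")
    for (nm in list(c("s_genes", s_genes), c("g2m_genes", g2m_genes)))
        if (!length(intersect(nm[-1], rownames(norm))))
            stop("input error: no ", nm[1], " present in the matrix")
    avg <- rowMeans(norm)
    # quantile bins on average expression; duplicate breaks collapse for
    # heavily tied (e.g. all-zero) strata
    br <- unique(stats::quantile(avg, probs = seq(0, 1, length.out =
                                                  n_control_bins + 1)))
    bin <- cut(avg, breaks = br, include.lowest = TRUE, labels = FALSE)
    names(bin) <- rownames(norm)
    scoreOne <- function(sig) {
        sig <- intersect(sig, rownames(norm))
        ctrl <- unlist(lapply(sig, function(g) {
            pool <- names(bin)[bin == bin[g]]
            pool <- setdiff(pool, sig)
            if (!length(pool)) pool <- setdiff(names(bin), sig)
            sample(pool, n_controls, replace = TRUE)
        }))
        colMeans(norm[sig, , drop = FALSE]) -
            colMeans(norm[ctrl, , drop = FALSE])
    }
    withSeed(seed + 505L, {
        s_score <- scoreOne(s_genes)
        g2m_score <- scoreOne(g2m_genes)
        phase <- ifelse(g2m_score > s_score & g2m_score > 0, "G2M",
                 ifelse(s_score >= g2m_score & s_score > 0, "S", "G1(G0)"))
        data.frame(cell_id = colnames(norm), phase = phase,
                   s_score = unname(s_score), g2m_score = unname(g2m_score))
    })
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns the step-up q-values in the input order, clipped to [0, 1]:
#' \code{q_(i) = min_{j >= i} p_(j) * n / j} over the sorted p-values.
#'
#' @param pvals numeric vector of p-values in [0, 1] (NA passed through).
#' @return q-values aligned with \code{pvals}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pvals) {
    if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
        stop("input error: p-values must lie in [0,1]")
    ok <- !is.na(pvals)
    p <- pvals[ok]
    n <- length(p)
    q <- rep(NA_real_, length(pvals))
    if (n) {
        o <- order(p)
        ranked <- p[o] * n / seq_len(n)
        stepped <- rev(cummin(rev(ranked)))
        qq <- numeric(n)
        qq[o] <- pmin(1, stepped)
        q[ok] <- qq
    }
    q
}

#' Negative-binomial differential expression between two conditions
#'
#' Per gene passing the expression filter: a common NB dispersion is
#' estimated by the method of moments (floored at 1e-8) from both groups
#' after removing group means, and a Wald test compares the group log means
#' with cell-total offsets. P-values are BH-adjusted across tested genes;
#' direction is the sign of the log2 fold change of \code{group_b} over
#' \code{group_a} (\code{up} = higher in \code{group_b}). Genes failing the
#' filter are reported untested (NA statistics).
#'
#' @param x a \code{\linkS4class{HibExperiment}}, or a count matrix.
#' @param condition condition label per cell (ignored for a
#'   \code{HibExperiment}, which carries its own).
#' @param group_a,group_b the two condition labels to compare.
#' @param min_frac expression filter: a gene is tested when detected
#'   (count > 0) in at least this fraction of the cells of either group
#'   (default 0.10).
#' @return A \code{DETable} data.frame: \code{gene}, \code{mean_a},
#'   \code{mean_b} (offset-corrected group means), \code{log2fc},
#'   \code{dispersion}, \code{stat}, \code{pvalue}, \code{qvalue},
#'   \code{direction}, \code{tested}.
#' @export
differentialExpression <- function(x, condition = NULL, group_a, group_b,
                                   min_frac = 0.10) {
    counts <- .countsOf(x)
    if (is(x, "SummarizedExperiment") && is.null(condition))
        condition <- as.character(cellCondition(x))
    condition <- as.character(condition)
    if (!all(c(group_a, group_b) %in% condition))
        stop("input error: unknown condition label '",
             setdiff(c(group_a, group_b), condition)[1], "'")
    ia <- which(condition == group_a)
    ib <- which(condition == group_b)
    if (length(ia) < 2 || length(ib) < 2)
        stop("input error: both groups need at least 2 cells")
    ca <- counts[, ia, drop = FALSE]
    cb <- counts[, ib, drop = FALSE]
    # cell-total offsets (size factors relative to the joint mean total)
    tot <- c(colSums(ca), colSums(cb))
    sfa <- colSums(ca) / mean(tot)
    sfb <- colSums(cb) / mean(tot)
    tested <- pmax(rowMeans(ca > 0), rowMeans(cb > 0)) >= min_frac
    fit <- .nbWald(ca[tested, , drop = FALSE], cb[tested, , drop = FALSE],
                   sfa, sfb)
    out <- data.frame(gene = rownames(counts),
                      mean_a = NA_real_, mean_b = NA_real_,
                      log2fc = NA_real_, dispersion = NA_real_,
                      stat = NA_real_, pvalue = NA_real_, qvalue = NA_real_,
                      direction = NA_character_, tested = tested,
                      row.names = NULL)
    out[tested, c("mean_a", "mean_b", "log2fc", "dispersion", "stat",
                  "pvalue")] <- fit
    out$qvalue[tested] <- bhAdjust(out$pvalue[tested])
    out$direction[tested] <- ifelse(out$log2fc[tested] > 0, "up", "down")
    attr(out, "groups") <- c(a = group_a, b = group_b)
    out
}

# Vectorized NB method-of-moments + Wald machinery shared by DE and its
# calibration tests. Returns a data.frame of per-gene statistics.
.nbWald <- function(ca, cb, sfa, sfb) {
    na <- ncol(ca); nb <- ncol(cb)
    qa <- rowSums(ca) / sum(sfa)
    qb <- rowSums(cb) / sum(sfb)
    # continuity for empty groups so the log fold change stays finite
    qa0 <- ifelse(qa == 0, 0.5 / sum(sfa), qa)
    qb0 <- ifelse(qb == 0, 0.5 / sum(sfb), qb)
    mua <- qa0 %o% sfa
    mub <- qb0 %o% sfb
    rss <- rowSums((ca - mua)^2) + rowSums((cb - mub)^2)
    mu_sum <- rowSums(mua) + rowSums(mub)
    mu2_sum <- rowSums(mua^2) + rowSums(mub^2)
    n <- na + nb
    disp <- pmax((rss * n / (n - 2) - mu_sum) / mu2_sum, 1e-8)
    va <- (rowSums(mua) + disp * rowSums(mua^2)) / rowSums(mua)^2
    vb <- (rowSums(mub) + disp * rowSums(mub^2)) / rowSums(mub)^2
    lfc <- (log(qb0) - log(qa0)) / log(2)
    z <- (log(qb0) - log(qa0)) / sqrt(va + vb)
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(mean_a = qa, mean_b = qb, log2fc = lfc, dispersion = disp,
               stat = z, pvalue = p)
}

#' Direction-aware intersection of two DE tables
#'
#' Genes significant (q below the cut) with the same direction in both
#' tables; genes significant with opposite directions are excluded from
#' both sets.
#'
#' @param table_1,table_2 DE tables from
#'   \code{\link{differentialExpression}}.
#' @param q_cut significance threshold in (0, 1), default 0.05.
#' @return list with character vectors \code{common_up} and
#'   \code{common_down}.
#' @export
intersectDE <- function(table_1, table_2, q_cut = 0.05) {
    if (!is.numeric(q_cut) || q_cut <= 0 || q_cut >= 1)
        stop("input error: q_cut must lie in (0,1)")
    sig <- function(tab, dir)
        tab$gene[!is.na(tab$qvalue) & tab$qvalue < q_cut &
                 tab$direction == dir]
    list(common_up = intersect(sig(table_1, "up"), sig(table_2, "up")),
         common_down = intersect(sig(table_1, "down"), sig(table_2, "down")))
}

#' Hypergeometric gene-set enrichment
#'
#' For each collection set (intersected with the universe first), the
#' upper-tail hypergeometric probability of an overlap at least as large as
#' observed, BH-adjusted across tested sets. Sets with an empty
#' universe-intersection are skipped and listed in
#' \code{attr(, "skipped")}.
#'
#' @param query character vector of genes (must be a subset of
#'   \code{universe}).
#' @param collections named list of gene sets (e.g. from
#'   \code{\link{readGmt}}).
#' @param universe character vector: the tested gene universe.
#' @return data.frame: \code{set}, \code{overlap}, \code{set_size},
#'   \code{query_size}, \code{universe_size}, \code{pvalue}, \code{qvalue}.
#' @examples
#' enrichmentTest(letters[1:5], list(hit = letters[1:5]), letters[1:20])
#' @export
enrichmentTest <- function(query, collections, universe) {
    query <- unique(query); universe <- unique(universe)
    if (!all(query %in% universe))
        stop("input error: query genes outside the universe: ",
             paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
    N <- length(universe); n <- length(query)
    sets <- lapply(collections, intersect, y = universe)
    skipped <- names(sets)[lengths(sets) == 0]
    sets <- sets[lengths(sets) > 0]
    rows <- lapply(names(sets), function(nm) {
        K <- length(sets[[nm]])
        k <- length(intersect(sets[[nm]], query))
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(set = nm, overlap = k, set_size = K, query_size = n,
                   universe_size = N, pvalue = p)
    })
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(set = character(), overlap = integer(),
                   set_size = integer(), query_size = integer(),
                   universe_size = integer(), pvalue = numeric())
    out$qvalue <- bhAdjust(out$pvalue)
    attr(out, "skipped") <- skipped
    out
}

#' Per-condition proliferation-signature summary
#'
#' Mean signature score per condition, with a check that both
#' SCF-stimulated conditions exceed both unstimulated ones (the expected
#' pattern for a proliferation program).
#'
#' @param norm normalized matrix.
#' @param condition condition label per column of \code{norm}.
#' @param signature proliferation signature gene list.
#' @return data.frame: \code{condition}, \code{mean_score}, with attribute
#'   \code{stimulated_exceed_unstimulated} (logical).
#' @export
proliferationSummary <- function(norm, condition, signature) {
    sc <- signatureScore(norm, signature, name = "proliferation")
    condition <- as.character(condition)
    stopifnot(length(condition) == nrow(sc))
    means <- tapply(sc$score, condition, mean)
    out <- data.frame(condition = names(means), mean_score = as.vector(means))
    stim <- grepl("\\+SCF$", out$condition)
    ok <- if (any(stim) && any(!stim))
        min(out$mean_score[stim]) > max(out$mean_score[!stim]) else NA
    attr(out, "stimulated_exceed_unstimulated") <- ok
    out
}
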