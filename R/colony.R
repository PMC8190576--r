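# Colony lineage typing from flow-marker positivity.

.positivity <- function(rec, threshold, gm_rule = "and") {
    pos <- rec[.COLONY_MARKERS] >= threshold
    gm_pos <- if (gm_rule == "and") pos[, "Gr1"] & pos[, "CD11b"]
              else pos[, "Gr1"] | pos[, "CD11b"]
    list(pos = pos, gm = gm_pos)
}

#' Classify colonies into lineage classes
#'
#' A marker is positive when its event fraction reaches the positivity
#' threshold. With GM+ meaning Gr1 and CD11b both positive, classes are:
#' GEMM (GM+, CD41+, Ter119+), GMM (GM+, CD41+), GEM (GM+, Ter119+),
#' GM (GM+ only), MK (CD41+ only) and \code{other} for any remaining
#' pattern (no class is defined e.g. for Ter119 alone).
#'
#' @param x a \code{\linkS4class{ColonyFlowSet}} or a data.frame with
#'   columns \code{colony_id}, \code{CD41}, \code{Gr1}, \code{CD11b},
#'   \code{Ter119}.
#' @param threshold positivity threshold; defaults to the set's threshold
#'   (0.01 for a plain data.frame).
#' @param gm_rule \code{"and"} (default: both Gr1 and CD11b) or \code{"or"}.
#' @return data.frame: \code{colony_id}, \code{class}.
#' @examples
#' rec <- data.frame(colony_id = "c1", CD41 = 0.2, Gr1 = 0, CD11b = 0,
#'                   Ter119 = 0)
#' classifyColony(rec)  # MK
#' @export
classifyColony <- function(x, threshold = NULL, gm_rule = c("and", "or")) {
    gm_rule <- match.arg(gm_rule)
    if (is(x, "ColonyFlowSet")) {
        if (is.null(threshold)) threshold <- positivityThreshold(x)
        rec <- colonyRecords(x)
    } else {
        if (is.null(threshold)) threshold <- 0.01
        rec <- x
    }
    miss <- setdiff(.COLONY_MARKERS, names(rec))
    if (length(miss))
        stop("input error: missing marker column(s): ",
             paste(miss, collapse = ", "))
    p <- .positivity(rec, threshold, gm_rule)
    pos <- p$pos; gm <- p$gm
    cls <- rep("other", nrow(rec))
    cls[pos[, "CD41"] & !pos[, "Gr1"] & !pos[, "CD11b"] &
        !pos[, "Ter119"]] <- "MK"
    cls[gm & !pos[, "CD41"] & !pos[, "Ter119"]] <- "GM"
    cls[gm & !pos[, "CD41"] & pos[, "Ter119"]] <- "GEM"
    cls[gm & pos[, "CD41"] & !pos[, "Ter119"]] <- "GMM"
    cls[gm & pos[, "CD41"] & pos[, "Ter119"]] <- "GEMM"
    data.frame(colony_id = rec$colony_id, class = cls)
}

#' Count distinct lineages per colony
#'
#' Lineages are granulocyte (Gr1+), monocyte (CD11b+), erythroid (Ter119+)
#' and megakaryocyte (CD41+), so a GM colony counts 2 and GEM/GMM count 3.
#' A colony is multipotent when it spans at least three lineages -- exactly
#' the GEM, GMM and GEMM classes under the AND rule.
#'
#' @inheritParams classifyColony
#' @return data.frame: \code{colony_id}, \code{n_lineages},
#'   \code{multipotent}.
#' @export
countLineages <- function(x, threshold = NULL) {
    if (is(x, "ColonyFlowSet")) {
        if (is.null(threshold)) threshold <- positivityThreshold(x)
        rec <- colonyRecords(x)
    } else {
        if (is.null(threshold)) threshold <- 0.01
        rec <- x
    }
    miss <- setdiff(.COLONY_MARKERS, names(rec))
    if (length(miss))
        stop("input error: missing marker column(s): ",
             paste(miss, collapse = ", "))
    pos <- rec[.COLONY_MARKERS] >= threshold
    n <- rowSums(pos)
    data.frame(colony_id = rec$colony_id, n_lineages = as.integer(n),
               multipotent = n >= 3)
}

#' Summarize colony typing for a plate
#'
#' @param x a \code{\linkS4class{ColonyFlowSet}}.
#' @param threshold optional positivity threshold override.
#' @return list with \code{classes} (class counts), \code{n},
#'   \code{pct_multipotent}.
#' @export
summarizeColonies <- function(x, threshold = NULL) {
    cls <- classifyColony(x, threshold)
    lin <- countLineages(x, threshold)
    list(classes = table(cls$class), n = nrow(cls),
         pct_multipotent = 100 * mean(lin$multipotent))
}
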