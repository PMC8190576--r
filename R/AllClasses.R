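#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# WellTrackSet
# ---------------------------------------------------------------------------

#' Daily single-cell culture tracks for a plate of wells
#'
#' A \code{WellTrackSet} holds the daily cell counts of single-HSC cultures:
#' one sorted cell per well, observed over consecutive days. Death is
#' absorbing: once a well reports 0 cells it must report 0 at every later
#' observation. Optional flow-cytometry index-sort intensities (one row per
#' well and marker) are carried alongside, as is arbitrary per-well metadata
#' such as a GFP transduction flag.
#'
#' @slot wells data.frame with columns \code{well_id}, \code{arm} and any
#'   extra per-well columns (e.g. \code{gfp}).
#' @slot tracks data.frame with columns \code{well_id}, \code{day},
#'   \code{cell_count}; observation days strictly increasing per well.
#' @slot index data.frame with columns \code{well_id}, \code{marker},
#'   \code{intensity}, possibly empty.
#' @slot metadata list of unstructured metadata (simulation truth, config),
#'   via \code{\link[S4Vectors]{Annotated}}.
#'
#' @export
setClass("WellTrackSet",
    representation(wells = "data.frame", tracks = "data.frame",
                   index = "data.frame"),
    contains = "Annotated")

setValidity("WellTrackSet", function(object) {
    w <- object@wells; tr <- object@tracks; ix <- object@index
    msg <- character()
    if (!all(c("well_id", "arm") %in% names(w)))
        msg <- c(msg, "'wells' needs columns well_id, arm")
    if (!all(c("well_id", "day", "cell_count") %in% names(tr)))
        msg <- c(msg, "'tracks' needs columns well_id, day, cell_count")
    if (anyDuplicated(w$well_id))
        msg <- c(msg, "duplicated well_id in 'wells'")
    if (nrow(tr)) {
        if (any(tr$cell_count < 0)) msg <- c(msg, "negative cell_count")
        if (!all(tr$well_id %in% w$well_id))
            msg <- c(msg, "tracks refer to unknown wells")
        sp <- split(seq_len(nrow(tr)), tr$well_id)
        for (i in sp) {
            d <- tr$day[i]; cc <- tr$cell_count[i]
            o <- order(d)
            if (any(diff(d[o]) <= 0)) {
                msg <- c(msg, "observation days not strictly increasing")
                break
            }
            cc <- cc[o]
            # death is absorbing
            if (any(cc[cummax(cc == 0) == 1] != 0)) {
                msg <- c(msg, sprintf(
                    "well '%s': nonzero count after death", tr$well_id[i[1]]))
                break
            }
        }
    }
    if (nrow(ix) && !all(c("well_id", "marker", "intensity") %in% names(ix)))
        msg <- c(msg, "'index' needs columns well_id, marker, intensity")
    if (length(msg)) msg else TRUE
})

#' Construct a WellTrackSet
#'
#' @param wells per-well data.frame (\code{well_id}, \code{arm}, ...).
#' @param tracks long data.frame of daily observations.
#' @param index optional long data.frame of index-sort intensities.
#' @param metadata optional list.
#' @return A \code{\linkS4class{WellTrackSet}}.
#' @examples
#' wts <- WellTrackSet(
#'     wells  = data.frame(well_id = "w1", arm = "hib"),
#'     tracks = data.frame(well_id = "w1", day = 0:2, cell_count = c(1, 1, 0)))
#' nWells(wts)
#' @export
WellTrackSet <- function(wells, tracks,
                         index = data.frame(well_id = character(),
                                            marker = character(),
                                            intensity = numeric()),
                         metadata = list()) {
    wells$well_id <- as.character(wells$well_id)
    tracks$well_id <- as.character(tracks$well_id)
    if (nrow(index)) index$well_id <- as.character(index$well_id)
    new("WellTrackSet", wells = wells, tracks = tracks, index = index,
        metadata = metadata)
}

#' @rdname WellTrackSet
#' @param x a \code{WellTrackSet}.
#' @export
wellTracks <- function(x) x@tracks

#' @rdname WellTrackSet
#' @export
wellData <- function(x) x@wells

#' @rdname WellTrackSet
#' @export
indexData <- function(x) x@index

#' @rdname WellTrackSet
#' @export
nWells <- function(x) nrow(x@wells)

setMethod("show", "WellTrackSet", function(object) {
    cat("WellTrackSet with", nrow(object@wells), "wells over",
        length(unique(object@wells$arm)), "arm(s);",
        nrow(object@tracks), "observations\n")
    if (nrow(object@index))
        cat("  index markers:",
            paste(unique(object@index$marker), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# ChimerismSet
# ---------------------------------------------------------------------------

#' Post-transplant donor chimerism records
#'
#' One row per recipient mouse and bleed week: percent donor chimerism in
#' peripheral blood and the donor-derived granulocyte/monocyte (GM), B and T
#' percentages of total peripheral blood.
#'
#' @slot records data.frame with columns \code{mouse_id}, \code{arm},
#'   \code{week}, \code{donor_pct}, \code{gm_pct}, \code{b_pct}, \code{t_pct}.
#' @slot metadata list (simulation truth, config).
#' @export
setClass("ChimerismSet", representation(records = "data.frame"),
    contains = "Annotated")

setValidity("ChimerismSet", function(object) {
    r <- object@records
    need <- c("mouse_id", "arm", "week", "donor_pct", "gm_pct", "b_pct",
              "t_pct")
    msg <- character()
    if (!all(need %in% names(r)))
        msg <- c(msg, paste("'records' needs columns",
                            paste(need, collapse = ", ")))
    else if (nrow(r)) {
        pct <- unlist(r[c("donor_pct", "gm_pct", "b_pct", "t_pct")])
        if (any(pct < 0 | pct > 100)) msg <- c(msg, "percentages outside [0,100]")
        # lineage percentages cannot exceed total donor chimerism (tolerance
        # for measurement noise on independent stains)
        tol <- 1
        if (any(r$gm_pct > r$donor_pct + tol | r$b_pct > r$donor_pct + tol |
                r$t_pct > r$donor_pct + tol))
            msg <- c(msg, "lineage percentage exceeds donor_pct beyond tolerance")
        dup <- anyDuplicated(r[c("mouse_id", "week")])
        if (dup) msg <- c(msg, "duplicated (mouse_id, week)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ChimerismSet
#'
#' @param records long data.frame of weekly measurements (see class slots).
#' @param metadata optional list.
#' @return A \code{\linkS4class{ChimerismSet}}.
#' @export
ChimerismSet <- function(records, metadata = list()) {
    records$mouse_id <- as.character(records$mouse_id)
    new("ChimerismSet", records = records, metadata = metadata)
}

#' @rdname ChimerismSet
#' @param x a \code{ChimerismSet}.
#' @export
chimerismRecords <- function(x) x@records

setMethod("show", "ChimerismSet", function(object) {
    r <- object@records
    cat("ChimerismSet:", length(unique(r$mouse_id)), "mice,",
        length(unique(r$arm)), "arm(s), weeks",
        paste(sort(unique(r$week)), collapse = "/"), "\n")
})

# ---------------------------------------------------------------------------
# ColonyFlowSet
# ---------------------------------------------------------------------------

#' Colony flow-marker positivity records
#'
#' One row per colony from a colony-forming cell (CFC) assay, with the
#' fraction of events positive for each of the four lineage markers:
#' CD41 (megakaryocyte), Gr1 (granulocyte), CD11b (monocyte), Ter119
#' (erythroid).
#'
#' @slot records data.frame with columns \code{colony_id}, \code{CD41},
#'   \code{Gr1}, \code{CD11b}, \code{Ter119} (fractions in [0,1]).
#' @slot threshold numeric(1), fraction of positive events above which a
#'   marker is called positive; in (0,1).
#' @slot metadata list.
#' @export
setClass("ColonyFlowSet",
    representation(records = "data.frame", threshold = "numeric"),
    contains = "Annotated")

.COLONY_MARKERS <- c("CD41", "Gr1", "CD11b", "Ter119")

setValidity("ColonyFlowSet", function(object) {
    r <- object@records
    msg <- character()
    if (!all(c("colony_id", .COLONY_MARKERS) %in% names(r)))
        msg <- c(msg, "'records' needs colony_id and the four marker columns")
    else if (nrow(r)) {
        fr <- unlist(r[.COLONY_MARKERS])
        if (any(is.na(fr))) msg <- c(msg, "missing marker fractions")
        else if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions outside [0,1]")
    }
    th <- object@threshold
    if (length(th) != 1 || is.na(th) || th <= 0 || th >= 1)
        msg <- c(msg, "threshold must be a single value in (0,1)")
    if (length(msg)) msg else TRUE
})

#' Construct a ColonyFlowSet
#'
#' @param records data.frame of per-colony marker positivity fractions.
#' @param threshold positivity threshold on the event fraction (default 0.01).
#' @param metadata optional list.
#' @return A \code{\linkS4class{ColonyFlowSet}}.
#' @export
ColonyFlowSet <- function(records, threshold = 0.01, metadata = list()) {
    records$colony_id <- as.character(records$colony_id)
    new("ColonyFlowSet", records = records, threshold = threshold,
        metadata = metadata)
}

#' @rdname ColonyFlowSet
#' @param x a \code{ColonyFlowSet}.
#' @export
colonyRecords <- function(x) x@records

#' @rdname ColonyFlowSet
#' @export
positivityThreshold <- function(x) x@threshold

setMethod("show", "ColonyFlowSet", function(object) {
    cat("ColonyFlowSet:", nrow(object@records), "colonies, positivity",
        "threshold", object@threshold, "\n")
})

# ---------------------------------------------------------------------------
# HibExperiment
# ---------------------------------------------------------------------------

#' Four-condition single-cell expression experiment
#'
#' \code{HibExperiment} extends
#' \code{\link[SingleCellExperiment]{SingleCellExperiment}} with the
#' constraint that a \code{counts} assay of non-negative integers is present
#' and that \code{colData(x)$condition} assigns every cell to one of the four
#' culture conditions: freshly isolated HSCs (\code{HSC}), 7-day hibernation
#' cultures (\code{hibHSC}), and their 16 h SCF-stimulated counterparts
#' (\code{HSC+SCF}, \code{hibHSC+SCF}).
#'
#' @export
setClass("HibExperiment", contains = "SingleCellExperiment")

#' The four culture condition labels
#' @export
HIB_CONDITIONS <- c("HSC", "hibHSC", "HSC+SCF", "hibHSC+SCF")

setValidity("HibExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        v <- as.vector(if (methods::is(m, "Matrix")) m@x else m)
        if (length(v) && (any(v < 0) || any(v != round(v))))
            msg <- c(msg, "'counts' must be non-negative integers")
    }
    if (!"condition" %in% names(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain 'condition'")
    else {
        cond <- SummarizedExperiment::colData(object)$condition
        if (!all(as.character(cond) %in% HIB_CONDITIONS))
            msg <- c(msg, paste("conditions must be one of:",
                                paste(HIB_CONDITIONS, collapse = ", ")))
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "unique gene identifiers (rownames) required")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "unique cell identifiers (colnames) required")
    if (length(msg)) msg else TRUE
})

#' Construct a HibExperiment
#'
#' @param counts gene x cell matrix of non-negative integer counts with
#'   dimnames.
#' @param condition character/factor of length \code{ncol(counts)} with
#'   values in \code{\link{HIB_CONDITIONS}}.
#' @param ... further arguments passed to the
#'   \code{SingleCellExperiment} constructor (e.g. \code{rowData},
#'   \code{metadata}).
#' @return A \code{\linkS4class{HibExperiment}}.
#' @examples
#' m <- matrix(rpois(20, 4), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' hx <- HibExperiment(m, rep(c("HSC", "hibHSC"), c(2, 3)))
#' table(cellCondition(hx))
#' @export
HibExperiment <- function(counts, condition, ...) {
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), ...)
    SummarizedExperiment::colData(sce)$condition <-
        factor(as.character(condition), levels = HIB_CONDITIONS)
    new("HibExperiment", sce)
}

#' @rdname HibExperiment
#' @param x a \code{HibExperiment}.
#' @export
cellCondition <- function(x)
    SummarizedExperiment::colData(x)$condition

setMethod("show", "HibExperiment", function(object) {
    callNextMethod()
    cat("condition:",
        paste(sprintf("%s=%d", levels(cellCondition(object)),
                      tabulate(cellCondition(object),
                               length(HIB_CONDITIONS))), collapse = " "), "\n")
})
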