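# Clonal culture kinetics: survival scoring, division detection, clone
# sizes, and index-sort stratification.

# last observation carried forward at `at_day`, per well
.lastCounts <- function(tracks, at_day) {
    tr <- tracks[tracks$day <= at_day, ]
    bad <- setdiff(unique(tracks$well_id), unique(tr$well_id))
    if (length(bad))
        stop("input error: no observation at or before day ", at_day,
             " for well(s): ", paste(utils::head(bad, 5), collapse = ", "))
    tr <- tr[order(tr$well_id, tr$day), ]
    last <- tr[!duplicated(tr$well_id, fromLast = TRUE), ]
    stats::setNames(last$cell_count, last$well_id)
}

#' Score per-arm survival at a given day
#'
#' A well is alive at \code{at_day} if its last observation at or before
#' that day reports at least one cell (death is absorbing, so carrying the
#' last observation forward is exact for dead wells). If the wells carry a
#' \code{gfp} flag, the GFP-positive fraction among alive wells is reported
#' as well.
#'
#' @param x a \code{\linkS4class{WellTrackSet}}.
#' @param at_day day at which survival is scored (default 7).
#' @param groups optional grouping overriding the culture arm: a data.frame
#'   with columns \code{well_id} and a label column (e.g. the output of
#'   \code{\link{stratifyByIndex}}), or a named vector over wells.
#' @return data.frame with one row per arm: \code{arm}, \code{n},
#'   \code{alive}, \code{fraction} (NA and flagged \code{missing} for empty
#'   arms), and \code{gfp_fraction} when GFP flags are present.
#' @export
scoreSurvival <- function(x, at_day = 7, groups = NULL) {
    stopifnot(is(x, "WellTrackSet"))
    w <- wellData(x)
    if (!is.null(groups)) {
        if (is.data.frame(groups)) {
            lab <- groups[[setdiff(names(groups), "well_id")[1]]]
            names(lab) <- groups$well_id
        } else lab <- groups
        w$arm <- unname(lab[w$well_id])
        if (anyNA(w$arm)) stop("input error: wells without group label")
    }
    last <- .lastCounts(wellTracks(x), at_day)
    alive <- last[w$well_id] >= 1
    arms <- unique(w$arm)
    out <- do.call(rbind, lapply(arms, function(a) {
        i <- w$arm == a
        n <- sum(i)
        al <- sum(alive[i])
        data.frame(arm = a, n = n, alive = al,
                   fraction = if (n > 0) al / n else NA_real_,
                   missing = n == 0)
    }))
    if ("gfp" %in% names(w))
        out$gfp_fraction <- vapply(arms, function(a) {
            i <- w$arm == a & alive
            if (!sum(i)) return(NA_real_)
            mean(w$gfp[i])
        }, numeric(1))
    out
}

#' Detect divisions and their timing from well tracks
#'
#' The first division is called at the earliest observation with at least
#' \code{min_cells} cells (default 2: a well going from 1 to 2 cells has
#' divided); the second division at the earliest observation with at least
#' \code{min_cells + 1} cells, since a 2-to-3 transition requires at least
#' one further division.
#'
#' @param x a \code{\linkS4class{WellTrackSet}}.
#' @param min_cells count threshold calling the first division (default 2).
#' @return data.frame: \code{well_id}, \code{divided},
#'   \code{first_division_day}, \code{second_division_day} (NA when absent).
#' @export
detectDivisions <- function(x, min_cells = 2) {
    stopifnot(is(x, "WellTrackSet"))
    tr <- wellTracks(x)
    tr <- tr[order(tr$well_id, tr$day), ]
    sp <- split(tr[c("day", "cell_count")], tr$well_id)
    ids <- wellData(x)$well_id
    first <- second <- rep(NA_real_, length(ids))
    names(first) <- names(second) <- ids
    for (id in names(sp)) {
        d <- sp[[id]]
        i1 <- which(d$cell_count >= min_cells)
        i2 <- which(d$cell_count >= min_cells + 1)
        if (length(i1)) first[id] <- d$day[i1[1]]
        if (length(i2)) second[id] <- d$day[i2[1]]
    }
    data.frame(well_id = ids, divided = !is.na(first),
               first_division_day = unname(first),
               second_division_day = unname(second))
}

#' Fraction of surviving wells that never divided
#'
#' Among wells alive at \code{at_day}, the fraction still holding a single
#' undivided cell -- the headline readout of a hibernation culture.
#'
#' @param x a \code{\linkS4class{WellTrackSet}}.
#' @param at_day scoring day (default 7).
#' @param min_cells division threshold, see \code{\link{detectDivisions}}.
#' @return data.frame per arm: \code{n_alive}, \code{n_undivided},
#'   \code{pct_undivided}.
#' @export
undividedFraction <- function(x, at_day = 7, min_cells = 2) {
    w <- wellData(x)
    last <- .lastCounts(wellTracks(x), at_day)
    div <- detectDivisions(x, min_cells)
    divided_by <- !is.na(div$first_division_day) &
        div$first_division_day <= at_day
    names(divided_by) <- div$well_id
    alive <- last[w$well_id] >= 1
    do.call(rbind, lapply(unique(w$arm), function(a) {
        i <- w$arm == a & alive
        na <- sum(i)
        nu <- sum(i & !divided_by[w$well_id])
        data.frame(arm = a, n_alive = na, n_undivided = nu,
                   pct_undivided = if (na > 0) 100 * nu / na else NA_real_)
    }))
}

#' Clone size distribution of alive wells
#'
#' Histogram of last-carried-forward cell counts of wells alive at
#' \code{at_day}, per arm.
#'
#' @param x a \code{\linkS4class{WellTrackSet}}.
#' @param at_day scoring day.
#' @param bins strictly increasing bin edges; counts are tallied in
#'   \code{[edge_i, edge_{i+1})}, with the last bin closed.
#' @return data.frame: \code{arm}, \code{bin} (label), \code{count}.
#' @export
cloneSizeDistribution <- function(x, at_day, bins) {
    if (length(bins) < 2 || any(diff(bins) <= 0))
        stop("input error: 'bins' must be strictly increasing edges")
    w <- wellData(x)
    last <- .lastCounts(wellTracks(x), at_day)
    labs <- paste0("[", bins[-length(bins)], ",", bins[-1], ")")
    do.call(rbind, lapply(unique(w$arm), function(a) {
        cc <- last[w$well_id[w$arm == a]]
        cc <- cc[cc >= 1]
        h <- if (length(cc))
            tabulate(findInterval(cc, bins, rightmost.closed = TRUE),
                     nbins = length(bins) - 1)
        else integer(length(bins) - 1)
        # counts falling left of the first edge are not binned
        data.frame(arm = a, bin = labs, count = h)
    }))
}

#' Stratify wells by an index-sort marker
#'
#' Tertile scheme: wells ranked by decreasing intensity; the top third is
#' \code{high}, the bottom third \code{low}, the remainder \code{mid}.
#' Stratum sizes differ by at most one; ties are broken by stable well_id
#' order, so the labelling is invariant to input row permutation.
#' Threshold scheme: \code{high} iff intensity >= \code{threshold}, else
#' \code{low}.
#'
#' @param x a \code{\linkS4class{WellTrackSet}} or an index data.frame
#'   (\code{well_id}, \code{marker}, \code{intensity}).
#' @param marker marker name, e.g. \code{"CD150"}.
#' @param scheme \code{"tertile"} (default) or \code{"threshold"}.
#' @param threshold intensity cut for the threshold scheme.
#' @return data.frame: \code{well_id}, \code{stratum}.
#' @export
stratifyByIndex <- function(x, marker = "CD150",
                            scheme = c("tertile", "threshold"),
                            threshold = NULL) {
    scheme <- match.arg(scheme)
    ix <- if (is(x, "WellTrackSet")) indexData(x) else x
    ix <- ix[ix$marker == marker, ]
    wells <- if (is(x, "WellTrackSet")) wellData(x)$well_id else
        unique(ix$well_id)
    miss <- setdiff(wells, ix$well_id[!is.na(ix$intensity)])
    if (length(miss))
        stop("input error: missing '", marker, "' intensity for well(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
    ix <- ix[match(wells, ix$well_id), ]
    if (scheme == "threshold") {
        if (is.null(threshold)) stop("input error: threshold scheme needs 'threshold'")
        return(data.frame(well_id = wells,
                          stratum = ifelse(ix$intensity >= threshold,
                                           "high", "low")))
    }
    n <- length(wells)
    n_high <- (n + 2L) %/% 3L
    n_low <- (n + 1L) %/% 3L
    ord <- order(-ix$intensity, wells)   # stable: ties by well_id
    stratum <- character(n)
    stratum[ord[seq_len(n_high)]] <- "high"
    stratum[ord[seq.int(n - n_low + 1L, n)]] <- "low"
    stratum[stratum == ""] <- "mid"
    data.frame(well_id = wells, stratum = stratum)
}

#' Fold change between two survival fractions
#'
#' @param fraction_a,fraction_b survival fractions (or single-row outputs of
#'   \code{\link{scoreSurvival}}).
#' @return \code{fraction_a / fraction_b}; 0 when a is 0; an error (not
#'   infinity) when b is 0 and a is positive.
#' @examples
#' survivalFoldChange(0.42, 0.10)  # 4.2
#' @export
survivalFoldChange <- function(fraction_a, fraction_b) {
    if (is.data.frame(fraction_a)) fraction_a <- fraction_a$fraction
    if (is.data.frame(fraction_b)) fraction_b <- fraction_b$fraction
    stopifnot(length(fraction_a) == 1, length(fraction_b) == 1)
    if (is.na(fraction_a) || is.na(fraction_b))
        stop("input error: undefined survival fraction")
    if (fraction_a == 0) return(0)
    if (fraction_b == 0)
        stop("undefined fold change: reference survival fraction is 0")
    fraction_a / fraction_b
}
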