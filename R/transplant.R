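# Transplantation analysis: repopulation classification, myeloid:lymphoid
# ratios, HSC subtyping, cohort summaries.

.mouseRecords <- function(x) {
    if (is(x, "ChimerismSet")) chimerismRecords(x) else x
}

#' Classify recipients as repopulated
#'
#' A mouse is repopulated if, at some bleed week inside the window, donor
#' chimerism exceeds 1\% with at least 0.5\% each of donor GM, B and T
#' cells. Engraftment is delayed when the criterion is first met at weeks
#' 20--24 but not yet at week 16.
#'
#' @param x a \code{\linkS4class{ChimerismSet}} or its records data.frame.
#' @param window weeks defining the assessment window (default 16--24).
#' @param donor_cut,lineage_cut criterion thresholds (percent of peripheral
#'   blood), defaults 1 and 0.5.
#' @return data.frame: \code{mouse_id}, \code{arm}, \code{repopulated},
#'   \code{delayed}, \code{first_met_week}.
#' @examples
#' rec <- data.frame(mouse_id = "m1", arm = "fresh", week = 16,
#'                   donor_pct = 5, gm_pct = 1, b_pct = 2, t_pct = 1)
#' classifyRepopulation(rec)
#' @export
classifyRepopulation <- function(x, window = c(16, 24), donor_cut = 1,
                                 lineage_cut = 0.5) {
    r <- .mouseRecords(x)
    mice <- unique(r$mouse_id)
    out <- do.call(rbind, lapply(mice, function(m) {
        rm_ <- r[r$mouse_id == m, ]
        inw <- rm_$week >= window[1] & rm_$week <= window[2]
        if (!any(inw))
            stop("input error: mouse '", m, "' has no measurement in weeks ",
                 window[1], "-", window[2])
        rw <- rm_[inw, ]
        met <- rw$donor_pct > donor_cut & rw$gm_pct >= lineage_cut &
            rw$b_pct >= lineage_cut & rw$t_pct >= lineage_cut
        repop <- any(met)
        first <- if (repop) min(rw$week[met]) else NA_integer_
        delayed <- repop && !any(met & rw$week <= 16)
        data.frame(mouse_id = m, arm = rm_$arm[1], repopulated = repop,
                   delayed = delayed, first_met_week = first)
    }))
    rownames(out) <- NULL
    out
}

#' Donor myeloid to lymphoid ratio
#'
#' \code{gm_pct / (b_pct + t_pct)} at the given week; undefined (NA,
#' flagged) when the lymphoid denominator is zero.
#'
#' @param x a \code{\linkS4class{ChimerismSet}} or records data.frame.
#' @param at_week bleed week (default 16).
#' @return data.frame: \code{mouse_id}, \code{ml_ratio}, \code{undefined}.
#' @export
mlRatio <- function(x, at_week = 16) {
    r <- .mouseRecords(x)
    r <- r[r$week == at_week, ]
    miss <- setdiff(unique(.mouseRecords(x)$mouse_id), r$mouse_id)
    if (length(miss))
        stop("input error: no week-", at_week, " measurement for mouse: ",
             paste(utils::head(miss, 5), collapse = ", "))
    denom <- r$b_pct + r$t_pct
    data.frame(mouse_id = r$mouse_id,
               ml_ratio = ifelse(denom > 0, r$gm_pct / denom, NA_real_),
               undefined = denom == 0)
}

#' Whether donor myeloid output persists past week 16
#'
#' TRUE when donor GM chimerism is at or above the lineage threshold at any
#' measured week strictly after 16 (the delta subtype is defined by losing
#' this output).
#'
#' @param x a \code{\linkS4class{ChimerismSet}} or records data.frame.
#' @param lineage_cut threshold in percent (default 0.5, the repopulation
#'   lineage threshold).
#' @return named logical vector over mice.
#' @export
myeloidPersists <- function(x, lineage_cut = 0.5) {
    r <- .mouseRecords(x)
    vapply(split(r, r$mouse_id), function(d)
        any(d$week > 16 & d$gm_pct >= lineage_cut), logical(1))
}

#' Assign the founder HSC subtype from its mature output
#'
#' Subtypes are intervals of the week-16 donor myeloid:lymphoid ratio:
#' alpha (M:L > 2), beta (0.25 < M:L <= 2), gamma (M:L <= 0.25 with
#' persisting myeloid output) and delta (M:L <= 0.25 with loss of myeloid
#' output past week 16). The boundary points, which the interval notation
#' leaves open, are assigned to the lower class (ratio 2 is beta, 0.25 is
#' gamma/delta). Undefined ratios yield \code{unclassified}.
#'
#' @param ml_ratio numeric vector of M:L ratios (NA allowed).
#' @param myeloid_persists logical vector, see \code{\link{myeloidPersists}}.
#' @return character vector of subtypes in
#'   \{alpha, beta, gamma, delta, unclassified\}.
#' @examples
#' assignHscSubtype(c(3, 1, 0.1, 0.1), c(TRUE, TRUE, TRUE, FALSE))
#' @export
assignHscSubtype <- function(ml_ratio, myeloid_persists) {
    stopifnot(length(ml_ratio) == length(myeloid_persists))
    if (any(ml_ratio < 0, na.rm = TRUE))
        stop("input error: negative M:L ratio")
    ifelse(is.na(ml_ratio), "unclassified",
    ifelse(ml_ratio > 2, "alpha",
    ifelse(ml_ratio > 0.25, "beta",
    ifelse(myeloid_persists, "gamma", "delta"))))
}

#' Full per-mouse subtype calls for a cohort
#'
#' Combines \code{\link{classifyRepopulation}}, \code{\link{mlRatio}} and
#' \code{\link{myeloidPersists}}; only repopulated mice receive a subtype.
#'
#' @param x a \code{\linkS4class{ChimerismSet}} or records data.frame.
#' @param window,at_week see the component functions.
#' @return data.frame: \code{mouse_id}, \code{arm}, \code{repopulated},
#'   \code{delayed}, \code{ml_ratio}, \code{myeloid_persists_past_16w},
#'   \code{subtype}.
#' @export
callSubtypes <- function(x, window = c(16, 24), at_week = 16) {
    rp <- classifyRepopulation(x, window)
    ml <- mlRatio(x, at_week)
    mp <- myeloidPersists(x)
    out <- merge(rp, ml, by = "mouse_id", sort = FALSE)
    out$myeloid_persists_past_16w <- unname(mp[out$mouse_id])
    out$subtype <- ifelse(out$repopulated,
                          assignHscSubtype(out$ml_ratio,
                                           out$myeloid_persists_past_16w),
                          NA_character_)
    out
}

#' Summarize a transplantation cohort per arm
#'
#' Per arm: number of mice, repopulated count and fraction, delayed count,
#' and the subtype distribution over repopulated mice.
#'
#' @param x a \code{\linkS4class{ChimerismSet}} or records data.frame.
#' @param window assessment window.
#' @return data.frame with one row per arm; subtype counts in columns
#'   \code{alpha}..\code{delta}; \code{pct_repopulated} on the percent
#'   scale (15/24 prints as 62.5).
#' @export
summarizeCohort <- function(x, window = c(16, 24)) {
    r <- .mouseRecords(x)
    if (!nrow(r)) {
        return(data.frame(arm = character(), n = integer(),
                          repopulated = integer(), pct_repopulated = numeric(),
                          delayed = integer(), alpha = integer(),
                          beta = integer(), gamma = integer(),
                          delta = integer(), unclassified = integer()))
    }
    calls <- callSubtypes(x, window)
    do.call(rbind, lapply(split(calls, calls$arm), function(d) {
        st <- factor(d$subtype[d$repopulated],
                     levels = c("alpha", "beta", "gamma", "delta",
                                "unclassified"))
        cnt <- table(st)
        data.frame(arm = d$arm[1], n = nrow(d),
                   repopulated = sum(d$repopulated),
                   pct_repopulated = 100 * mean(d$repopulated),
                   delayed = sum(d$delayed),
                   alpha = as.integer(cnt[["alpha"]]),
                   beta = as.integer(cnt[["beta"]]),
                   gamma = as.integer(cnt[["gamma"]]),
                   delta = as.integer(cnt[["delta"]]),
                   unclassified = as.integer(cnt[["unclassified"]]),
                   row.names = NULL)
    }))
}

#' Surviving-clone accounting
#'
#' Percent of surviving clones carrying a marker (e.g. GFP after lentiviral
#' transduction during hibernation): \code{100 * n_positive / n_surviving}.
#'
#' @param n_surviving number of surviving clones.
#' @param n_positive number of marker-positive clones among them.
#' @return percent positive.
#' @examples
#' clonePositiveFraction(284, 50)  # 17.6 to one decimal
#' @export
clonePositiveFraction <- function(n_surviving, n_positive) {
    stopifnot(n_surviving >= 0, n_positive >= 0, n_positive <= n_surviving)
    if (n_surviving == 0) return(NA_real_)
    100 * n_positive / n_surviving
}
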