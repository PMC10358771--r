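# Quality categorisation of per-organ metric values ("best" / "good" /
# "sub-optimal"), the 1-6 contour-editing scorecard, and the aggregation
# that turns per-case results into per-organ / per-model summary tables.

#' Category threshold tables
#'
#' Default thresholds: \emph{best} requires DSC >= 0.9, MDA <= 1.5 mm,
#' HD95 <= 5 mm, |PVD| <= 3\%, sDSC >= 0.85, rAPL <= 5 mm/cc; \emph{good}
#' requires DSC >= 0.8, MDA <= 3 mm, HD95 <= 10 mm, |PVD| <= 6\%,
#' sDSC >= 0.75, rAPL <= 10 mm/cc. PVD is graded on its absolute value
#' (over- and under-drawn contours both need edits). Boundary values
#' satisfy their threshold (inclusive comparisons). Every best threshold
#' must be at least as strict as its good counterpart.
#'
#' @param best,good Named numeric vectors over the six metrics
#'   (\code{dsc}, \code{mda_mm}, \code{hd95_mm}, \code{pvd_pct},
#'   \code{sdsc}, \code{rapl_mm_per_cc}).
#' @return A list of class \code{GradeTables} with elements \code{best},
#'   \code{good}, and \code{higher_better} (direction per metric).
#' @export
gradeTables <- function(best = c(dsc = 0.9, mda_mm = 1.5, hd95_mm = 5,
                                 pvd_pct = 3, sdsc = 0.85,
                                 rapl_mm_per_cc = 5),
                        good = c(dsc = 0.8, mda_mm = 3, hd95_mm = 10,
                                 pvd_pct = 6, sdsc = 0.75,
                                 rapl_mm_per_cc = 10)) {
    hb <- c(dsc = TRUE, mda_mm = FALSE, hd95_mm = FALSE, pvd_pct = FALSE,
            sdsc = TRUE, rapl_mm_per_cc = FALSE)
    need <- names(hb)
    stopifnot(all(need %in% names(best)), all(need %in% names(good)))
    strict <- ifelse(hb[need], best[need] >= good[need],
                     best[need] <= good[need])
    if (!all(strict))
        stop("every 'best' threshold must be at least as strict as 'good'")
    structure(list(best = best[need], good = good[need],
                   higher_better = hb), class = "GradeTables")
}

#' Grade one metric value
#'
#' Assigns \code{"best"}, \code{"good"} or \code{"suboptimal"}: best if the
#' best threshold is satisfied, else good if the good threshold is, else
#' suboptimal. PVD is graded on \code{abs(value)}; comparisons are
#' inclusive, so a DSC of exactly 0.9 is best.
#'
#' @param metric One of \code{"dsc"}, \code{"mda_mm"}, \code{"hd95_mm"},
#'   \code{"pvd_pct"}, \code{"sdsc"}, \code{"rapl_mm_per_cc"} (bare names
#'   \code{"mda"}, \code{"hd95"}, \code{"pvd"}, \code{"rapl"} are accepted).
#' @param value Finite metric value (vectorised).
#' @param tables A [gradeTables()].
#' @return Character vector of categories, ordered factor-like levels
#'   \code{best < good < suboptimal}.
#' @examples
#' gradeMetric("dsc", c(0.96, 0.9, 0.85, 0.7))
#' gradeMetric("pvd", -36.3)
#' @export
gradeMetric <- function(metric, value, tables = gradeTables()) {
    key <- .canonMetricName(metric)
    if (key == "pvd_pct") value <- abs(value)
    hb <- tables$higher_better[[key]]
    ok <- function(thr) if (hb) value >= thr else value <= thr
    out <- ifelse(ok(tables$best[[key]]), "best",
                  ifelse(ok(tables$good[[key]]), "good", "suboptimal"))
    out[!is.finite(value)] <- NA_character_
    out
}

.canonMetricName <- function(metric) {
    map <- c(dsc = "dsc", mda = "mda_mm", mda_mm = "mda_mm",
             hd95 = "hd95_mm", hd95_mm = "hd95_mm", pvd = "pvd_pct",
             pvd_pct = "pvd_pct", sdsc = "sdsc", rapl = "rapl_mm_per_cc",
             rapl_mm_per_cc = "rapl_mm_per_cc", apl = "apl_mm")
    key <- map[tolower(metric)]
    if (is.na(key) || key == "apl_mm")
        stop(sprintf("unknown or ungradable metric '%s'", metric))
    unname(key)
}

#' Score the editing burden of one contour (1-6 scorecard)
#'
#' Ordinal editing score: 1 = no edits, 2 = small deletions/expansions
#' (fewer than 5 slices), 3 = fixing incomplete segmentation (fewer than
#' 10 slices), 4 = edits at organ junctions or hilum (around 20 slices,
#' under half the organ), 5 = more than half the slices redrawn, 6 = more
#' than 80\% or full redo recommended. The score is the worse (higher) of
#' a slice-count-based score and a floor implied by the edit kind, so ties
#' resolve toward the higher score and the result is monotone in the
#' number of edited slices.
#'
#' @param n_edited_slices Number of axial slices edited.
#' @param total_slices Number of slices the organ spans.
#' @param edit_kind One of \code{"none"}, \code{"delete_or_expand"},
#'   \code{"fix_incomplete"}, \code{"junction_or_hilum"},
#'   \code{"majority_redraw"}, \code{"full_redo"}.
#' @return Integer score in 1..6.
#' @examples
#' scoreEdits(0, 40)                 # 1
#' scoreEdits(60, 100)               # 5
#' scoreEdits(85, 100)               # 6
#' scoreEdits(3, 40, "delete_or_expand")  # 2
#' @export
scoreEdits <- function(n_edited_slices, total_slices,
                       edit_kind = c("none", "delete_or_expand",
                                     "fix_incomplete", "junction_or_hilum",
                                     "majority_redraw", "full_redo")) {
    edit_kind <- match.arg(edit_kind)
    if (n_edited_slices < 0 || total_slices < 1 ||
        n_edited_slices > total_slices)
        stop("inconsistent edit record: need 0 <= n_edited <= total_slices")
    frac <- n_edited_slices / total_slices
    countScore <-
        if (n_edited_slices == 0) 1L
        else if (frac > 0.8) 6L
        else if (frac > 0.5) 5L
        else if (n_edited_slices >= 20) 4L
        else if (n_edited_slices >= 10) 4L
        else if (n_edited_slices >= 5) 3L
        else 2L
    kindFloor <- c(none = 1L, delete_or_expand = 2L, fix_incomplete = 3L,
                   junction_or_hilum = 4L, majority_redraw = 5L,
                   full_redo = 6L)[[edit_kind]]
    if (edit_kind == "full_redo") return(6L)
    if (n_edited_slices == 0) return(1L)
    max(countScore, kindFloor)
}

#' Aggregate per-case metric results into summary tables
#'
#' From a long-format collection of per-(case, model, organ) metric values,
#' produces (a) per-organ, per-model means across cases; (b) per-model
#' overall means, computed as the \emph{unweighted} mean of the per-organ
#' means (each organ counts once, whatever its volume or case count); and
#' (c) radar-ready normalised values in which each per-organ mean is
#' divided by the maximum absolute value of that metric across all organs
#' and models, so the worst cell of each metric maps to magnitude 1.
#'
#' @param results Data.frame with columns \code{case_id} (optional),
#'   \code{model}, \code{organ}, and one column per metric (any subset of
#'   \code{dsc}, \code{mda_mm}, \code{hd95_mm}, \code{pvd_pct},
#'   \code{sdsc}, \code{apl_mm}, \code{rapl_mm_per_cc}).
#' @return List with data.frames \code{per_organ}, \code{overall},
#'   \code{radar}.
#' @export
aggregateMetrics <- function(results) {
    if (!is.data.frame(results) || nrow(results) == 0)
        stop("results must be a non-empty data.frame")
    stopifnot(all(c("model", "organ") %in% names(results)))
    metricCols <- intersect(c("dsc", "mda_mm", "hd95_mm", "pvd_pct",
                              "sdsc", "apl_mm", "rapl_mm_per_cc"),
                            names(results))
    if (!length(metricCols)) stop("no metric columns found")
    perOrgan <- stats::aggregate(results[metricCols],
                                 by = list(model = results$model,
                                           organ = results$organ),
                                 FUN = mean, na.rm = TRUE)
    overall <- stats::aggregate(perOrgan[metricCols],
                                by = list(model = perOrgan$model),
                                FUN = mean, na.rm = TRUE)
    radar <- perOrgan
    for (mc in metricCols) {
        mx <- max(abs(perOrgan[[mc]]), na.rm = TRUE)
        radar[[mc]] <- if (mx > 0) perOrgan[[mc]] / mx else perOrgan[[mc]]
    }
    list(per_organ = perOrgan, overall = overall, radar = radar)
}

#' Per-contour category by majority vote
#'
#' Combines the six per-metric categories of one contour into a single
#' label: the category receiving the most votes, ties resolved toward the
#' worse category (suboptimal over good over best). Missing metric values
#' abstain.
#'
#' @param metrics Named numeric vector (or one-row data.frame) of metric
#'   values for one contour.
#' @param tables A [gradeTables()].
#' @return One of \code{"best"}, \code{"good"}, \code{"suboptimal"}.
#' @export
contourCategory <- function(metrics, tables = gradeTables()) {
    if (is.data.frame(metrics)) metrics <- unlist(metrics[1, ])
    keys <- intersect(names(tables$best), names(metrics))
    if (!length(keys)) stop("no gradable metrics supplied")
    cats <- vapply(keys, function(k) {
        v <- as.numeric(metrics[[k]])
        if (!is.finite(v)) NA_character_ else gradeMetric(k, v, tables)
    }, character(1))
    cats <- cats[!is.na(cats)]
    if (!length(cats)) stop("all metric values missing")
    lev <- c("suboptimal", "good", "best")  # worse first for tie-breaking
    counts <- table(factor(cats, levels = lev))
    lev[which.max(counts)]   # which.max returns the first (= worse) on ties
}

#' Percentage of contours graded best or good
#'
#' Each row of \code{results} is one contour (one organ of one case under
#' one model); its category is the majority vote over its six per-metric
#' categories ([contourCategory()]). Returns the percentage of contours
#' whose category is best or good.
#'
#' @inheritParams aggregateMetrics
#' @param tables A [gradeTables()].
#' @return Percentage in [0, 100].
#' @export
percentBestGood <- function(results, tables = gradeTables()) {
    if (!is.data.frame(results) || nrow(results) == 0)
        stop("results must be a non-empty data.frame")
    metricCols <- intersect(names(tables$best), names(results))
    if (!length(metricCols)) stop("no metric columns found")
    cats <- vapply(seq_len(nrow(results)), function(i)
        contourCategory(unlist(results[i, metricCols, drop = FALSE]),
                        tables), character(1))
    100 * mean(cats %in% c("best", "good"))
}
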