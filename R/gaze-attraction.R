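#' Occupancy pixel counts for one level and one fixation area
#'
#' Counts the pixels entering the gaze-attraction ratio: level-`level`
#' pixels inside the fixation-area mask, total mask pixels, level pixels in
#' the whole image, and total image pixels.
#'
#' @param dmap a [DiscretizedFeatureMap].
#' @param level intensity level in `1..n_levels`.
#' @param mask logical matrix of the same shape as the map (e.g. from
#'   [fixationDiskMask()]).
#' @return an [OccupancyCounts] object.
#' @export
occupancyCounts <- function(dmap, level, mask) {
    stopifnot(is(dmap, "DiscretizedFeatureMap"))
    if (!all(dim(mask) == dim(dmap@level)))
        stop("mask shape must equal the feature-map shape")
    if (level < 1L || level > dmap@n_levels)
        stop("level must lie in 1..n_levels")
    lv <- dmap@level
    new("OccupancyCounts",
        n_feature_fa  = sum(lv[mask] == level),
        n_all_fa      = sum(mask),
        n_feature_img = sum(lv == level),
        n_all_img     = length(lv))
}

#' Gaze attraction of a visual feature in a fixation area
#'
#' The relative occupancy rate: the feature's occupancy inside the
#' fixation area divided by its occupancy in the entire image,
#' \deqn{GA = \frac{N^{FA}_{F_L} / N^{FA}_{all}}{N^{I}_{F_L} / N^{I}_{all}}.}
#' A value of 1 means the fixation area contains the feature at exactly
#' its image-wide density (chance); values above 1 mean the gaze is drawn
#' to the feature. When the feature level is absent from the whole image
#' the statistic is undefined and `NA` is returned (the image is excluded
#' from averages rather than contributing 0, which would conflate "absent"
#' with "avoided").
#'
#' @param counts an [OccupancyCounts] object.
#' @return the gaze-attraction value, or `NA` when undefined.
#' @examples
#' cts <- new("OccupancyCounts", n_feature_fa = 4, n_all_fa = 4,
#'            n_feature_img = 25, n_all_img = 100)
#' gaValue(cts)  # (4/4) / (25/100) = 4
#' @export
gaValue <- function(counts) {
    stopifnot(is(counts, "OccupancyCounts"))
    if (counts@n_all_fa == 0)
        stop("empty fixation area: n_all_fa = 0")
    if (counts@n_feature_img == 0) return(NA_real_)
    (counts@n_feature_fa / counts@n_all_fa) /
        (counts@n_feature_img / counts@n_all_img)
}

## Per-level pixel counts of a circular fixation area around (x, y),
## using a local window rather than a full-image mask. With wrap = TRUE
## the disk wraps around the image (torus), giving an edge-free setting
## used for chance calibration. Identical to fixationDiskMask counts for
## wrap = FALSE.
.fixationLevelCounts <- function(lev, n_levels, x, y, r, wrap = FALSE) {
    h <- nrow(lev); w <- ncol(lev)
    cx <- ceiling(x - r):floor(x + r)
    cy <- ceiling(y - r):floor(y + r)
    if (!wrap) {
        cx <- cx[cx >= 0 & cx < w]
        cy <- cy[cy >= 0 & cy < h]
    }
    mask <- outer((cy - y)^2, (cx - x)^2, `+`) <= r^2
    ci <- if (wrap) (cx %% w) + 1L else cx + 1L
    ri <- if (wrap) (cy %% h) + 1L else cy + 1L
    sub <- lev[ri, ci, drop = FALSE]
    list(counts = tabulate(sub[mask], nbins = n_levels), n_fa = sum(mask))
}

## GA values for all levels of one fixation: vector of length n_levels,
## NA where the level is absent from the image.
.gaAllLevels <- function(dmap, x, y, r, img_counts = NULL, wrap = FALSE) {
    lev <- dmap@level
    if (is.null(img_counts)) img_counts <- levelOccupancy(dmap)
    fc <- .fixationLevelCounts(lev, dmap@n_levels, x, y, r, wrap)
    if (fc$n_fa == 0) stop("empty fixation area")
    ga <- (fc$counts / fc$n_fa) / (img_counts / length(lev))
    ga[img_counts == 0] <- NA_real_
    ga
}

#' Gaze-attraction time course of one trial
#'
#' For each fixation of the trial, the gaze-attraction value of its
#' 1-degree circular fixation area is written onto the time grid over the
#' fixation's full duration, `[onset_ms, min(offset_ms, trial_ms))`; the
#' series is zero whenever no fixation is in progress. When the feature
#' level is absent from the image the series stays zero and the result is
#' flagged missing (attribute `missing`), so that [meanTimeCourse()] can
#' exclude the image.
#'
#' @param trial a filtered [TrialRecord].
#' @param dmap the [DiscretizedFeatureMap] of the trial's stimulus.
#' @param level intensity level.
#' @param geometry a [ViewingGeometry].
#' @param radius_deg fixation-area radius in visual degrees.
#' @param grid_ms time step of the grid (default 1 ms, matching a 1000 Hz
#'   recording).
#' @param onset_only if `TRUE`, write the value only at the fixation onset
#'   sample instead of over the fixation's duration.
#' @return numeric vector of length `trial_ms / grid_ms` with attribute
#'   `missing` (logical).
#' @export
trialTimeCourse <- function(trial, dmap, level, geometry, radius_deg = 1.0,
                            grid_ms = 1, onset_only = FALSE) {
    stopifnot(is(trial, "TrialRecord"), is(dmap, "DiscretizedFeatureMap"))
    n <- as.integer(geometry@trial_ms / grid_ms)
    values <- numeric(n)
    fx <- trial@fixations
    img_counts <- levelOccupancy(dmap)
    missing <- img_counts[level] == 0L
    r <- radius_deg * suppressWarnings(pxPerDeg(geometry))
    if (!missing && nrow(fx) > 0L) {
        for (k in seq_len(nrow(fx))) {
            ga <- .gaAllLevels(dmap, fx$x_px[k], fx$y_px[k], r,
                               img_counts)[level]
            idx <- .gridInterval(fx$onset_ms[k],
                                 min(fx$offset_ms[k], geometry@trial_ms),
                                 grid_ms, n, onset_only)
            if (length(idx)) values[idx] <- ga
        }
    }
    attr(values, "missing") <- missing
    values
}

## sample indices whose time (i-1)*grid_ms falls in [onset, offset)
.gridInterval <- function(onset, offset, grid_ms, n, onset_only = FALSE) {
    i1 <- as.integer(ceiling(onset / grid_ms)) + 1L
    if (onset_only) return(if (i1 <= n) i1 else integer(0))
    i2 <- min(as.integer(ceiling(offset / grid_ms)), n)
    if (i1 > i2) integer(0) else i1:i2
}

#' Average per-image time courses into a participant time course
#'
#' Pointwise mean of the per-image gaze-attraction series over a
#' participant's presented images; series flagged missing (feature level
#' absent from that image) are excluded from the average for that
#' feature x level. The result is invariant to the order of the images.
#'
#' @param per_image_series list of numeric series from
#'   [trialTimeCourse()] (equal lengths).
#' @param feature_name,level,participant_id identifiers stored in the
#'   result.
#' @param grid_ms time step of the series.
#' @param is_chance whether the series come from coordinate-randomized
#'   fixations.
#' @return a [GATimeCourse].
#' @export
meanTimeCourse <- function(per_image_series, feature_name = "feature",
                           level = 1L, participant_id = "participant",
                           grid_ms = 1, is_chance = FALSE) {
    if (length(per_image_series) == 0L)
        stop("no per-image series supplied")
    miss <- vapply(per_image_series, function(s)
        isTRUE(attr(s, "missing")), logical(1L))
    used <- per_image_series[!miss]
    n_img <- length(used)
    vals <- if (n_img == 0L) numeric(length(per_image_series[[1L]]))
            else Reduce(`+`, used) / n_img
    new("GATimeCourse", feature_name = as.character(feature_name),
        level = as.integer(level), participant_id = as.character(participant_id),
        grid_ms = grid_ms, values = as.numeric(vals),
        is_chance = is_chance, n_images = as.integer(n_img))
}

#' Participant gaze-attraction time courses for all levels of one feature
#'
#' Convenience driver: computes [trialTimeCourse()] for every trial and
#' every intensity level of one feature and averages over the
#' participant's images with [meanTimeCourse()]. All trials must belong to
#' one participant.
#'
#' @param trials list of filtered [TrialRecord] objects (one participant).
#' @param dmaps named list mapping `stimulus_id` to
#'   [DiscretizedFeatureMap] for one feature.
#' @param geometry a [ViewingGeometry].
#' @param levels integer vector of levels (default all).
#' @param radius_deg,grid_ms,onset_only passed to [trialTimeCourse()].
#' @return list of [GATimeCourse], one per level.
#' @export
participantTimeCourses <- function(trials, dmaps, geometry, levels = NULL,
                                   radius_deg = 1.0, grid_ms = 1,
                                   onset_only = FALSE) {
    if (length(trials) == 0L) stop("no trials supplied")
    pid <- trials[[1L]]@participant_id
    n_levels <- dmaps[[1L]]@n_levels
    if (is.null(levels)) levels <- seq_len(n_levels)
    n <- as.integer(geometry@trial_ms / grid_ms)
    r <- radius_deg * suppressWarnings(pxPerDeg(geometry))
    feature <- dmaps[[1L]]@feature_name

    sums <- matrix(0, nrow = n, ncol = length(levels))
    n_used <- integer(length(levels))
    for (tr in trials) {
        dmap <- dmaps[[tr@stimulus_id]]
        if (is.null(dmap)) stop("no feature map for stimulus ", tr@stimulus_id)
        img_counts <- levelOccupancy(dmap)
        fx <- tr@fixations
        series <- matrix(0, nrow = n, ncol = length(levels))
        if (nrow(fx) > 0L) {
            for (k in seq_len(nrow(fx))) {
                ga <- .gaAllLevels(dmap, fx$x_px[k], fx$y_px[k], r, img_counts)
                idx <- .gridInterval(fx$onset_ms[k],
                                     min(fx$offset_ms[k], geometry@trial_ms),
                                     grid_ms, n, onset_only)
                if (length(idx))
                    for (j in seq_along(levels)) {
                        v <- ga[levels[j]]
                        if (!is.na(v)) series[idx, j] <- v
                    }
            }
        }
        present <- img_counts[levels] > 0L
        sums[, present] <- sums[, present] + series[, present, drop = FALSE]
        n_used[present] <- n_used[present] + 1L
    }
    out <- vector("list", length(levels))
    for (j in seq_along(levels)) {
        vals <- if (n_used[j] > 0L) sums[, j] / n_used[j] else numeric(n)
        out[[j]] <- new("GATimeCourse", feature_name = feature,
            level = as.integer(levels[j]), participant_id = pid,
            grid_ms = grid_ms, values = vals, is_chance = FALSE,
            n_images = n_used[j])
    }
    names(out) <- paste0("level", levels)
    out
}
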