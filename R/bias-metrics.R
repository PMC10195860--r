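#' Spatial gaze bias
#'
#' The time average of the gaze-attraction time course over the full trial
#' grid (zeros between fixations included). It summarizes how strongly a
#' feature draws fixations overall, ignoring when they happen; 1 is the
#' chance reference for uniform feature coverage.
#'
#' @param tc a [GATimeCourse] or a numeric series.
#' @return the spatial gaze bias (scalar, >= 0).
#' @export
spatialGazeBias <- function(tc) {
    v <- if (is(tc, "GATimeCourse")) tc@values else as.numeric(tc)
    mean(v)
}

#' Temporal gaze bias
#'
#' Quantifies how early the gaze-attraction mass occurs: the series is
#' min-max normalized to `[0, 1]` (the constant component is irrelevant to
#' timing), integrated cumulatively (trapezoidal rule), the cumulative
#' integral is again min-max normalized, and its area over normalized time
#' is returned. Convex cumulative curves (early mass) give values above
#' 0.5, concave ones (late mass) below; a constant series has no temporal
#' structure and returns 0.5 by definition, the limit of vanishing
#' transients.
#'
#' @param tc a [GATimeCourse] or a numeric series.
#' @return temporal gaze bias in `[0, 1]`.
#' @examples
#' temporalGazeBias(seq(0, 1, length.out = 5000))      # ramp up -> 1/3
#' temporalGazeBias(seq(1, 0, length.out = 5000))      # ramp down -> 2/3
#' temporalGazeBias(rep(2, 5000))                      # flat -> 0.5
#' @export
temporalGazeBias <- function(tc) {
    v <- if (is(tc, "GATimeCourse")) tc@values else as.numeric(tc)
    if (length(v) < 2L) return(0.5)
    rng <- range(v)
    if (diff(rng) == 0) return(0.5)
    x <- (v - rng[1L]) / diff(rng)
    ci <- pracma::cumtrapz(x)[, 1L]
    rci <- range(ci)
    if (diff(rci) == 0) return(0.5)
    ci <- (ci - rci[1L]) / diff(rci)
    pracma::trapz(ci) / (length(v) - 1L)
}

#' Chance-level gaze-attraction time courses by coordinate randomization
#'
#' Empirical chance levels: every fixation's coordinates are redrawn
#' uniformly over the stimulus while its onset/offset timing is kept, the
#' participant's mean time course is recomputed, and the result is
#' averaged over `n_randomizations` replicates. The averaged chance course
#' preserves the timing support of the original data exactly; its
#' occupancy values approach the image-wide feature density.
#'
#' By default coordinates are drawn over the full stimulus including its
#' edges, where the clipped fixation disk loses area (this is what makes
#' edge-attenuated feature maps such as Itti-Koch saliency fall below
#' chance when real gaze is center-biased). For calibration an edge-free
#' variant is available: `wrap = TRUE` evaluates the disk on a torus, and
#' `interior_margin_px` restricts the sampled centers to the image
#' interior.
#'
#' @param trials list of filtered [TrialRecord] objects (one participant).
#' @param dmaps named list mapping `stimulus_id` to
#'   [DiscretizedFeatureMap] for one feature.
#' @param geometry a [ViewingGeometry].
#' @param levels intensity levels to evaluate (default all).
#' @param n_randomizations number of coordinate reassignments (default
#'   100).
#' @param seed RNG seed for this participant's randomization stream.
#' @param radius_deg,grid_ms as in [trialTimeCourse()].
#' @param wrap evaluate fixation disks on a torus (edge-free) and draw
#'   centers over a full torus period, making the expected gaze
#'   attraction exactly 1 at every level.
#' @param interior_margin_px restrict random centers to
#'   `[margin, dim - 1 - margin]` (ignored when `wrap = TRUE`).
#' @return `chanceTimeCourses`: a list of [GATimeCourse] objects
#'   (`is_chance = TRUE`), one per level, each carrying the per-replicate
#'   spatial biases in attribute `replicate_spatial`;
#'   `chanceTimeCourse`: a single [GATimeCourse] for `level`.
#' @export
chanceTimeCourses <- function(trials, dmaps, geometry, levels = NULL,
                              n_randomizations = 100, seed = 1L,
                              radius_deg = 1.0, grid_ms = 1,
                              wrap = FALSE, interior_margin_px = 0) {
    if (n_randomizations < 1) stop("n_randomizations must be >= 1")
    if (length(trials) == 0L) stop("no trials supplied")
    pid <- trials[[1L]]@participant_id
    n_levels <- dmaps[[1L]]@n_levels
    if (is.null(levels)) levels <- seq_len(n_levels)
    feature <- dmaps[[1L]]@feature_name
    n <- as.integer(geometry@trial_ms / grid_ms)
    r <- radius_deg * suppressWarnings(pxPerDeg(geometry))
    w <- geometry@width_px; h <- geometry@height_px
    R <- as.integer(n_randomizations)
    L <- length(levels)

    ## images contributing per level (same exclusion rule as the original)
    img_counts_all <- lapply(trials, function(tr)
        levelOccupancy(dmaps[[tr@stimulus_id]]))
    n_used <- integer(L)
    for (ic in img_counts_all) n_used <- n_used + as.integer(ic[levels] > 0L)

    sums <- matrix(0, nrow = n, ncol = L)
    rep_spatial <- matrix(0, nrow = R, ncol = L)

    set.seed(as.integer(seed))
    if (wrap) {
        ## a full torus period, so reassigned centers form an exactly
        ## uniform translation of the disk over the image
        xlo <- 0; xhi <- w; ylo <- 0; yhi <- h
    } else {
        xlo <- interior_margin_px; xhi <- (w - 1) - interior_margin_px
        ylo <- interior_margin_px; yhi <- (h - 1) - interior_margin_px
    }
    for (ti in seq_along(trials)) {
        tr <- trials[[ti]]
        dmap <- dmaps[[tr@stimulus_id]]
        img_counts <- img_counts_all[[ti]]
        present <- img_counts[levels] > 0L
        fx <- tr@fixations
        if (nrow(fx) == 0L || !any(present)) next
        wt <- ifelse(present, 1 / pmax(n_used, 1L), 0)
        for (k in seq_len(nrow(fx))) {
            xs <- runif(R, xlo, xhi)
            ys <- runif(R, ylo, yhi)
            ga <- matrix(0, nrow = R, ncol = L)
            for (rr in seq_len(R))
                ga[rr, ] <- .gaAllLevels(dmap, xs[rr], ys[rr], r,
                                         img_counts, wrap)[levels]
            ga[, !present] <- 0
            idx <- .gridInterval(fx$onset_ms[k],
                                 min(fx$offset_ms[k], geometry@trial_ms),
                                 grid_ms, n)
            if (!length(idx)) next
            mga <- colMeans(ga)
            sums[idx, ] <- sums[idx, ] +
                matrix(mga * wt, nrow = length(idx), ncol = L, byrow = TRUE)
            rep_spatial <- rep_spatial +
                ga * matrix(wt * length(idx) / n, nrow = R, ncol = L,
                            byrow = TRUE)
        }
    }

    out <- vector("list", L)
    for (j in seq_len(L)) {
        tc <- new("GATimeCourse", feature_name = feature,
            level = as.integer(levels[j]), participant_id = pid,
            grid_ms = grid_ms, values = sums[, j], is_chance = TRUE,
            n_images = n_used[j])
        attr(tc, "replicate_spatial") <- rep_spatial[, j]
        out[[j]] <- tc
    }
    names(out) <- paste0("level", levels)
    out
}

#' @rdname chanceTimeCourses
#' @param level a single intensity level.
#' @export
chanceTimeCourse <- function(trials, dmaps, level, geometry,
                             n_randomizations = 100, seed = 1L,
                             radius_deg = 1.0, grid_ms = 1,
                             wrap = FALSE, interior_margin_px = 0) {
    chanceTimeCourses(trials, dmaps, geometry, levels = level,
                      n_randomizations = n_randomizations, seed = seed,
                      radius_deg = radius_deg, grid_ms = grid_ms,
                      wrap = wrap, interior_margin_px = interior_margin_px)[[1L]]
}

#' Spatial and temporal gaze bias with matched chance levels
#'
#' Applies [spatialGazeBias()] and [temporalGazeBias()] to each
#' participant time course and its matched chance course, returning a tidy
#' summary table.
#'
#' @param tcs list of [GATimeCourse] objects (one feature, one
#'   participant; e.g. from [participantTimeCourses()]).
#' @param chance_tcs matching list of chance courses from
#'   [chanceTimeCourses()], or `NULL` to omit chance columns.
#' @return `data.frame` with columns `participant`, `feature`, `level`,
#'   `spatial_bias`, `temporal_bias`, `chance_spatial`, `chance_temporal`,
#'   `n_images`.
#' @export
biasSummary <- function(tcs, chance_tcs = NULL) {
    rows <- lapply(seq_along(tcs), function(j) {
        tc <- tcs[[j]]
        ch_s <- ch_t <- NA_real_
        if (!is.null(chance_tcs)) {
            ch <- chance_tcs[[j]]
            stopifnot(ch@level == tc@level)
            ch_s <- spatialGazeBias(ch)
            ch_t <- temporalGazeBias(ch)
        }
        data.frame(participant = tc@participant_id, feature = tc@feature_name,
                   level = tc@level, spatial_bias = spatialGazeBias(tc),
                   temporal_bias = temporalGazeBias(tc),
                   chance_spatial = ch_s, chance_temporal = ch_t,
                   n_images = tc@n_images)
    })
    do.call(rbind, rows)
}
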