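#' Fixation-latency histograms by fixation order
#'
#' Histograms of fixation onset times (latency relative to stimulus
#' onset), separately per fixation order up to `max_order`, with
#' left-closed bins of `bin_ms` over `[0, trial_ms)`. An onset exactly on
#' a bin edge belongs to the bin opening at that edge.
#'
#' @param trials list of filtered [TrialRecord] objects (one participant).
#' @param bin_ms bin width in ms (default 20).
#' @param max_order highest fixation order analyzed (default 10).
#' @param trial_ms trial duration in ms (default 5000).
#' @return `data.frame` with columns `order`, `bin_start_ms`, `count`
#'   covering all orders `1..max_order` and all bins.
#' @export
latencyHistogram <- function(trials, bin_ms = 20, max_order = 10,
                             trial_ms = 5000) {
    if (bin_ms <= 0) stop("bin_ms must be > 0")
    edges <- seq(0, trial_ms - bin_ms, by = bin_ms)
    n_bins <- length(edges)
    counts <- matrix(0L, nrow = n_bins, ncol = max_order)
    for (tr in trials) {
        fx <- tr@fixations
        if (nrow(fx) == 0L) next
        sel <- fx$order <= max_order
        if (!any(sel)) next
        b <- pmin(fx$onset_ms[sel] %/% bin_ms + 1L, n_bins)
        o <- fx$order[sel]
        for (i in seq_along(b))
            counts[b[i], o[i]] <- counts[b[i], o[i]] + 1L
    }
    data.frame(order = rep(seq_len(max_order), each = n_bins),
               bin_start_ms = rep(edges, times = max_order),
               count = as.integer(counts))
}

#' Gaze attraction by fixation order
#'
#' For each fixation order `1..max_order`, the mean gaze-attraction value
#' of the order-k fixations pooled over a participant's trials, at one
#' feature intensity level. Images in which the level is absent are
#' excluded (undefined occupancy denominator).
#'
#' @param trials list of filtered [TrialRecord] objects (one participant).
#' @param dmaps named list mapping `stimulus_id` to
#'   [DiscretizedFeatureMap] for one feature.
#' @param level intensity level.
#' @param geometry a [ViewingGeometry].
#' @param max_order highest fixation order analyzed (default 10).
#' @param radius_deg fixation-area radius in visual degrees.
#' @return `data.frame` with columns `order`, `mean_ga`, `n` (`mean_ga`
#'   is `NA` for orders with no fixations).
#' @export
gaByOrder <- function(trials, dmaps, level, geometry, max_order = 10,
                      radius_deg = 1.0) {
    r <- radius_deg * suppressWarnings(pxPerDeg(geometry))
    sums <- numeric(max_order)
    ns <- integer(max_order)
    for (tr in trials) {
        dmap <- dmaps[[tr@stimulus_id]]
        if (is.null(dmap)) stop("no feature map for stimulus ", tr@stimulus_id)
        img_counts <- levelOccupancy(dmap)
        if (img_counts[level] == 0L) next
        fx <- tr@fixations
        if (nrow(fx) == 0L) next
        sel <- which(fx$order <= max_order)
        for (k in sel) {
            ga <- .gaAllLevels(dmap, fx$x_px[k], fx$y_px[k], r,
                               img_counts)[level]
            o <- fx$order[k]
            sums[o] <- sums[o] + ga
            ns[o] <- ns[o] + 1L
        }
    }
    data.frame(order = seq_len(max_order),
               mean_ga = ifelse(ns > 0L, sums / pmax(ns, 1L), NA_real_),
               n = ns)
}
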