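#' Configure the synthetic free-viewing cohort
#'
#' Builds a [SimConfig] describing a simulated free-viewing experiment
#' whose scanpaths are biased toward high-intensity regions of known
#' feature fields with a feature-specific, time-varying gain. The
#' defaults emulate the study conditions the analysis is designed for: a
#' 20-participant cohort, 800 x 600 px stimuli subtending 20 x 15 degrees
#' viewed for 5000 ms, gamma-distributed fixation durations (mean 250 ms),
#' first-fixation latencies near 270 ms (normal, sd 40 ms), an occasional
#' anticipatory event, and three features whose spatial gains are ordered
#' `feature1 < feature2 < feature3` with an early (500 ms) transient gain
#' on `feature3`.
#'
#' @param n_participants,n_stimuli cohort dimensions (defaults 20 and 30).
#' @param geometry a [ViewingGeometry] for the simulated display.
#' @param feature_names simulated feature labels.
#' @param bias_weights named non-negative per-feature spatial gains
#'   (softmax inverse temperature on the `[0, 1]` intensity fields).
#' @param temporal_baseline baseline b of the time-varying gain
#'   `g_f(t) = b + A_f exp(-(t - t_peak)^2 / (2 s^2))`.
#' @param temporal_amplitude,temporal_peak_ms,temporal_width_ms per-feature
#'   transient parameters A, t_peak, s (recycled to the feature count).
#' @param duration_shape,duration_scale_ms gamma fixation-duration model
#'   (defaults 4 and 62.5: mean 250 ms).
#' @param first_latency_mean_ms,first_latency_sd_ms first-fixation latency
#'   model (defaults 270 and 40 ms).
#' @param anticipatory_rate probability of an injected anticipatory
#'   fixation with onset < 80 ms (default 0.05).
#' @param center_bias_sd_px Gaussian center-bias width in px; `NA`
#'   (default) disables the center bias.
#' @param saccade_gap_ms fixed inter-fixation gap (default 30 ms).
#' @param field_smoothness_px Gaussian blur sigma of the synthetic feature
#'   fields (default: stimulus width / 10).
#' @param master_seed master RNG seed.
#' @return a [SimConfig].
#' @export
simConfig <- function(n_participants = 20, n_stimuli = 30,
                      geometry = ViewingGeometry(),
                      feature_names = c("feature1", "feature2", "feature3"),
                      bias_weights = c(feature1 = 1, feature2 = 2, feature3 = 4),
                      temporal_baseline = 1,
                      temporal_amplitude = c(0, 0, 1.5),
                      temporal_peak_ms = 500,
                      temporal_width_ms = 200,
                      duration_shape = 4, duration_scale_ms = 62.5,
                      first_latency_mean_ms = 270, first_latency_sd_ms = 40,
                      anticipatory_rate = 0.05,
                      center_bias_sd_px = NA_real_,
                      saccade_gap_ms = 30,
                      field_smoothness_px = NULL,
                      master_seed = 1L) {
    nf <- length(feature_names)
    if (is.null(field_smoothness_px))
        field_smoothness_px <- geometry@width_px / 10
    new("SimConfig",
        n_participants = as.integer(n_participants),
        n_stimuli = as.integer(n_stimuli),
        geometry = geometry,
        feature_names = feature_names,
        bias_weights = setNames(rep_len(as.numeric(bias_weights), nf),
                                feature_names),
        temporal_baseline = as.numeric(temporal_baseline),
        temporal_amplitude = rep_len(as.numeric(temporal_amplitude), nf),
        temporal_peak_ms = rep_len(as.numeric(temporal_peak_ms), nf),
        temporal_width_ms = rep_len(as.numeric(temporal_width_ms), nf),
        duration_shape = as.numeric(duration_shape),
        duration_scale_ms = as.numeric(duration_scale_ms),
        first_latency_mean_ms = as.numeric(first_latency_mean_ms),
        first_latency_sd_ms = as.numeric(first_latency_sd_ms),
        anticipatory_rate = as.numeric(anticipatory_rate),
        center_bias_sd_px = as.numeric(center_bias_sd_px),
        saccade_gap_ms = as.numeric(saccade_gap_ms),
        field_smoothness_px = as.numeric(field_smoothness_px),
        master_seed = as.integer(master_seed))
}

#' Generate a smooth synthetic feature-intensity field
#'
#' Seeded uniform white noise, optionally blurred with a Gaussian kernel
#' of sigma `smoothness_px`, then min-max rescaled to `[0, 1]`. Stands in
#' for the per-stimulus feature maps that a network back-projection or
#' saliency model would produce. Unsmoothed fields occupy all ten
#' intensity levels evenly; smoothing concentrates occupancy in the
#' middle levels, as graded natural feature maps do. Bit-reproducible per
#' seed.
#'
#' @param width_px,height_px field size in pixels.
#' @param smoothness_px Gaussian blur sigma in px; 0 yields white noise.
#' @param seed RNG seed.
#' @param stimulus_id,feature_name identifiers for the result.
#' @return a [FeatureMap] with values in `[0, 1]`.
#' @export
genFeatureField <- function(width_px, height_px, smoothness_px, seed,
                            stimulus_id = "stimulus",
                            feature_name = "synthetic") {
    stopifnot(width_px > 0, height_px > 0)
    set.seed(as.integer(seed))
    m <- matrix(stats::runif(width_px * height_px), nrow = height_px)
    if (smoothness_px > 0)
        m <- .gaussBlurPeriodic(m, smoothness_px)
    if (diff(range(m)) < 1e-12) m[] <- mean(m)
    rescaleIntensity(FeatureMap(m - min(m), stimulus_id, feature_name))
}

## separable Gaussian blur with periodic (torus) boundary, so synthetic
## fields are stationary with no edge artifacts; the kernel is capped at
## the image size, under which very large sigmas approach the field mean
.gaussBlurPeriodic <- function(m, sigma) {
    if (sigma >= min(dim(m))) {
        ## blur scale beyond the torus period: the field collapses to its mean
        m[] <- mean(m)
        return(m)
    }
    k <- min(2L * ceiling(3 * sigma) + 1L,
             (min(dim(m)) - 1L) %/% 2L * 2L + 1L)
    if (k < 3L) return(m)
    half <- (k - 1L) / 2
    g <- exp(-(-half:half)^2 / (2 * sigma^2))
    kern <- outer(g, g) / sum(g)^2
    as.matrix(EBImage::filter2(m, kern, boundary = "circular"))
}

## time-varying gain g_f(t) = b + A exp(-(t - t_peak)^2 / (2 s^2))
.temporalGain <- function(t, b, A, t_peak, s) {
    if (A != 0 && s <= 0) stop("temporal width s must be > 0 when A != 0")
    if (A == 0) return(rep(b, length(t)))
    b + A * exp(-(t - t_peak)^2 / (2 * s^2))
}

#' Hypothetical gaze-attraction time course
#'
#' The parametric course `g(t) = b + A exp(-(t - t_peak)^2 / (2 s^2))`
#' for `t >= onset_delay_ms` (and 0 before), sampled on the trial grid.
#' It is used to validate the temporal-bias index: the index decreases as
#' the transient moves later and increases with the transient amplitude
#' for early peaks.
#'
#' The onset delay emulates the empty head of measured gaze-attraction
#' courses (no fixation before the first-fixation latency, about 270 ms),
#' which anchors the course minimum at zero. This anchor is what makes
#' the index sensitive to the transient amplitude: relative to a zero
#' floor, a larger transient shrinks the normalized baseline, whereas a
#' transient riding on a strictly positive floor is removed entirely by
#' the min-max normalization regardless of its amplitude.
#'
#' @param b baseline level.
#' @param A transient amplitude.
#' @param t_peak_ms transient peak time (ms).
#' @param s_ms transient width (ms).
#' @param duration_ms trial duration (default 5000).
#' @param grid_ms sampling step (default 1).
#' @param onset_delay_ms zero-valued head of the course (default 270).
#' @return numeric series of length `duration_ms / grid_ms`.
#' @examples
#' temporalGazeBias(hypotheticalGATimeCourse(1, 2, 500, 200))   # > 0.5
#' temporalGazeBias(hypotheticalGATimeCourse(1, 2, 4500, 200))  # < 0.5
#' @export
hypotheticalGATimeCourse <- function(b, A, t_peak_ms, s_ms,
                                     duration_ms = 5000, grid_ms = 1,
                                     onset_delay_ms = 270) {
    if (duration_ms <= 0) stop("duration_ms must be > 0")
    t <- seq(0, duration_ms - grid_ms, by = grid_ms)
    g <- .temporalGain(t, b, A, t_peak_ms, s_ms)
    g[t < onset_delay_ms] <- 0
    g
}

#' Simulate one scanpath over known feature fields
#'
#' Generates the fixation sequence of one trial: the first onset is drawn
#' from the first-latency model, subsequent onsets follow gamma-distributed
#' fixation durations separated by a fixed saccade gap, and every fixation
#' location is sampled from a softmax over pixels with log-weights
#' `sum_f beta_f g_f(onset) intensity_f(x, y)` plus an optional centered
#' Gaussian term. With probability `anticipatory_rate` an extra fixation
#' with onset < 80 ms is injected before the first regular fixation.
#' Sampling is exact (no MCMC) and bit-reproducible per `trial_seed`.
#'
#' @param fmaps named list of [FeatureMap] objects (one per feature,
#'   intensities in `[0, 1]`, equal shapes).
#' @param cfg a [SimConfig].
#' @param trial_seed RNG seed for this trial.
#' @param participant_id,stimulus_id identifiers for the resulting record.
#' @return a [TrialRecord].
#' @export
simulateScanpath <- function(fmaps, cfg, trial_seed,
                             participant_id = "p01", stimulus_id = "s01") {
    stopifnot(is(cfg, "SimConfig"))
    dims <- lapply(fmaps, function(m) dim(m@intensity))
    if (length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
        stop("feature maps must share one shape")
    h <- dims[[1L]][1L]; w <- dims[[1L]][2L]
    geom <- cfg@geometry
    if (h != geom@height_px || w != geom@width_px)
        stop("feature-map shape must match the configured geometry")
    trial_ms <- geom@trial_ms
    nf <- length(cfg@feature_names)
    ivec <- vapply(cfg@feature_names, function(f) as.vector(fmaps[[f]]@intensity),
                   numeric(h * w))

    center_term <- 0
    if (!is.na(cfg@center_bias_sd_px)) {
        xs <- rep((0:(w - 1L)) - (w - 1) / 2, each = h)
        ys <- rep((0:(h - 1L)) - (h - 1) / 2, times = w)
        center_term <- -(xs^2 + ys^2) / (2 * cfg@center_bias_sd_px^2)
    }

    set.seed(as.integer(trial_seed))
    onset <- max(0, stats::rnorm(1L, cfg@first_latency_mean_ms,
                                 cfg@first_latency_sd_ms))
    xs_out <- ys_out <- on_out <- off_out <- numeric(0)
    while (onset < trial_ms) {
        dur <- max(1, stats::rgamma(1L, shape = cfg@duration_shape,
                                    scale = cfg@duration_scale_ms))
        offset <- min(onset + dur, trial_ms)
        g <- vapply(seq_len(nf), function(f)
            .temporalGain(onset, cfg@temporal_baseline,
                          cfg@temporal_amplitude[f], cfg@temporal_peak_ms[f],
                          cfg@temporal_width_ms[f]), numeric(1L))
        logw <- as.vector(ivec %*% (cfg@bias_weights * g)) + center_term
        pr <- exp(logw - max(logw))
        idx <- sample.int(h * w, 1L, prob = pr)
        row <- ((idx - 1L) %% h) + 1L
        col <- ((idx - 1L) %/% h) + 1L
        xs_out <- c(xs_out, col - 1L); ys_out <- c(ys_out, row - 1L)
        on_out <- c(on_out, onset); off_out <- c(off_out, offset)
        onset <- offset + cfg@saccade_gap_ms
    }

    if (stats::runif(1L) < cfg@anticipatory_rate) {
        u <- stats::runif(1L, 0, 80)
        cap <- if (length(on_out)) on_out[1L] - cfg@saccade_gap_ms else trial_ms
        dur <- min(max(1, stats::rgamma(1L, shape = cfg@duration_shape,
                                        scale = cfg@duration_scale_ms)),
                   cap - u)
        if (dur >= 5) {
            xs_out <- c(stats::runif(1L, 0, w - 1), xs_out)
            ys_out <- c(stats::runif(1L, 0, h - 1), ys_out)
            on_out <- c(u, on_out)
            off_out <- c(u + dur, off_out)
        }
    }
    newTrialRecord(participant_id, stimulus_id, xs_out, ys_out,
                   on_out, off_out)
}

#' Generate a full synthetic cohort
#'
#' Produces everything the analysis consumes: per-stimulus feature fields
#' shared across participants, one simulated trial per participant x
#' stimulus, the discretized maps, and a ground-truth sidecar recording
#' the generating parameters. Per-stimulus field seeds and per-trial
#' scanpath seeds are derived deterministically from `master_seed`, so
#' adding participants never reshuffles other participants' draws.
#'
#' @param cfg a [SimConfig].
#' @param n_levels number of intensity levels for the discretized maps.
#' @return a list with elements `trials` (list of [TrialRecord]),
#'   `feature_maps` (`feature_maps[[stimulus]][[feature]]`, [FeatureMap]),
#'   `dmaps` (same shape, [DiscretizedFeatureMap]), `truth`
#'   (`data.frame` of generating parameters), `config`.
#' @export
genCohort <- function(cfg, n_levels = 10) {
    stopifnot(is(cfg, "SimConfig"))
    geom <- cfg@geometry
    sids <- sprintf("s%03d", seq_len(cfg@n_stimuli))
    pids <- sprintf("p%02d", seq_len(cfg@n_participants))
    nf <- length(cfg@feature_names)

    feature_maps <- lapply(seq_along(sids), function(si) {
        maps <- lapply(seq_len(nf), function(fi)
            genFeatureField(geom@width_px, geom@height_px,
                            cfg@field_smoothness_px,
                            seed = cfg@master_seed + 1000L * si + fi,
                            stimulus_id = sids[si],
                            feature_name = cfg@feature_names[fi]))
        names(maps) <- cfg@feature_names
        maps
    })
    names(feature_maps) <- sids
    dmaps <- lapply(feature_maps, function(maps)
        lapply(maps, discretizeLevels, n_levels = n_levels))

    trials <- vector("list", cfg@n_participants * cfg@n_stimuli)
    k <- 0L
    for (pi in seq_along(pids)) {
        for (si in seq_along(sids)) {
            k <- k + 1L
            trials[[k]] <- simulateScanpath(
                feature_maps[[si]], cfg,
                trial_seed = cfg@master_seed + 100000L * pi + si,
                participant_id = pids[pi], stimulus_id = sids[si])
        }
    }

    truth <- data.frame(feature = cfg@feature_names,
                        beta = unname(cfg@bias_weights),
                        temporal_baseline = cfg@temporal_baseline,
                        temporal_amplitude = cfg@temporal_amplitude,
                        temporal_peak_ms = cfg@temporal_peak_ms,
                        temporal_width_ms = cfg@temporal_width_ms)
    list(trials = trials, feature_maps = feature_maps, dmaps = dmaps,
         truth = truth, config = cfg)
}

#' Write a synthetic cohort in the pipeline's file formats
#'
#' Writes `fixations.csv` (the schema [readFixations()] consumes), the
#' feature maps as TIFF grids with a manifest (see [writeFeatureMaps()]),
#' and the ground-truth sidecar `truth.csv` (never read by the analysis).
#'
#' @param cohort result of [genCohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeFixations(cohort$trials, file.path(dir, "fixations.csv"))
    writeFeatureMaps(unlist(cohort$feature_maps, use.names = FALSE),
                     file.path(dir, "feature_maps"))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
    invisible(dir)
}
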