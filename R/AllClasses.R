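#' @import methods
#' @importFrom stats rnorm rgamma runif aov t.test p.adjust pt sd setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Viewing geometry of the eye-tracking setup
#'
#' Describes the physical presentation geometry needed to convert between
#' pixels and degrees of visual angle: the viewing distance, the stimulus
#' size in pixels and in visual degrees, and the trial duration.
#'
#' Defaults correspond to a typical desktop free-viewing experiment:
#' an 800 x 600 px stimulus subtending about 20 x 15 degrees at 86 cm,
#' shown for 5000 ms.
#'
#' @slot distance_cm viewing distance in centimetres.
#' @slot width_px,height_px stimulus size in pixels.
#' @slot width_deg,height_deg stimulus size in degrees of visual angle.
#' @slot trial_ms stimulus presentation duration in milliseconds.
#'
#' @seealso [ViewingGeometry()], [pxPerDeg()]
#' @exportClass ViewingGeometry
setClass("ViewingGeometry",
    representation(
        distance_cm = "numeric",
        width_px    = "numeric",
        height_px   = "numeric",
        width_deg   = "numeric",
        height_deg  = "numeric",
        trial_ms    = "numeric"
    ),
    prototype(
        distance_cm = 86, width_px = 800, height_px = 600,
        width_deg = 20, height_deg = 15, trial_ms = 5000
    )
)

setValidity("ViewingGeometry", function(object) {
    vals <- c(
        distance_cm = object@distance_cm,
        width_px = object@width_px, height_px = object@height_px,
        width_deg = object@width_deg, height_deg = object@height_deg,
        trial_ms = object@trial_ms
    )
    if (any(!is.finite(vals)) || any(vals <= 0))
        return("all geometry fields must be finite and > 0")
    TRUE
})

#' One participant x stimulus scanpath
#'
#' An ordered sequence of fixation events for a single presentation of one
#' stimulus to one participant. Fixation coordinates are 0-based pixel
#' coordinates (x rightward, y downward, origin at the stimulus top-left
#' pixel center); times are milliseconds relative to stimulus onset.
#'
#' @slot participant_id participant identifier.
#' @slot stimulus_id stimulus identifier.
#' @slot fixations `data.frame` with columns `x_px`, `y_px`, `onset_ms`,
#'   `offset_ms`, `order` (1-based rank after filtering), sorted by onset.
#'
#' @seealso [loadTrials()], [filterAnticipatory()]
#' @exportClass TrialRecord
setClass("TrialRecord",
    representation(
        participant_id = "character",
        stimulus_id    = "character",
        fixations      = "data.frame"
    )
)

setValidity("TrialRecord", function(object) {
    fx <- object@fixations
    need <- c("x_px", "y_px", "onset_ms", "offset_ms", "order")
    if (!all(need %in% names(fx)))
        return(paste("fixations must have columns:", paste(need, collapse = ", ")))
    if (nrow(fx) == 0L) return(TRUE)
    if (any(fx$offset_ms <= fx$onset_ms))
        return("each fixation must have onset_ms < offset_ms")
    if (is.unsorted(fx$onset_ms))
        return("fixations must be sorted by onset_ms")
    if (any(fx$onset_ms[-1L] < fx$offset_ms[-nrow(fx)]))
        return("fixations must not overlap in time")
    if (!identical(as.integer(fx$order), seq_len(nrow(fx))))
        return("order must be consecutive integers starting at 1")
    TRUE
})

#' Per-stimulus feature-intensity map
#'
#' A per-pixel, non-negative intensity field for one visual feature of one
#' stimulus: a gradient back-projection of a convolutional layer
#' ([smoothGradMap()]), an Itti-Koch saliency map ([ittiKochSaliency()]),
#' or a synthetic field ([genFeatureField()]). Stored as a numeric matrix
#' with rows indexing y (downward) and columns indexing x (rightward), the
#' same shape as the stimulus.
#'
#' @slot stimulus_id stimulus identifier.
#' @slot feature_name feature label (e.g. `"layer1"`..`"layer5"`,
#'   `"ittikoch"`, or a synthetic label).
#' @slot intensity numeric matrix of finite, non-negative values.
#'
#' @seealso [rescaleIntensity()], [discretizeLevels()]
#' @exportClass FeatureMap
setClass("FeatureMap",
    representation(
        stimulus_id  = "character",
        feature_name = "character",
        intensity    = "matrix"
    )
)

setValidity("FeatureMap", function(object) {
    v <- object@intensity
    if (!is.numeric(v)) return("intensity must be numeric")
    if (any(!is.finite(v))) return("intensity must be finite")
    if (any(v < 0)) return("intensity must be >= 0")
    TRUE
})

#' Discretized feature-intensity map
#'
#' The ten-level (by default) equal-width discretization of a min-max
#' rescaled [FeatureMap]. Every pixel carries exactly one level in
#' `1..n_levels`.
#'
#' @slot stimulus_id,feature_name as in [FeatureMap].
#' @slot level integer matrix with values in `1..n_levels`.
#' @slot n_levels number of intensity levels (default 10).
#'
#' @seealso [discretizeLevels()], [occupancyCounts()]
#' @exportClass DiscretizedFeatureMap
setClass("DiscretizedFeatureMap",
    representation(
        stimulus_id  = "character",
        feature_name = "character",
        level        = "matrix",
        n_levels     = "integer"
    )
)

setValidity("DiscretizedFeatureMap", function(object) {
    lv <- object@level
    if (!is.integer(lv)) return("level must be an integer matrix")
    if (length(object@n_levels) != 1L || object@n_levels < 1L)
        return("n_levels must be a single positive integer")
    if (any(lv < 1L) || any(lv > object@n_levels))
        return("levels must lie in 1..n_levels")
    TRUE
})

#' Occupancy pixel counts behind the gaze-attraction ratio
#'
#' The four pixel counts that enter the gaze-attraction statistic: the
#' level-L feature pixels inside the fixation area, the total fixation-area
#' pixels, the level-L pixels in the whole image, and the total image
#' pixels.
#'
#' @slot n_feature_fa level pixels inside the fixation area.
#' @slot n_all_fa total pixels in the fixation area.
#' @slot n_feature_img level pixels in the entire image.
#' @slot n_all_img total pixels in the entire image.
#'
#' @seealso [occupancyCounts()], [gaValue()]
#' @exportClass OccupancyCounts
setClass("OccupancyCounts",
    representation(
        n_feature_fa  = "numeric",
        n_all_fa      = "numeric",
        n_feature_img = "numeric",
        n_all_img     = "numeric"
    )
)

setValidity("OccupancyCounts", function(object) {
    a <- object@n_feature_fa; b <- object@n_all_fa
    c_ <- object@n_feature_img; d <- object@n_all_img
    if (a < 0 || c_ < 0) return("counts must be >= 0")
    if (a > b) return("n_feature_fa must not exceed n_all_fa")
    if (c_ > d) return("n_feature_img must not exceed n_all_img")
    if (b > d) return("fixation area cannot exceed the image")
    TRUE
})

#' Gaze-attraction time course
#'
#' Per-millisecond (by default) gaze-attraction values over the trial for
#' one participant, feature and intensity level, averaged over that
#' participant's stimuli. `is_chance` marks courses built from
#' coordinate-randomized fixations.
#'
#' @slot feature_name,participant_id identifiers.
#' @slot level feature intensity level.
#' @slot grid_ms time step of the sampling grid in ms.
#' @slot values numeric vector of length `trial_ms / grid_ms`.
#' @slot is_chance logical flag.
#' @slot n_images number of stimuli contributing to the average (images in
#'   which the level does not occur are excluded).
#'
#' @seealso [meanTimeCourse()], [spatialGazeBias()], [temporalGazeBias()]
#' @exportClass GATimeCourse
setClass("GATimeCourse",
    representation(
        feature_name   = "character",
        level          = "integer",
        participant_id = "character",
        grid_ms        = "numeric",
        values         = "numeric",
        is_chance      = "logical",
        n_images       = "integer"
    ),
    prototype(is_chance = FALSE, grid_ms = 1, n_images = 0L)
)

setValidity("GATimeCourse", function(object) {
    if (any(!is.finite(object@values))) return("values must be finite")
    if (any(object@values < 0)) return("values must be >= 0")
    if (length(object@grid_ms) != 1L || object@grid_ms <= 0)
        return("grid_ms must be a single positive number")
    TRUE
})

#' ANOVA result with Bonferroni pairwise comparisons
#'
#' Container for the inferential layer: per-effect F statistics and
#' p-values, plus Bonferroni-corrected pairwise comparisons between
#' feature labels.
#'
#' @slot factors factor labels entering the model.
#' @slot F named numeric vector of F statistics per effect.
#' @slot p named numeric vector of p-values per effect.
#' @slot pairwise `data.frame` with columns `pair`, `t`, `p_raw`,
#'   `p_corrected`, `significant`.
#' @slot method description of the ANOVA variant used.
#'
#' @seealso [twoWayAnovaPairwise()], [firstFixationAnova()]
#' @exportClass AnovaResult
setClass("AnovaResult",
    representation(
        factors  = "character",
        F        = "numeric",
        p        = "numeric",
        pairwise = "data.frame",
        method   = "character"
    )
)

setValidity("AnovaResult", function(object) {
    if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
        return("p-values must lie in [0, 1]")
    TRUE
})

#' Configuration of the synthetic cohort generator
#'
#' Parameters of the simulated free-viewing experiment: cohort and stimulus
#' counts, stimulus geometry, the per-feature spatial bias gains, the
#' time-varying gain profile, fixation duration and latency models, the
#' anticipatory-event rate and optional center bias. See
#' [simConfig()] for defaults and units.
#'
#' @slot n_participants,n_stimuli cohort dimensions.
#' @slot geometry a [ViewingGeometry] describing the simulated display.
#' @slot feature_names labels of the simulated features.
#' @slot bias_weights named per-feature spatial gain (beta >= 0).
#' @slot temporal_baseline baseline b of the time-varying gain.
#' @slot temporal_amplitude per-feature transient amplitude A.
#' @slot temporal_peak_ms per-feature transient peak time (ms).
#' @slot temporal_width_ms per-feature transient width s (ms).
#' @slot duration_shape,duration_scale_ms gamma fixation-duration model.
#' @slot first_latency_mean_ms,first_latency_sd_ms normal first-fixation
#'   latency model.
#' @slot anticipatory_rate probability of injecting an anticipatory
#'   fixation (< 80 ms onset) into a trial.
#' @slot center_bias_sd_px Gaussian center-bias width in px (`NA` = none).
#' @slot saccade_gap_ms fixed inter-fixation gap approximating saccade
#'   flight time.
#' @slot field_smoothness_px blur radius of the synthetic feature fields.
#' @slot master_seed master RNG seed for the whole cohort.
#'
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        n_participants        = "integer",
        n_stimuli             = "integer",
        geometry              = "ViewingGeometry",
        feature_names         = "character",
        bias_weights          = "numeric",
        temporal_baseline     = "numeric",
        temporal_amplitude    = "numeric",
        temporal_peak_ms      = "numeric",
        temporal_width_ms     = "numeric",
        duration_shape        = "numeric",
        duration_scale_ms     = "numeric",
        first_latency_mean_ms = "numeric",
        first_latency_sd_ms   = "numeric",
        anticipatory_rate     = "numeric",
        center_bias_sd_px     = "numeric",
        saccade_gap_ms        = "numeric",
        field_smoothness_px   = "numeric",
        master_seed           = "integer"
    )
)

setValidity("SimConfig", function(object) {
    if (object@n_participants < 1L || object@n_stimuli < 1L)
        return("n_participants and n_stimuli must be >= 1")
    if (any(object@bias_weights < 0)) return("bias_weights must be >= 0")
    if (object@anticipatory_rate < 0 || object@anticipatory_rate > 1)
        return("anticipatory_rate must be a probability")
    if (object@duration_shape <= 0 || object@duration_scale_ms <= 0)
        return("gamma duration parameters must be > 0")
    nf <- length(object@feature_names)
    if (length(object@bias_weights) != nf ||
        length(object@temporal_amplitude) != nf ||
        length(object@temporal_peak_ms) != nf ||
        length(object@temporal_width_ms) != nf)
        return("per-feature parameters must match feature_names in length")
    TRUE
})

#' Pluggable convolutional feature extractor
#'
#' The contract a feature extractor must satisfy to drive
#' [smoothGradMap()]: it names its convolutional layers, exposes a forward
#' pass returning per-layer activations, and exposes the gradient of the
#' summed layer activation with respect to the input pixels.
#'
#' @slot name extractor label.
#' @slot layers names of the convolutional layers available.
#' @slot native_size integer `c(height, width)` the extractor operates at,
#'   or `integer(0)` when it accepts any input size.
#' @slot forward `function(image)` returning a named list of activation
#'   arrays, one per layer.
#' @slot gradientSum `function(image, layer)` returning the gradient of
#'   `sum(activations(layer))` with respect to the input, an array with the
#'   image's dimensions.
#'
#' @seealso [tinyConvnetFixture()], [linearExtractor()]
#' @exportClass FeatureExtractor
setClass("FeatureExtractor",
    representation(
        name        = "character",
        layers      = "character",
        native_size = "integer",
        forward     = "function",
        gradientSum = "function"
    )
)
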