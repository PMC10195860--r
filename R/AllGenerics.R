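#' @rdname TrialRecord-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("fixations", function(x) standardGeneric("fixations"))

#' @rdname TrialRecord-class
#' @export
setMethod("fixations", "TrialRecord", function(x) x@fixations)

#' @rdname TrialRecord-class
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' @rdname TrialRecord-class
#' @export
setMethod("participantId", "TrialRecord", function(x) x@participant_id)

#' @rdname TrialRecord-class
#' @export
setGeneric("stimulusId", function(x) standardGeneric("stimulusId"))

#' @rdname TrialRecord-class
#' @export
setMethod("stimulusId", "TrialRecord", function(x) x@stimulus_id)

#' @rdname FeatureMap-class
#' @export
setGeneric("featureName", function(x) standardGeneric("featureName"))

#' @rdname FeatureMap-class
#' @export
setMethod("featureName", "FeatureMap", function(x) x@feature_name)

#' @rdname FeatureMap-class
#' @export
setMethod("featureName", "DiscretizedFeatureMap", function(x) x@feature_name)

#' @rdname FeatureMap-class
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname FeatureMap-class
#' @export
setMethod("intensity", "FeatureMap", function(x) x@intensity)

#' @rdname DiscretizedFeatureMap-class
#' @param x a [DiscretizedFeatureMap].
#' @export
setGeneric("levelGrid", function(x) standardGeneric("levelGrid"))

#' @rdname DiscretizedFeatureMap-class
#' @export
setMethod("levelGrid", "DiscretizedFeatureMap", function(x) x@level)

#' @rdname GATimeCourse-class
#' @param x a [GATimeCourse].
#' @export
setGeneric("gaSeries", function(x) standardGeneric("gaSeries"))

#' @rdname GATimeCourse-class
#' @export
setMethod("gaSeries", "GATimeCourse", function(x) x@values)

#' @rdname GATimeCourse-class
#' @export
setGeneric("isChance", function(x) standardGeneric("isChance"))

#' @rdname GATimeCourse-class
#' @export
setMethod("isChance", "GATimeCourse", function(x) x@is_chance)

setMethod("show", "ViewingGeometry", function(object) {
    cat(sprintf(
        "ViewingGeometry: %g x %g px, %g x %g deg at %g cm (%.2f px/deg), trial %g ms\n",
        object@width_px, object@height_px, object@width_deg, object@height_deg,
        object@distance_cm, mean(c(object@width_px / object@width_deg,
                                   object@height_px / object@height_deg)),
        object@trial_ms))
})

setMethod("show", "TrialRecord", function(object) {
    fx <- object@fixations
    cat(sprintf("TrialRecord: participant '%s', stimulus '%s', %d fixation(s)\n",
                object@participant_id, object@stimulus_id, nrow(fx)))
    if (nrow(fx) > 0L)
        print(utils::head(fx, 5L))
    if (nrow(fx) > 5L) cat(sprintf("  ... and %d more\n", nrow(fx) - 5L))
})

setMethod("show", "FeatureMap", function(object) {
    v <- object@intensity
    cat(sprintf(
        "FeatureMap '%s' for stimulus '%s': %d x %d px, range [%.4g, %.4g]\n",
        object@feature_name, object@stimulus_id, ncol(v), nrow(v),
        min(v), max(v)))
})

setMethod("show", "DiscretizedFeatureMap", function(object) {
    cat(sprintf(
        "DiscretizedFeatureMap '%s' for stimulus '%s': %d x %d px, %d levels\n",
        object@feature_name, object@stimulus_id, ncol(object@level),
        nrow(object@level), object@n_levels))
})

setMethod("show", "GATimeCourse", function(object) {
    cat(sprintf(
        "GATimeCourse%s: participant '%s', feature '%s', level %d, %d samples @ %g ms (mean %.4g)\n",
        if (object@is_chance) " [chance]" else "",
        object@participant_id, object@feature_name, object@level,
        length(object@values), object@grid_ms, mean(object@values)))
})

setMethod("show", "AnovaResult", function(object) {
    cat("AnovaResult (", object@method, ")\n", sep = "")
    eff <- data.frame(effect = names(object@F), F = object@F, p = object@p,
                      row.names = NULL)
    print(eff)
    if (nrow(object@pairwise) > 0L) {
        cat("Bonferroni pairwise comparisons:\n")
        print(object@pairwise)
    }
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d participants x %d stimuli, features: %s\n",
        object@n_participants, object@n_stimuli,
        paste(object@feature_names, collapse = ", ")))
    cat(sprintf("  bias weights: %s; peak times (ms): %s; master seed %d\n",
        paste(format(object@bias_weights), collapse = ", "),
        paste(format(object@temporal_peak_ms), collapse = ", "),
        object@master_seed))
})

setMethod("show", "FeatureExtractor", function(object) {
    cat(sprintf("FeatureExtractor '%s': layers %s%s\n",
        object@name, paste(object@layers, collapse = ", "),
        if (length(object@native_size))
            sprintf(" (native %d x %d)", object@native_size[2L],
                    object@native_size[1L]) else ""))
})
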