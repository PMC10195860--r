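#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file with blocks `geometry` (required:
#' `width_px`, `height_px`, `width_deg`, `height_deg`, `distance_cm`,
#' `trial_ms`), `analysis` (optional: `n_levels`, `radius_deg`,
#' `anticipatory_threshold_ms`, `grid_ms`, `n_randomizations`), `simulate`
#' (optional overrides of [simConfig()] fields for synthetic runs),
#' `paths` (for data runs: `fixations`, `stimuli`, `feature_maps`),
#' `stats` (`alpha`), and a top-level `master_seed`.
#'
#' @param path YAML file path, or a named list already parsed.
#' @return validated configuration list with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (is.character(path)) yaml::read_yaml(path) else path
    if (is.null(cfg$geometry))
        stop("config missing required block: geometry")
    need <- c("width_px", "height_px", "width_deg", "height_deg")
    for (f in need)
        if (is.null(cfg$geometry[[f]]))
            stop("config geometry block missing field: ", f)
    g <- cfg$geometry
    cfg$geometry_obj <- ViewingGeometry(
        distance_cm = g$distance_cm %||% 86,
        width_px = g$width_px, height_px = g$height_px,
        width_deg = g$width_deg, height_deg = g$height_deg,
        trial_ms = g$trial_ms %||% 5000)
    a <- cfg$analysis %||% list()
    cfg$analysis <- list(
        n_levels = a$n_levels %||% 10L,
        radius_deg = a$radius_deg %||% 1.0,
        anticipatory_threshold_ms = a$anticipatory_threshold_ms %||% 80,
        grid_ms = a$grid_ms %||% 1,
        n_randomizations = a$n_randomizations %||% 100L)
    cfg$stats <- list(alpha = (cfg$stats$alpha %||% 0.05))
    cfg$master_seed <- as.integer(cfg$master_seed %||% 1L)
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full gaze-bias pipeline
#'
#' Orchestrates one reproducible end-to-end run: obtain trials and feature
#' maps (simulating a synthetic cohort, or loading a fixation CSV plus
#' stimuli/feature maps), filter anticipatory fixations, compute per
#' participant the gaze-attraction time courses, spatial and temporal
#' gaze biases with randomization chance levels, fixation-order and
#' latency summaries, and the ANOVA layer; write all result tables as CSV
#' plus a run log, and optionally summary plots (PDF). Identical config
#' and seed give identical numeric outputs.
#'
#' @param config a config list from [readPipelineConfig()], or a YAML
#'   path.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config's `master_seed`.
#' @param plots write summary PDF plots (default `FALSE`; all acceptance
#'   surfaces are the CSV numbers).
#' @return invisibly, a list with `bias`, `latency`, `by_order`,
#'   `anova_spatial`, `anova_temporal`, `first_fixation`,
#'   `time_courses`.
#' @export
runPipeline <- function(config, out_dir, seed = NULL, plots = FALSE) {
    cfg <- if (is.list(config) && !is.null(config$geometry_obj)) config
           else readPipelineConfig(config)
    if (!is.null(seed)) cfg$master_seed <- as.integer(seed)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    geom <- cfg$geometry_obj
    an <- cfg$analysis
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }

    ## --- data stage -----------------------------------------------------
    data <- stage("input", {
        if (!is.null(cfg$simulate) || is.null(cfg$paths)) {
            sim <- cfg$simulate %||% list()
            sc <- simConfig(
                n_participants = sim$n_participants %||% 20,
                n_stimuli = sim$n_stimuli %||% 30,
                geometry = geom,
                feature_names = unlist(sim$feature_names) %||%
                    c("feature1", "feature2", "feature3"),
                bias_weights = unlist(sim$bias_weights) %||%
                    c(feature1 = 1, feature2 = 2, feature3 = 4),
                temporal_amplitude = unlist(sim$temporal_amplitude) %||%
                    c(0, 0, 1.5),
                temporal_peak_ms = unlist(sim$temporal_peak_ms) %||% 500,
                anticipatory_rate = sim$anticipatory_rate %||% 0.05,
                center_bias_sd_px = sim$center_bias_sd_px %||% NA_real_,
                master_seed = cfg$master_seed)
            cohort <- genCohort(sc, n_levels = an$n_levels)
            list(trials = cohort$trials, dmaps = cohort$dmaps,
                 features = sc@feature_names)
        } else {
            trials <- readFixations(cfg$paths$fixations, geom)
            maps <- readFeatureMaps(cfg$paths$feature_maps)
            feats <- unique(vapply(maps, featureName, character(1L)))
            dmaps <- list()
            for (m in maps) {
                sid <- m@stimulus_id
                if (is.null(dmaps[[sid]])) dmaps[[sid]] <- list()
                dmaps[[sid]][[m@feature_name]] <-
                    discretizeLevels(rescaleIntensity(m), an$n_levels)
            }
            list(trials = trials, dmaps = dmaps, features = feats)
        }
    })

    trials <- lapply(data$trials, filterAnticipatory,
                     threshold_ms = an$anticipatory_threshold_ms)
    pids <- unique(vapply(trials, participantId, character(1L)))
    features <- data$features
    levels <- seq_len(an$n_levels)

    ## --- per-participant analysis --------------------------------------
    bias_rows <- list(); lat_rows <- list(); ord_rows <- list()
    tc_sum <- list()
    res <- stage("gaze_attraction", {
        for (pi in seq_along(pids)) {
            ptr <- Filter(function(tr) tr@participant_id == pids[pi], trials)
            lat <- latencyHistogram(ptr, trial_ms = geom@trial_ms)
            lat$participant <- pids[pi]
            lat_rows[[length(lat_rows) + 1L]] <- lat
            for (f in features) {
                fdm <- lapply(data$dmaps, `[[`, f)
                tcs <- participantTimeCourses(ptr, fdm, geom,
                    radius_deg = an$radius_deg, grid_ms = an$grid_ms)
                ch <- chanceTimeCourses(ptr, fdm, geom,
                    n_randomizations = an$n_randomizations,
                    seed = cfg$master_seed + 7919L * pi,
                    radius_deg = an$radius_deg, grid_ms = an$grid_ms)
                bias_rows[[length(bias_rows) + 1L]] <- biasSummary(tcs, ch)
                for (j in seq_along(tcs)) {
                    key <- paste(f, j, sep = "_")
                    v <- tcs[[j]]@values
                    tc_sum[[key]] <- if (is.null(tc_sum[[key]])) v
                                     else tc_sum[[key]] + v
                }
                for (lv in c(an$n_levels)) {
                    bo <- gaByOrder(ptr, fdm, lv, geom,
                                    radius_deg = an$radius_deg)
                    bo$participant <- pids[pi]; bo$feature <- f; bo$level <- lv
                    ord_rows[[length(ord_rows) + 1L]] <- bo
                }
            }
        }
        list(bias = do.call(rbind, bias_rows),
             latency = do.call(rbind, lat_rows),
             by_order = do.call(rbind, ord_rows))
    })

    tc_tab <- stage("time_courses", {
        t_ms <- seq(0, geom@trial_ms - an$grid_ms, by = an$grid_ms)
        rows <- lapply(names(tc_sum), function(key) {
            parts <- strsplit(key, "_(?=[0-9]+$)", perl = TRUE)[[1L]]
            data.frame(feature = parts[1L], level = as.integer(parts[2L]),
                       t_ms = t_ms, mean_ga = tc_sum[[key]] / length(pids))
        })
        do.call(rbind, rows)
    })

    ## --- inference ------------------------------------------------------
    inference <- stage("stats", {
        alpha <- cfg$stats$alpha
        two_sp <- two_tp <- ff <- NULL
        if (length(features) > 1L || an$n_levels > 1L) {
            two_sp <- twoWayAnovaPairwise(res$bias, "spatial_bias",
                                          alpha = alpha)
            two_tp <- twoWayAnovaPairwise(res$bias, "temporal_bias",
                                          alpha = alpha)
        }
        if (length(features) > 1L) {
            ord1 <- res$by_order[res$by_order$order == 1L, ]
            ff <- firstFixationAnova(data.frame(
                participant = ord1$participant, feature = ord1$feature,
                value = ord1$mean_ga), alpha = alpha)
        }
        list(spatial = two_sp, temporal = two_tp, first = ff)
    })

    ## --- outputs --------------------------------------------------------
    stage("report", {
        utils::write.csv(res$bias, file.path(out_dir, "bias_summary.csv"),
                         row.names = FALSE)
        utils::write.csv(res$latency,
                         file.path(out_dir, "latency_histograms.csv"),
                         row.names = FALSE)
        utils::write.csv(res$by_order, file.path(out_dir, "ga_by_order.csv"),
                         row.names = FALSE)
        utils::write.csv(tc_tab, file.path(out_dir, "time_courses.csv"),
                         row.names = FALSE)
        rpt <- file(file.path(out_dir, "report.txt"), "w")
        on.exit(close(rpt))
        writeLines(c(
            sprintf("GazeBias pipeline run, package %s",
                    as.character(utils::packageVersion("GazeBias"))),
            sprintf("R %s", R.version.string),
            sprintf("master_seed: %d", cfg$master_seed),
            sprintf("participants: %d, features: %s, levels: %d",
                    length(pids), paste(features, collapse = ", "),
                    an$n_levels),
            sprintf("n_randomizations: %d, radius_deg: %g, grid_ms: %g",
                    an$n_randomizations, an$radius_deg, an$grid_ms), ""),
            rpt)
        for (nm in names(inference)) {
            if (is.null(inference[[nm]])) next
            writeLines(sprintf("== %s ==", nm), rpt)
            writeLines(utils::capture.output(show(inference[[nm]])), rpt)
        }
    })
    if (plots) stage("plots", .writePlots(res, tc_tab, out_dir, an))

    invisible(list(bias = res$bias, latency = res$latency,
                   by_order = res$by_order,
                   anova_spatial = inference$spatial,
                   anova_temporal = inference$temporal,
                   first_fixation = inference$first,
                   time_courses = tc_tab))
}

#' Participant-level bias table for a whole cohort
#'
#' Convenience driver over [participantTimeCourses()] and
#' [biasSummary()]: filters anticipatory fixations, computes the
#' gaze-attraction time courses for every participant and feature, and
#' stacks the per-participant bias summaries into one table suitable for
#' [twoWayAnovaPairwise()].
#'
#' @param cohort a [genCohort()] result, or any list with elements
#'   `trials` (list of [TrialRecord]) and `dmaps`
#'   (`dmaps[[stimulus]][[feature]]`, [DiscretizedFeatureMap]).
#' @param geometry a [ViewingGeometry]; defaults to the cohort's
#'   configured geometry.
#' @param radius_deg,grid_ms as in [trialTimeCourse()].
#' @param anticipatory_threshold_ms exclusion threshold (default 80 ms).
#' @return `data.frame` of [biasSummary()] rows over all participants and
#'   features (chance columns `NA`; compute them with
#'   [chanceTimeCourses()] where needed).
#' @export
cohortBiasTable <- function(cohort, geometry = NULL, radius_deg = 1.0,
                            grid_ms = 1, anticipatory_threshold_ms = 80) {
    if (is.null(geometry)) geometry <- cohort$config@geometry
    trials <- lapply(cohort$trials, filterAnticipatory,
                     threshold_ms = anticipatory_threshold_ms)
    pids <- unique(vapply(trials, participantId, character(1L)))
    features <- names(cohort$dmaps[[1L]])
    rows <- list()
    for (p in pids) {
        ptr <- Filter(function(tr) tr@participant_id == p, trials)
        for (f in features) {
            tcs <- participantTimeCourses(ptr, lapply(cohort$dmaps, `[[`, f),
                                          geometry, radius_deg = radius_deg,
                                          grid_ms = grid_ms)
            rows[[paste(p, f)]] <- biasSummary(tcs)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

## advisory summary plots: GA time courses per level, bias vs level,
## order profiles
.writePlots <- function(res, tc_tab, out_dir, an) {
    grDevices::pdf(file.path(out_dir, "summary_plots.pdf"), width = 9,
                   height = 6)
    on.exit(grDevices::dev.off())
    feats <- unique(tc_tab$feature)
    show_levels <- unique(c(1L, ceiling(an$n_levels / 2), an$n_levels))
    for (lv in show_levels) {
        sub <- tc_tab[tc_tab$level == lv, ]
        if (nrow(sub) == 0L) next
        graphics::plot(NULL, xlim = range(sub$t_ms), ylim = range(sub$mean_ga),
             xlab = "time (ms)", ylab = "gaze attraction",
             main = sprintf("GA time course, level %d", lv))
        for (i in seq_along(feats)) {
            s <- sub[sub$feature == feats[i], ]
            graphics::lines(s$t_ms, s$mean_ga, col = i)
        }
        graphics::legend("topright", legend = feats, col = seq_along(feats),
                         lty = 1, bty = "n")
        graphics::abline(h = 1, lty = 3)
    }
    agg <- stats::aggregate(cbind(spatial_bias, temporal_bias) ~ feature + level,
                            data = res$bias, FUN = mean)
    for (what in c("spatial_bias", "temporal_bias")) {
        graphics::plot(NULL, xlim = range(agg$level), ylim = range(agg[[what]]),
             xlab = "feature intensity level", ylab = what,
             main = sprintf("%s by level", what))
        for (i in seq_along(feats)) {
            s <- agg[agg$feature == feats[i], ]
            graphics::lines(s$level, s[[what]], col = i, type = "b")
        }
        graphics::legend("topleft", legend = feats, col = seq_along(feats),
                         lty = 1, bty = "n")
    }
    aggo <- stats::aggregate(mean_ga ~ feature + order, data = res$by_order,
                             FUN = mean, na.rm = TRUE)
    graphics::plot(NULL, xlim = range(aggo$order), ylim = range(aggo$mean_ga),
         xlab = "fixation order", ylab = "gaze attraction",
         main = "GA by fixation order (top level)")
    for (i in seq_along(feats)) {
        s <- aggo[aggo$feature == feats[i], ]
        graphics::lines(s$order, s$mean_ga, col = i, type = "b")
    }
    graphics::legend("topright", legend = feats, col = seq_along(feats),
                     lty = 1, bty = "n")
    invisible(NULL)
}
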