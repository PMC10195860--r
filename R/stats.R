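## shared machinery for the repeated-measures / fixed-effects ANOVA layer

.checkBalanced <- function(df, factors) {
    tab <- table(df[factors])
    if (any(tab != 1L)) {
        bad <- which(tab != 1L, arr.ind = TRUE)
        lab <- apply(bad, 1L, function(i)
            paste(mapply(function(f, k) dimnames(tab)[[f]][k],
                         seq_along(factors), i), collapse = " x "))
        stop("unbalanced design; cells not observed exactly once: ",
             paste(unique(lab), collapse = ", "))
    }
    invisible(TRUE)
}

.extractAov <- function(fit, effects) {
    s <- summary(fit)
    rows <- list()
    collect <- function(tb) {
        tb <- as.data.frame(tb)
        nm <- trimws(rownames(tb))
        for (i in seq_along(nm))
            if (nm[i] %in% effects)
                rows[[nm[i]]] <<- c(F = tb[i, "F value"], p = tb[i, "Pr(>F)"])
    }
    if (inherits(fit, "aovlist")) {
        for (stratum in s) collect(stratum[[1L]])
    } else {
        collect(s[[1L]])
    }
    Fv <- vapply(effects, function(e)
        if (!is.null(rows[[e]])) rows[[e]]["F"] else NA_real_, numeric(1L))
    pv <- vapply(effects, function(e)
        if (!is.null(rows[[e]])) rows[[e]]["p"] else NA_real_, numeric(1L))
    names(Fv) <- names(pv) <- effects
    list(F = Fv, p = pv)
}

.pairwiseFeatures <- function(df, response, alpha) {
    feats <- levels(df$feature)
    prs <- utils::combn(feats, 2L, simplify = FALSE)
    ## participant x feature means (averaging over levels), paired t-tests
    agg <- stats::aggregate(df[[response]],
        by = list(participant = df$participant, feature = df$feature), FUN = mean)
    raw <- t_ <- numeric(length(prs))
    for (i in seq_along(prs)) {
        a <- agg$x[agg$feature == prs[[i]][1L]][order(agg$participant[agg$feature == prs[[i]][1L]])]
        b <- agg$x[agg$feature == prs[[i]][2L]][order(agg$participant[agg$feature == prs[[i]][2L]])]
        d <- a - b
        if (stats::sd(d) == 0) {
            t_[i] <- 0; raw[i] <- 1
        } else {
            tt <- stats::t.test(a, b, paired = TRUE)
            t_[i] <- unname(tt$statistic); raw[i] <- tt$p.value
        }
    }
    corr <- pmin(1, raw * length(prs))
    data.frame(pair = vapply(prs, paste, character(1L), collapse = " vs "),
               t = t_, p_raw = raw, p_corrected = corr,
               significant = corr < alpha)
}

#' Two-way ANOVA of gaze-bias indices with Bonferroni pairwise comparisons
#'
#' Factorial analysis of a participant-level bias table with factors
#' visual feature and intensity level. The default treats both factors as
#' within-participant (repeated measures, one observation per participant
#' and cell, participant error strata); `type = "fixed"` fits a plain
#' fixed-effects two-way ANOVA for comparison. Pairwise feature
#' comparisons are paired t-tests on participant-wise feature means with
#' Bonferroni correction (`p_corrected = min(1, p_raw * n_pairs)`).
#'
#' @param table `data.frame` with columns `participant`, `feature`,
#'   `level` and the response column (e.g. from [biasSummary()] rows bound
#'   over participants and features).
#' @param response name of the response column: `"spatial_bias"` or
#'   `"temporal_bias"` (any numeric column is accepted).
#' @param type `"repeated"` (default) or `"fixed"`.
#' @param alpha significance threshold for the corrected comparisons.
#' @return an [AnovaResult] with effects `feature`, `level`,
#'   `feature:level` (those estimable given the design).
#' @export
twoWayAnovaPairwise <- function(table, response = "spatial_bias",
                                type = c("repeated", "fixed"), alpha = 0.05) {
    type <- match.arg(type)
    need <- c("participant", "feature", "level", response)
    miss <- setdiff(need, names(table))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    df <- data.frame(participant = factor(table$participant),
                     feature = factor(table$feature),
                     level = factor(table$level),
                     y = table[[response]])
    .checkBalanced(df, c("participant", "feature", "level"))
    terms <- c(if (nlevels(df$feature) > 1L) "feature",
               if (nlevels(df$level) > 1L) "level")
    if (length(terms) == 0L) stop("need at least two features or two levels")
    effects <- c(terms, if (length(terms) == 2L) "feature:level")

    if (stats::sd(df$y) == 0) {
        Fv <- setNames(rep(0, length(effects)), effects)
        pv <- setNames(rep(1, length(effects)), effects)
    } else {
        rhs <- paste(terms, collapse = " * ")
        fml <- if (type == "repeated")
            stats::as.formula(sprintf("y ~ %s + Error(participant/(%s))",
                                      rhs, rhs))
        else stats::as.formula(paste("y ~", rhs))
        fit <- stats::aov(fml, data = df)
        ext <- .extractAov(fit, effects)
        Fv <- ext$F; pv <- ext$p
    }
    pw <- if (nlevels(df$feature) > 1L) .pairwiseFeatures(df, "y", alpha)
          else data.frame()
    new("AnovaResult", factors = terms, F = Fv, p = pmin(pmax(pv, 0), 1),
        pairwise = pw,
        method = paste0("two-way ", type,
                        if (type == "repeated") "-measures", " ANOVA"))
}

#' One-way ANOVA of first-fixation gaze attraction across features
#'
#' Compares the gaze attraction at a given fixation order (typically the
#' first) between visual features, one value per participant and feature,
#' with a within-participant one-way ANOVA and Bonferroni-corrected paired
#' pairwise comparisons.
#'
#' @param table `data.frame` with columns `participant`, `feature`,
#'   `value` (e.g. order-1 rows of [gaByOrder()] output bound over
#'   participants and features).
#' @param alpha significance threshold.
#' @return an [AnovaResult] with the `feature` effect.
#' @export
firstFixationAnova <- function(table, alpha = 0.05) {
    need <- c("participant", "feature", "value")
    miss <- setdiff(need, names(table))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    df <- data.frame(participant = factor(table$participant),
                     feature = factor(table$feature), y = table$value)
    if (nlevels(df$feature) < 2L) stop("need at least two features")
    .checkBalanced(df, c("participant", "feature"))
    if (stats::sd(df$y) == 0) {
        Fv <- c(feature = 0); pv <- c(feature = 1)
    } else {
        fit <- stats::aov(y ~ feature + Error(participant/feature), data = df)
        ext <- .extractAov(fit, "feature")
        Fv <- ext$F; pv <- ext$p
    }
    new("AnovaResult", factors = "feature", F = Fv,
        p = pmin(pmax(pv, 0), 1),
        pairwise = .pairwiseFeatures(df, "y", alpha),
        method = "one-way repeated-measures ANOVA")
}

#' Steady-state-referenced transient peak of a gaze-attraction time course
#'
#' Detects an early transient in a group of per-participant time courses:
#' at every time point before the steady-state window, the participants'
#' values are compared with their own steady-state means (the last
#' `steady_window_ms` of the trial) by a paired, one-sided t-test; within
#' the contiguous region(s) where `p < alpha`, the time of the group-mean
#' maximum is returned. No correction over time points is applied
#' (deliberately liberal, matching common practice for peak localization).
#'
#' @param tc_group list of [GATimeCourse] objects (one per participant,
#'   same grid) or a numeric matrix `participants x time`.
#' @param steady_window_ms length of the steady-state reference window at
#'   the end of the trial (default 1000 ms).
#' @param alpha per-time-point significance threshold.
#' @param grid_ms grid step; taken from the time courses when omitted.
#' @return the peak time in ms, or `NA` when no supra-threshold region
#'   exists; the supra-threshold regions are attached as attribute
#'   `regions` (`data.frame` with `start_ms`, `end_ms`).
#' @export
transientPeak <- function(tc_group, steady_window_ms = 1000, alpha = 0.05,
                          grid_ms = NULL) {
    if (is.list(tc_group)) {
        stopifnot(all(vapply(tc_group, is, logical(1L), "GATimeCourse")))
        if (is.null(grid_ms)) grid_ms <- tc_group[[1L]]@grid_ms
        m <- do.call(rbind, lapply(tc_group, function(tc) tc@values))
    } else {
        m <- as.matrix(tc_group)
        if (is.null(grid_ms)) grid_ms <- 1
    }
    np <- nrow(m); nt <- ncol(m)
    if (np < 2L) stop("need >= 2 participants")
    n_steady <- as.integer(round(steady_window_ms / grid_ms))
    if (n_steady >= nt) stop("steady-state window must be shorter than the trial")
    steady_idx <- (nt - n_steady + 1L):nt
    search_idx <- seq_len(nt - n_steady)
    steady_mean <- rowMeans(m[, steady_idx, drop = FALSE])
    d <- m[, search_idx, drop = FALSE] - steady_mean
    md <- colMeans(d)
    sdd <- apply(d, 2L, stats::sd)
    p <- ifelse(sdd == 0, ifelse(md > 0, 0, 1),
                stats::pt(md / (sdd / sqrt(np)), df = np - 1L,
                          lower.tail = FALSE))
    sig <- p < alpha
    if (!any(sig)) {
        out <- NA_real_
        attr(out, "regions") <- data.frame(start_ms = numeric(0),
                                           end_ms = numeric(0))
        return(out)
    }
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    reg <- data.frame(start_ms = (starts[runs$values] - 1L) * grid_ms,
                      end_ms = (ends[runs$values] - 1L) * grid_ms)
    gm <- colMeans(m[, search_idx, drop = FALSE])
    cand <- which(sig)
    peak_idx <- cand[which.max(gm[cand])]
    out <- (peak_idx - 1L) * grid_ms
    attr(out, "regions") <- reg
    out
}
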