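#' Build trial records from a tabular fixation listing
#'
#' Groups fixation rows into one [TrialRecord] per participant x stimulus,
#' sorts fixations by onset, and applies the package's coordinate
#' conventions: coordinates are 0-based pixel positions in the half-open
#' window `[0, width) x [0, height)`; rows outside the stimulus are dropped
#' (with a message reporting the count) rather than clipped, because gaze
#' that left the stimulus cannot be mapped to its features. Rows with
#' `offset_ms <= onset_ms` are rejected with a warning. Fixations
#' straddling the end of the trial are truncated at `trial_ms`.
#'
#' @param table `data.frame` with columns `participant`, `stimulus`,
#'   `x_px`, `y_px`, `onset_ms`, `offset_ms`.
#' @param geometry a [ViewingGeometry].
#' @return a list of [TrialRecord] objects.
#' @examples
#' tab <- data.frame(participant = "p1", stimulus = "s1",
#'                   x_px = c(100, 200, 300), y_px = c(50, 60, 70),
#'                   onset_ms = c(100, 400, 900),
#'                   offset_ms = c(350, 800, 1200))
#' trials <- loadTrials(tab, ViewingGeometry())
#' fixations(trials[[1]])
#' @seealso [readFixations()], [filterAnticipatory()]
#' @export
loadTrials <- function(table, geometry) {
    stopifnot(is(geometry, "ViewingGeometry"))
    need <- c("participant", "stimulus", "x_px", "y_px", "onset_ms", "offset_ms")
    miss <- setdiff(need, names(table))
    if (length(miss))
        stop("fixation table is missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(table) == 0L) return(list())

    bad_time <- table$offset_ms <= table$onset_ms
    if (any(bad_time)) {
        warning(sprintf("rejected %d row(s) with offset_ms <= onset_ms",
                        sum(bad_time)))
        table <- table[!bad_time, , drop = FALSE]
    }
    oob <- table$x_px < 0 | table$x_px >= geometry@width_px |
           table$y_px < 0 | table$y_px >= geometry@height_px
    if (any(oob)) {
        message(sprintf("dropped %d out-of-bounds fixation row(s)", sum(oob)))
        table <- table[!oob, , drop = FALSE]
    }
    keep <- table$onset_ms >= 0 & table$onset_ms < geometry@trial_ms
    if (any(!keep)) {
        warning(sprintf("rejected %d row(s) with onset outside [0, trial_ms)",
                        sum(!keep)))
        table <- table[keep, , drop = FALSE]
    }
    table$offset_ms <- pmin(table$offset_ms, geometry@trial_ms)
    if (nrow(table) == 0L) return(list())

    key <- paste(table$participant, table$stimulus, sep = "\r")
    out <- lapply(split(seq_len(nrow(table)), key), function(idx) {
        rows <- table[idx, , drop = FALSE]
        rows <- rows[order(rows$onset_ms), , drop = FALSE]
        newTrialRecord(
            participant_id = as.character(rows$participant[1L]),
            stimulus_id = as.character(rows$stimulus[1L]),
            x_px = rows$x_px, y_px = rows$y_px,
            onset_ms = rows$onset_ms, offset_ms = rows$offset_ms)
    })
    names(out) <- NULL
    out
}

## internal constructor: renumbers orders 1..n
newTrialRecord <- function(participant_id, stimulus_id, x_px, y_px,
                           onset_ms, offset_ms) {
    fx <- data.frame(
        x_px = as.numeric(x_px), y_px = as.numeric(y_px),
        onset_ms = as.numeric(onset_ms), offset_ms = as.numeric(offset_ms),
        order = seq_along(x_px))
    new("TrialRecord", participant_id = participant_id,
        stimulus_id = stimulus_id, fixations = fx)
}

#' Read a fixation CSV into trial records
#'
#' Expects a UTF-8, comma-separated file with header columns
#' `participant,stimulus,x_px,y_px,onset_ms,offset_ms`.
#'
#' @param path path to the CSV file.
#' @param geometry a [ViewingGeometry].
#' @return a list of [TrialRecord] objects (see [loadTrials()]).
#' @export
readFixations <- function(path, geometry) {
    loadTrials(utils::read.csv(path, stringsAsFactors = FALSE), geometry)
}

#' Write trial records back to the fixation CSV schema
#'
#' @param trials list of [TrialRecord] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFixations <- function(trials, path) {
    rows <- lapply(trials, function(tr) {
        fx <- tr@fixations
        if (nrow(fx) == 0L) return(NULL)
        data.frame(participant = tr@participant_id, stimulus = tr@stimulus_id,
                   x_px = fx$x_px, y_px = fx$y_px,
                   onset_ms = fx$onset_ms, offset_ms = fx$offset_ms)
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Remove anticipatory fixations
#'
#' Fixations beginning sooner than `threshold_ms` after stimulus onset
#' cannot be driven by the stimulus and are excluded. The cut is strict
#' (`onset_ms < threshold_ms` removed; a fixation starting exactly at the
#' threshold is kept) and the remaining fixations are renumbered from 1.
#' The operation is idempotent.
#'
#' @param trial a [TrialRecord].
#' @param threshold_ms anticipatory threshold in ms (default 80).
#' @return the filtered [TrialRecord] (possibly with no fixations).
#' @examples
#' tr <- loadTrials(data.frame(participant = "p", stimulus = "s",
#'     x_px = c(10, 20), y_px = c(10, 20),
#'     onset_ms = c(50, 300), offset_ms = c(120, 500)),
#'     ViewingGeometry())[[1]]
#' fixations(filterAnticipatory(tr))  # only the 300 ms fixation remains
#' @export
filterAnticipatory <- function(trial, threshold_ms = 80) {
    stopifnot(is(trial, "TrialRecord"))
    if (threshold_ms < 0) stop("threshold_ms must be >= 0")
    fx <- trial@fixations
    keep <- fx$onset_ms >= threshold_ms
    fx <- fx[keep, , drop = FALSE]
    fx$order <- seq_len(nrow(fx))
    rownames(fx) <- NULL
    initialize(trial, fixations = fx)
}

#' Circular fixation-area mask
#'
#' The fixation area is a circular region of `radius_deg` (default 1
#' degree, matching foveal extent and tracker accuracy) around the fixated
#' location. A pixel belongs to the area when its center lies within
#' `radius_deg * pxPerDeg(geometry)` of `(x_px, y_px)` in Euclidean
#' distance; the disk is clipped at the stimulus bounds.
#'
#' @param x_px,y_px fixation coordinates (0-based pixel units; pixel
#'   centers sit at integer coordinates).
#' @param geometry a [ViewingGeometry].
#' @param radius_deg fixation-area radius in visual degrees.
#' @return a logical matrix of dimension `height_px x width_px` (rows = y).
#' @examples
#' geom <- ViewingGeometry(width_px = 10, height_px = 10,
#'                         width_deg = 5, height_deg = 5)
#' sum(fixationDiskMask(5, 5, geom, radius_deg = 1))  # 13 pixels at r = 2 px
#' @export
fixationDiskMask <- function(x_px, y_px, geometry, radius_deg = 1.0) {
    stopifnot(is(geometry, "ViewingGeometry"))
    if (x_px < 0 || x_px >= geometry@width_px ||
        y_px < 0 || y_px >= geometry@height_px)
        stop("fixation outside stimulus bounds; drop it upstream")
    r <- radius_deg * suppressWarnings(pxPerDeg(geometry))
    w <- as.integer(geometry@width_px); h <- as.integer(geometry@height_px)
    xs <- 0:(w - 1L); ys <- 0:(h - 1L)
    dx2 <- (xs - x_px)^2; dy2 <- (ys - y_px)^2
    outer(dy2, dx2, `+`) <= r^2
}
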