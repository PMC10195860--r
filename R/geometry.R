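#' Construct a viewing geometry
#'
#' @param distance_cm viewing distance in cm.
#' @param width_px,height_px stimulus size in pixels.
#' @param width_deg,height_deg stimulus extent in degrees of visual angle.
#' @param trial_ms stimulus presentation duration in ms.
#'
#' @details A warning is emitted when the horizontal and vertical
#' pixels-per-degree rates disagree by more than 5%, since an anisotropic
#' grid makes the circular fixation area elliptical in degree units.
#'
#' @return a [ViewingGeometry] object.
#' @examples
#' geom <- ViewingGeometry()
#' pxPerDeg(geom)   # 40 px/deg
#' @export
ViewingGeometry <- function(distance_cm = 86, width_px = 800, height_px = 600,
                            width_deg = 20, height_deg = 15, trial_ms = 5000) {
    obj <- new("ViewingGeometry",
        distance_cm = as.numeric(distance_cm),
        width_px = as.numeric(width_px), height_px = as.numeric(height_px),
        width_deg = as.numeric(width_deg), height_deg = as.numeric(height_deg),
        trial_ms = as.numeric(trial_ms))
    rh <- obj@width_px / obj@width_deg
    rv <- obj@height_px / obj@height_deg
    if (abs(rh - rv) / mean(c(rh, rv)) > 0.05)
        warning(sprintf(
            "horizontal (%.3g) and vertical (%.3g) px/deg differ by more than 5%%",
            rh, rv))
    obj
}

#' Pixels per degree of visual angle
#'
#' The mean of the horizontal (`width_px / width_deg`) and vertical
#' (`height_px / height_deg`) conversion rates. Warns when the two rates
#' disagree by more than 5%.
#'
#' @param geometry a [ViewingGeometry].
#' @return pixels per visual degree (scalar).
#' @examples
#' pxPerDeg(ViewingGeometry())  # 800/20 = 600/15 = 40
#' @export
pxPerDeg <- function(geometry) {
    stopifnot(is(geometry, "ViewingGeometry"))
    validObject(geometry)
    rh <- geometry@width_px / geometry@width_deg
    rv <- geometry@height_px / geometry@height_deg
    if (abs(rh - rv) / mean(c(rh, rv)) > 0.05)
        warning(sprintf(
            "horizontal (%.3g) and vertical (%.3g) px/deg differ by more than 5%%",
            rh, rv))
    mean(c(rh, rv))
}
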