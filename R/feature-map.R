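#' Construct a feature map
#'
#' @param intensity numeric matrix (rows = y, columns = x) of finite,
#'   non-negative values.
#' @param stimulus_id,feature_name identifiers.
#' @return a [FeatureMap].
#' @export
FeatureMap <- function(intensity, stimulus_id = "stimulus",
                       feature_name = "feature") {
    storage.mode(intensity) <- "double"
    new("FeatureMap", stimulus_id = as.character(stimulus_id),
        feature_name = as.character(feature_name), intensity = intensity)
}

#' Min-max rescale a feature map to [0, 1]
#'
#' Affine rescaling of the intensity field per stimulus so that its
#' minimum maps to 0 and its maximum to 1. A constant map carries no
#' spatial information; it is mapped to all zeros ("no intense feature
#' anywhere") with a warning.
#'
#' @param map a [FeatureMap] or a numeric matrix.
#' @return an object of the same kind with values in `[0, 1]`.
#' @examples
#' rescaleIntensity(FeatureMap(matrix(c(0, 5, 10, 5), 2)))
#' @export
rescaleIntensity <- function(map) {
    m <- if (is(map, "FeatureMap")) map@intensity else map
    rng <- range(m)
    if (diff(rng) == 0) {
        warning("constant feature map rescaled to all zeros")
        out <- array(0, dim = dim(m))
    } else {
        out <- (m - rng[1L]) / diff(rng)
    }
    if (is(map, "FeatureMap")) initialize(map, intensity = out) else out
}

#' Discretize a rescaled feature map into equal-width intensity levels
#'
#' Values in `[0, 1]` are assigned to `n_levels` equal-width bins,
#' `level(v) = min(floor(v * n_levels) + 1, n_levels)`: bins are left-closed
#' and the top bin is right-closed so that `v = 1` falls in level
#' `n_levels`.
#'
#' @param map a [FeatureMap] with values already in `[0, 1]`
#'   (see [rescaleIntensity()]).
#' @param n_levels number of levels (default 10).
#' @return a [DiscretizedFeatureMap].
#' @examples
#' fm <- rescaleIntensity(FeatureMap(matrix(runif(100), 10)))
#' table(levelGrid(discretizeLevels(fm)))
#' @export
discretizeLevels <- function(map, n_levels = 10) {
    stopifnot(is(map, "FeatureMap"))
    v <- map@intensity
    if (any(v < 0 | v > 1))
        stop("discretizeLevels expects values in [0, 1]; call rescaleIntensity first")
    lv <- pmin(floor(v * n_levels) + 1, n_levels)
    storage.mode(lv) <- "integer"
    new("DiscretizedFeatureMap", stimulus_id = map@stimulus_id,
        feature_name = map@feature_name, level = lv,
        n_levels = as.integer(n_levels))
}

#' Whole-image occupancy of each intensity level
#'
#' @param dmap a [DiscretizedFeatureMap].
#' @return integer vector of length `n_levels`: pixels per level.
#' @export
levelOccupancy <- function(dmap) {
    stopifnot(is(dmap, "DiscretizedFeatureMap"))
    tabulate(dmap@level, nbins = dmap@n_levels)
}

#' Read a stimulus image as an RGB array
#'
#' Thin wrapper around [EBImage::readImage()] returning a
#' `height x width x 3` numeric array in `[0, 1]` (rows = y, columns = x).
#' Grayscale images are replicated across the three channels.
#'
#' @param path image path (PNG/JPEG/TIFF).
#' @return numeric array `height x width x 3`.
#' @export
readStimulus <- function(path) {
    img <- EBImage::readImage(path)
    d <- dim(img)
    a <- as.array(img)
    if (length(d) == 2L) a <- array(rep(a, 3L), dim = c(d, 3L))
    if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
    ## EBImage stores [x, y, c]; transpose to [y, x, c]
    aperm(a, c(2L, 1L, 3L))
}

#' Write and read feature maps as lossless TIFF grids with a CSV manifest
#'
#' `writeFeatureMaps` stores each map as a 32-bit float TIFF named
#' `<stimulus_id>_<feature_name>.tiff` in `dir`, together with a
#' `manifest.csv` recording identifiers, file names and the intensity
#' range. `readFeatureMaps` restores the list from such a directory.
#'
#' @param maps list of [FeatureMap] objects.
#' @param dir output directory (created if needed).
#' @return `writeFeatureMaps`: the manifest path, invisibly;
#'   `readFeatureMaps`: a list of [FeatureMap] objects.
#' @export
writeFeatureMaps <- function(maps, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rows <- lapply(maps, function(m) {
        fn <- paste0(m@stimulus_id, "_", m@feature_name, ".tiff")
        EBImage::writeImage(EBImage::Image(t(m@intensity)),
                            file.path(dir, fn), type = "tiff",
                            bits.per.sample = 32L)
        data.frame(stimulus_id = m@stimulus_id, feature_name = m@feature_name,
                   path = fn, min = min(m@intensity), max = max(m@intensity))
    })
    manifest <- do.call(rbind, rows)
    mp <- file.path(dir, "manifest.csv")
    utils::write.csv(manifest, mp, row.names = FALSE)
    invisible(mp)
}

#' @rdname writeFeatureMaps
#' @export
readFeatureMaps <- function(dir) {
    manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                                stringsAsFactors = FALSE)
    lapply(seq_len(nrow(manifest)), function(i) {
        img <- EBImage::readImage(file.path(dir, manifest$path[i]))
        FeatureMap(t(as.array(img)), manifest$stimulus_id[i],
                   manifest$feature_name[i])
    })
}
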