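# shared builders for the test suite; everything is generated in code

toyGeometry <- function(width_px = 10, height_px = 10, width_deg = 5,
                        height_deg = 5, trial_ms = 5000) {
    ViewingGeometry(width_px = width_px, height_px = height_px,
                    width_deg = width_deg, height_deg = height_deg,
                    trial_ms = trial_ms)
}

makeTrial <- function(x, y, onset, offset, geom,
                      participant = "p1", stimulus = "s1") {
    loadTrials(data.frame(participant = participant, stimulus = stimulus,
                          x_px = x, y_px = y, onset_ms = onset,
                          offset_ms = offset), geom)[[1L]]
}

uniformDmap <- function(width_px = 10, height_px = 10, level = 10L,
                        n_levels = 10L, stimulus = "s1", feature = "f") {
    new("DiscretizedFeatureMap", stimulus_id = stimulus,
        feature_name = feature,
        level = matrix(as.integer(level), height_px, width_px),
        n_levels = as.integer(n_levels))
}

randomDmap <- function(width_px, height_px, seed, smoothness = 0,
                       stimulus = "s1", feature = "f") {
    discretizeLevels(genFeatureField(width_px, height_px, smoothness, seed,
                                     stimulus_id = stimulus,
                                     feature_name = feature))
}

# a one-blob intensity field: the level-10 region is a small disk
blobFeatureMap <- function(width_px = 100, height_px = 100, cx = 30,
                           cy = 60, sigma = 12, stimulus = "s1",
                           feature = "f") {
    xs <- matrix(rep(seq_len(width_px) - 1L, each = height_px), height_px)
    ys <- matrix(rep(seq_len(height_px) - 1L, times = width_px), height_px)
    rescaleIntensity(FeatureMap(exp(-((xs - cx)^2 + (ys - cy)^2) /
                                    (2 * sigma^2)), stimulus, feature))
}

# linear extractor whose gradient varies over space (fewer 3x3 windows
# cover border pixels under a zero-padded "same" convolution of the
# channel mean with a ones kernel) but is independent of the image, so
# its back-projected map has spatial structure yet is exactly invariant
# to scaling the image
borderLinearExtractor <- function() {
    nwin <- function(n) 3L - (seq_len(n) == 1L) - (seq_len(n) == n)
    new("FeatureExtractor", name = "border-linear", layers = "lin",
        native_size = integer(0),
        forward = function(image) {
            H <- dim(image)[1L]; W <- dim(image)[2L]
            list(lin = array((image[, , 1L] + image[, , 2L] +
                              image[, , 3L]) / 3, dim = c(H, W, 1L)))
        },
        gradientSum = function(image, layer) {
            H <- dim(image)[1L]; W <- dim(image)[2L]
            g <- outer(nwin(H), nwin(W)) / 3
            array(rep(g, 3L), dim = c(H, W, 3L))
        })
}
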