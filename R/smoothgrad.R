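#' Noise-averaged gradient back-projection of a convolutional layer
#'
#' Back-projects the summed activation of one convolutional layer into
#' the pixel space of the stimulus: for each of `n_samples` noisy copies
#' of the image (additive Gaussian noise with sd equal to `noise_sd`
#' times the image's dynamic range), the gradient of the summed layer
#' activation with respect to the input pixels is computed; absolute
#' gradients are averaged over color channels and over samples. The
#' resulting graded field is the feature-intensity map of that layer.
#' With `noise_sd = 0` the map equals the plain gradient magnitude
#' regardless of `n_samples`.
#'
#' The summed (rectified) activation is used as the back-projected scalar;
#' pass a different `reduce` to change it. If the extractor declares a
#' native input size, the image is resized to it (bilinear) and the map
#' is resized back to stimulus resolution.
#'
#' @param extractor a [FeatureExtractor].
#' @param layer one of `extractor@layers`.
#' @param image numeric array `height x width x 3` in `[0, 1]`.
#' @param n_samples number of noisy samples (default 50).
#' @param noise_sd noise level as a fraction of the input dynamic range
#'   (default 0.10).
#' @param seed RNG seed; maps are reproducible given
#'   `(seed, n_samples, noise_sd)`.
#' @param stimulus_id identifier for the resulting map.
#' @param reduce reserved for alternative activation reductions; only
#'   `"sum"` is implemented.
#' @return a [FeatureMap] named after the layer.
#' @examples
#' ext <- linearExtractor(c(1, -2, 3))
#' img <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
#' fm <- smoothGradMap(ext, "linear", img, n_samples = 1, noise_sd = 0)
#' unique(round(as.vector(intensity(fm)), 10))  # (|1|+|-2|+|3|)/3 = 2
#' @export
smoothGradMap <- function(extractor, layer, image, n_samples = 50,
                          noise_sd = 0.10, seed = 1L,
                          stimulus_id = "stimulus", reduce = "sum") {
    stopifnot(is(extractor, "FeatureExtractor"))
    if (!layer %in% extractor@layers)
        stop("unknown layer '", layer, "'; available: ",
             paste(extractor@layers, collapse = ", "))
    if (n_samples < 1) stop("n_samples must be >= 1")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (reduce != "sum") stop("only the summed-activation reduction is implemented")
    H <- dim(image)[1L]; W <- dim(image)[2L]

    work <- image
    if (length(extractor@native_size) == 2L &&
        !all(dim(image)[1:2] == extractor@native_size)) {
        work <- .resizeArray(image, extractor@native_size[1L],
                             extractor@native_size[2L])
    }
    sdv <- noise_sd * diff(range(work))
    set.seed(as.integer(seed))
    acc <- matrix(0, dim(work)[1L], dim(work)[2L])
    for (i in seq_len(n_samples)) {
        noisy <- if (sdv > 0)
            work + array(stats::rnorm(length(work), sd = sdv), dim = dim(work))
        else work
        g <- extractor@gradientSum(noisy, layer)
        acc <- acc + (abs(g[, , 1L]) + abs(g[, , 2L]) + abs(g[, , 3L])) / 3
    }
    m <- acc / n_samples
    if (!all(dim(m) == c(H, W)))
        m <- .resizeMatrix(m, H, W)
    FeatureMap(m, stimulus_id = stimulus_id, feature_name = layer)
}

## bilinear resize helpers (EBImage uses [x, y] order; our matrices are
## [y, x], so resize transposed dimensions consistently)
.resizeMatrix <- function(m, new_h, new_w) {
    r <- EBImage::imageData(EBImage::resize(EBImage::Image(t(m)),
                                            w = new_w, h = new_h))
    t(matrix(as.numeric(r), nrow = new_w, ncol = new_h))
}

.resizeArray <- function(a, new_h, new_w) {
    out <- array(0, dim = c(new_h, new_w, dim(a)[3L]))
    for (c_ in seq_len(dim(a)[3L]))
        out[, , c_] <- .resizeMatrix(a[, , c_], new_h, new_w)
    out
}
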