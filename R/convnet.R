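## Minimal dense convolution machinery for the fixture extractors.
## Inputs are arrays H x W x C; kernels kh x kw x Cin x Cout ("same"
## zero padding, stride 1). Small and explicit on purpose: the fixture
## must expose exact analytic gradients to validate the back-projection.

.conv2dSame <- function(x, w, b = NULL) {
    kh <- dim(w)[1L]; kw <- dim(w)[2L]
    cin <- dim(w)[3L]; cout <- dim(w)[4L]
    H <- dim(x)[1L]; W <- dim(x)[2L]
    ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
    xp <- array(0, dim = c(H + 2L * ph, W + 2L * pw, cin))
    xp[ph + seq_len(H), pw + seq_len(W), ] <- x
    out <- array(0, dim = c(H, W, cout))
    for (o in seq_len(cout)) {
        acc <- matrix(if (is.null(b)) 0 else b[o], H, W)
        for (ci in seq_len(cin))
            for (di in seq_len(kh))
                for (dj in seq_len(kw))
                    acc <- acc + w[di, dj, ci, o] *
                        xp[di + seq_len(H) - 1L, dj + seq_len(W) - 1L, ci]
        out[, , o] <- acc
    }
    out
}

## gradient of the convolution output wrt its input, given upstream
## gradient g (H x W x Cout)
.conv2dBackward <- function(g, w, H, W) {
    kh <- dim(w)[1L]; kw <- dim(w)[2L]
    cin <- dim(w)[3L]; cout <- dim(w)[4L]
    ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
    gx <- array(0, dim = c(H + 2L * ph, W + 2L * pw, cin))
    for (o in seq_len(cout)) {
        go <- g[, , o]
        for (ci in seq_len(cin))
            for (di in seq_len(kh))
                for (dj in seq_len(kw)) {
                    ri <- di + seq_len(H) - 1L; cj <- dj + seq_len(W) - 1L
                    gx[ri, cj, ci] <- gx[ri, cj, ci] + w[di, dj, ci, o] * go
                }
    }
    gx[ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
}

#' Tiny fixed-weight convolutional extractor
#'
#' A two-layer rectified convolutional network with seeded fixed weights,
#' serving as a deterministic, analytically differentiable stand-in for a
#' pretrained object-recognition network. Layers `conv1` and `conv2` are
#' bias-free 3 x 3 "same" convolutions (3 -> 4 and 4 -> 4 channels)
#' followed by ReLU, so an all-zero input yields zero activation and zero
#' gradient. The exposed gradient of the summed layer activation matches
#' finite differences, which is what qualifies it as a back-projection
#' oracle.
#'
#' @param seed seed for the fixed weights.
#' @return a [FeatureExtractor] with layers `conv1`, `conv2`.
#' @examples
#' ext <- tinyConvnetFixture(1)
#' img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
#' names(ext@forward(img))
#' @export
tinyConvnetFixture <- function(seed = 1L) {
    set.seed(as.integer(seed))
    w1 <- array(stats::rnorm(3 * 3 * 3 * 4, sd = 0.3), dim = c(3, 3, 3, 4))
    w2 <- array(stats::rnorm(3 * 3 * 4 * 4, sd = 0.3), dim = c(3, 3, 4, 4))

    fwd <- function(image) {
        z1 <- .conv2dSame(image, w1); a1 <- pmax(z1, 0)
        z2 <- .conv2dSame(a1, w2);    a2 <- pmax(z2, 0)
        list(z1 = z1, a1 = a1, z2 = z2, a2 = a2)
    }
    new("FeatureExtractor",
        name = "tiny-fixture",
        layers = c("conv1", "conv2"),
        native_size = integer(0),
        forward = function(image) {
            st <- fwd(image)
            list(conv1 = st$a1, conv2 = st$a2)
        },
        gradientSum = function(image, layer) {
            H <- dim(image)[1L]; W <- dim(image)[2L]
            st <- fwd(image)
            if (layer == "conv1") {
                g1 <- (st$z1 > 0) * 1
            } else if (layer == "conv2") {
                g2 <- (st$z2 > 0) * 1
                g1 <- .conv2dBackward(g2, w2, H, W) * (st$z1 > 0)
            } else stop("unknown layer: ", layer)
            .conv2dBackward(g1, w1, H, W)
        })
}

#' Linear single-layer extractor with known closed-form gradient
#'
#' A 1 x 1 convolution with channel weights `w`, no rectification: the
#' activation at every pixel is `w . rgb`, and the gradient of the summed
#' activation is exactly `w[c]` at every pixel and channel. The
#' back-projected map of such an extractor is the constant
#' `mean(abs(w))`, a closed form used to validate [smoothGradMap()].
#'
#' @param w numeric length-3 channel weights.
#' @return a [FeatureExtractor] with one layer `linear`.
#' @export
linearExtractor <- function(w = c(1, 2, 3)) {
    stopifnot(length(w) == 3L)
    new("FeatureExtractor",
        name = "linear",
        layers = "linear",
        native_size = integer(0),
        forward = function(image) {
            H <- dim(image)[1L]; W <- dim(image)[2L]
            a <- image[, , 1L] * w[1L] + image[, , 2L] * w[2L] +
                 image[, , 3L] * w[3L]
            list(linear = array(a, dim = c(H, W, 1L)))
        },
        gradientSum = function(image, layer) {
            if (layer != "linear") stop("unknown layer: ", layer)
            H <- dim(image)[1L]; W <- dim(image)[2L]
            array(rep(w, each = H * W), dim = c(H, W, 3L))
        })
}
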