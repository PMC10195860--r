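#' Per-channel conspicuity map
#'
#' Intermediate saliency map of one channel (intensity, color or
#' orientation) at the model's reduced output scale, before equal-weight
#' combination into the final saliency map.
#'
#' @slot channel one of `"intensity"`, `"color"`, `"orientation"`.
#' @slot values non-negative matrix at the output scale.
#' @slot scale pyramid scale index of the map.
#' @exportClass ConspicuityMap
setClass("ConspicuityMap",
    representation(channel = "character", values = "matrix",
                   scale = "integer"))

setValidity("ConspicuityMap", function(object) {
    if (any(!is.finite(object@values)) || any(object@values < 0))
        return("conspicuity values must be finite and >= 0")
    TRUE
})

setMethod("show", "ConspicuityMap", function(object) {
    cat(sprintf("ConspicuityMap '%s' at scale %d: %d x %d, max %.4g\n",
                object@channel, object@scale, ncol(object@values),
                nrow(object@values), max(object@values)))
})

## replicate-boundary 2-D convolution that tolerates images smaller than
## the kernel (pads by edge replication, filters, crops back)
.filterRep <- function(m, kern) {
    nr <- nrow(m); nc <- ncol(m)
    pr <- max(0L, nrow(kern) - nr); pc <- max(0L, ncol(kern) - nc)
    if (pr > 0L || pc > 0L) {
        ri <- pmin(pmax(seq_len(nr + 2L * pr) - pr, 1L), nr)
        ci <- pmin(pmax(seq_len(nc + 2L * pc) - pc, 1L), nc)
        out <- as.matrix(EBImage::filter2(m[ri, ci, drop = FALSE], kern,
                                          boundary = "replicate"))
        out[pr + seq_len(nr), pc + seq_len(nc), drop = FALSE]
    } else {
        as.matrix(EBImage::filter2(m, kern, boundary = "replicate"))
    }
}

## 5 x 5 binomial low-pass, then decimation by 2
.gaussReduce <- function(m) {
    k1 <- c(1, 4, 6, 4, 1) / 16
    kern <- outer(k1, k1)
    b <- .filterRep(m, kern)
    b[seq(1L, nrow(b), by = 2L), seq(1L, ncol(b), by = 2L), drop = FALSE]
}

## Gaussian pyramid, scales 0..depth-1 (list index = scale + 1)
.pyramid <- function(m, depth = 9L) {
    out <- vector("list", depth)
    out[[1L]] <- m
    for (s in 2:depth) out[[s]] <- .gaussReduce(out[[s - 1L]])
    out
}

## across-scale difference: surround upsampled to the center scale
.centerSurround <- function(center, surround) {
    abs(center - .resizeMatrix(surround, nrow(center), ncol(center)))
}

## linear ramp attenuation of the map borders, where the surround is
## undefined outside the image
.attenuateBorders <- function(m, width = NULL) {
    if (is.null(width)) width <- max(1L, round(min(dim(m)) / 20))
    nr <- nrow(m); nc <- ncol(m)
    width <- min(width, floor((min(nr, nc) - 1) / 2))
    if (width < 1L) return(m)
    ramp <- seq_len(width) / (width + 1)
    for (i in seq_len(width)) {
        m[i, ] <- m[i, ] * ramp[i]; m[nr - i + 1L, ] <- m[nr - i + 1L, ] * ramp[i]
        m[, i] <- m[, i] * ramp[i]; m[, nc - i + 1L] <- m[, nc - i + 1L] * ramp[i]
    }
    m
}

#' Map normalization promoting maps with one dominant peak
#'
#' The normalization operator of the classic bottom-up saliency model:
#' the map is rescaled to `[0, 1]` and multiplied by
#' `(1 - mean of local maxima excluding the global maximum)^2`. A map
#' with a single isolated peak keeps its peak near 1; a map with many
#' comparable peaks is globally suppressed. Constant maps (no distinct
#' maximum) return all zeros.
#'
#' @param map numeric matrix.
#' @param tol dynamic-range floor: maps whose min-to-max range does not
#'   exceed `tol` are treated as constant and return zeros, so that
#'   numerically flat maps (FFT roundoff on featureless input) are not
#'   amplified into spurious structure.
#' @return normalized matrix in `[0, 1]`.
#' @export
mapNormalization <- function(map, tol = 1e-9) {
    rng <- range(map)
    if (diff(rng) <= tol) return(array(0, dim = dim(map)))
    m <- (map - rng[1L]) / diff(rng)
    lm <- .localMaxima(m)
    vals <- m[lm]
    vals <- vals[vals > 0]
    if (length(vals)) {
        vals <- sort(vals, decreasing = TRUE)[-1L]  # drop the global max once
        mbar <- if (length(vals)) mean(vals) else 0
    } else mbar <- 0
    m * (1 - mbar)^2
}

## strict 8-neighbor local maxima (replicated borders)
.localMaxima <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    up <- function(x) x[c(1L, seq_len(nr - 1L)), , drop = FALSE]
    dn <- function(x) x[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
    lf <- function(x) x[, c(1L, seq_len(nc - 1L)), drop = FALSE]
    rt <- function(x) x[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
    sh <- list(up(m), dn(m), lf(m), rt(m),
               up(lf(m)), up(rt(m)), dn(lf(m)), dn(rt(m)))
    ge <- Reduce(`&`, lapply(sh, function(s) m >= s))
    gt <- Reduce(`|`, lapply(sh, function(s) m > s))
    ge & gt
}

## Gabor energy at one orientation (zero-mean even + odd quadrature pair)
.gaborEnergy <- function(m, theta_deg, ksize = 9L, lambda = 7, sigma = 7 / 3) {
    half <- (ksize - 1L) / 2
    xs <- matrix(rep(-half:half, each = ksize), ksize)
    ys <- matrix(rep(-half:half, times = ksize), ksize)
    th <- theta_deg * pi / 180
    xr <- xs * cos(th) + ys * sin(th)
    yr <- -xs * sin(th) + ys * cos(th)
    env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
    even <- env * cos(2 * pi * xr / lambda)
    even <- even - mean(even)
    odd <- env * sin(2 * pi * xr / lambda)
    e <- .filterRep(m, even)
    o <- .filterRep(m, odd)
    sqrt(e^2 + o^2)
}

.checkPyramidSize <- function(image, depth) {
    min_dim <- 2^(depth - 1L)
    if (min(dim(image)[1:2]) < min_dim)
        stop(sprintf(
            "image too small for a %d-scale pyramid: both dimensions must be >= %d px",
            depth, min_dim))
}

#' Channel conspicuity of the bottom-up saliency model
#'
#' Computes one channel of the classic multiscale saliency model: a
#' 9-scale Gaussian pyramid, across-scale center-surround differences
#' with centers `c` in \{2, 3, 4\} and deltas `d` in \{3, 4\}
#' (surround scale `s = c + d`), per-feature-map normalization
#' ([mapNormalization()]) with border attenuation, and summation at the
#' output scale. Intensity is the RGB mean; color uses red-green and
#' blue-yellow opponency; orientation uses Gabor energy at 0, 45, 90 and
#' 135 degrees.
#'
#' @param image numeric array `height x width x 3` in `[0, 1]`.
#' @param channel `"intensity"`, `"color"` or `"orientation"`.
#' @param depth pyramid depth (default 9).
#' @param centers,deltas center scales and center-surround scale offsets.
#' @param output_scale scale of the returned map (default 4).
#' @return a [ConspicuityMap].
#' @export
channelConspicuity <- function(image, channel = c("intensity", "color",
                                                  "orientation"),
                               depth = 9L, centers = c(2L, 3L, 4L),
                               deltas = c(3L, 4L), output_scale = 4L) {
    channel <- match.arg(channel)
    .checkPyramidSize(image, depth)
    r <- image[, , 1L]; g <- image[, , 2L]; b <- image[, , 3L]
    int <- (r + g + b) / 3
    out_dim <- dim(.pyramid(int, depth)[[output_scale + 1L]])

    accum <- matrix(0, out_dim[1L], out_dim[2L])
    addMaps <- function(center_pyr, surround_pyr) {
        acc <- matrix(0, out_dim[1L], out_dim[2L])
        for (cs in centers) for (d in deltas) {
            s <- cs + d
            fm <- .centerSurround(center_pyr[[cs + 1L]], surround_pyr[[s + 1L]])
            fm <- .attenuateBorders(fm)
            fm <- mapNormalization(fm)
            acc <- acc + .resizeMatrix(fm, out_dim[1L], out_dim[2L])
        }
        acc
    }

    if (channel == "intensity") {
        ip <- .pyramid(int, depth)
        accum <- addMaps(ip, ip)
    } else if (channel == "color") {
        gate <- int > max(int) / 10
        nz <- ifelse(gate, int, 1)
        rn <- ifelse(gate, r / nz, 0)
        gn <- ifelse(gate, g / nz, 0)
        bn <- ifelse(gate, b / nz, 0)
        R <- pmax(rn - (gn + bn) / 2, 0)
        G <- pmax(gn - (rn + bn) / 2, 0)
        B <- pmax(bn - (rn + gn) / 2, 0)
        Y <- pmax((rn + gn) / 2 - abs(rn - gn) / 2 - bn, 0)
        rg <- .pyramid(R - G, depth)
        gr <- .pyramid(G - R, depth)
        by <- .pyramid(B - Y, depth)
        yb <- .pyramid(Y - B, depth)
        for (cs in centers) for (d in deltas) {
            s <- cs + d
            fm1 <- .centerSurround(rg[[cs + 1L]], gr[[s + 1L]])
            fm2 <- .centerSurround(by[[cs + 1L]], yb[[s + 1L]])
            for (fm in list(fm1, fm2)) {
                fm <- mapNormalization(.attenuateBorders(fm))
                accum <- accum + .resizeMatrix(fm, out_dim[1L], out_dim[2L])
            }
        }
    } else {
        ip <- .pyramid(int, depth)
        for (th in c(0, 45, 90, 135)) {
            op <- lapply(ip, .gaborEnergy, theta_deg = th)
            th_sum <- addMaps(op, op)
            accum <- accum + mapNormalization(th_sum)
        }
    }
    new("ConspicuityMap", channel = channel, values = pmax(accum, 0),
        scale = as.integer(output_scale))
}

#' Bottom-up (Itti-Koch) saliency map
#'
#' Combines the intensity, color and orientation conspicuity maps with
#' equal weights after a final [mapNormalization()] of each, and
#' upsamples the result bilinearly to stimulus resolution so saliency
#' shares one grid with the other feature maps. Saliency is low near the
#' stimulus borders, where the multiscale surround is undefined outside
#' the image; this attenuation is a property of the model family and is
#' kept, not corrected.
#'
#' @param image numeric array `height x width x 3` in `[0, 1]` (a plain
#'   matrix is treated as grayscale).
#' @param stimulus_id identifier for the resulting map.
#' @param depth,centers,deltas,output_scale model parameters (see
#'   [channelConspicuity()]).
#' @return a [FeatureMap] with `feature_name = "ittikoch"`.
#' @export
ittiKochSaliency <- function(image, stimulus_id = "stimulus", depth = 9L,
                             centers = c(2L, 3L, 4L), deltas = c(3L, 4L),
                             output_scale = 4L) {
    if (is.matrix(image))
        image <- array(rep(image, 3L), dim = c(dim(image), 3L))
    .checkPyramidSize(image, depth)
    cons <- lapply(c("intensity", "color", "orientation"), function(ch)
        channelConspicuity(image, ch, depth, centers, deltas, output_scale))
    sal <- Reduce(`+`, lapply(cons, function(cm)
        mapNormalization(cm@values))) / 3
    sal <- .resizeMatrix(sal, dim(image)[1L], dim(image)[2L])
    FeatureMap(pmax(sal, 0), stimulus_id = stimulus_id,
               feature_name = "ittikoch")
}
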