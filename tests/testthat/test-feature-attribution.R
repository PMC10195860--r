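test_that("intensity rescaling is affine min-max with a degenerate-constant rule", {
    fm <- FeatureMap(matrix(c(0, 5, 10, 5), 2), "s", "f")
    expect_equal(sort(unique(as.vector(intensity(rescaleIntensity(fm))))),
                 c(0, 0.5, 1))
    already <- FeatureMap(matrix(c(0, 0.25, 1, 0.5), 2), "s", "f")
    expect_equal(intensity(rescaleIntensity(already)), intensity(already))
    const <- FeatureMap(matrix(3, 4, 4), "s", "f")
    expect_warning(out <- rescaleIntensity(const), "constant")
    expect_true(all(intensity(out) == 0))
})

test_that("level discretization uses equal-width bins with a right-closed top bin", {
    v <- matrix(c(0, 1, 0.55, 0.0999, 0.1, 0.999), 2, 3)
    dm <- discretizeLevels(FeatureMap(v, "s", "f"))
    expect_equal(as.vector(levelGrid(dm)), c(1L, 10L, 6L, 1L, 2L, 10L))
    expect_error(discretizeLevels(FeatureMap(matrix(1.5, 2, 2), "s", "f")),
                 "\\[0, 1\\]")
    # uniform values fill each level at about 10%
    set.seed(9)
    dm2 <- discretizeLevels(FeatureMap(matrix(runif(200 * 150), 150), "s", "f"))
    share <- levelOccupancy(dm2) / (200 * 150)
    expect_true(all(abs(share - 0.1) < 0.015))
    # every pixel has exactly one level: levels partition the stimulus
    expect_equal(sum(levelOccupancy(dm2)), 200L * 150L)
})

test_that("back-projection of a linear extractor reproduces the closed form", {
    img <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
    fm <- smoothGradMap(linearExtractor(c(1, -2, 3)), "linear", img,
                        n_samples = 1, noise_sd = 0)
    expect_equal(as.vector(intensity(fm)), rep(2, 144))  # (1 + 2 + 3) / 3
    expect_error(smoothGradMap(linearExtractor(), "nope", img), "unknown layer")
    expect_error(smoothGradMap(linearExtractor(), "linear", img,
                               n_samples = 0), "n_samples")
})

test_that("zero-noise maps are independent of the sample count and reproducible", {
    ext <- tinyConvnetFixture(7)
    set.seed(5)
    img <- array(runif(10 * 10 * 3), dim = c(10, 10, 3))
    m1 <- smoothGradMap(ext, "conv2", img, n_samples = 1, noise_sd = 0)
    m5 <- smoothGradMap(ext, "conv2", img, n_samples = 5, noise_sd = 0)
    expect_equal(intensity(m1), intensity(m5))
    a <- smoothGradMap(ext, "conv2", img, n_samples = 8, noise_sd = 0.1,
                       seed = 42)
    b <- smoothGradMap(ext, "conv2", img, n_samples = 8, noise_sd = 0.1,
                       seed = 42)
    c_ <- smoothGradMap(ext, "conv2", img, n_samples = 8, noise_sd = 0.1,
                        seed = 43)
    expect_identical(intensity(a), intensity(b))
    expect_false(identical(intensity(a), intensity(c_)))
})

test_that("zero-noise maps agree with finite differences of the activation sum", {
    ext <- tinyConvnetFixture(1)
    set.seed(8)
    img <- array(runif(8 * 8 * 3, 0.1, 0.9), dim = c(8, 8, 3))
    for (layer in c("conv1", "conv2")) {
        g <- ext@gradientSum(img, layer)
        eps <- 1e-5
        idx <- sample(length(img), 20)
        for (i in idx) {
            up <- img; up[i] <- up[i] + eps
            dn <- img; dn[i] <- dn[i] - eps
            fd <- (sum(ext@forward(up)[[layer]]) -
                   sum(ext@forward(dn)[[layer]])) / (2 * eps)
            expect_lt(abs(fd - g[i]) / max(abs(fd), 1e-8), 1e-3)
        }
    }
})

test_that("native-size extractors trigger bilinear resize both ways", {
    ext <- linearExtractor(c(2, 2, 2))
    ext@native_size <- c(6L, 6L)
    img <- array(runif(12 * 18 * 3), dim = c(12, 18, 3))
    fm <- smoothGradMap(ext, "linear", img, n_samples = 1, noise_sd = 0)
    expect_equal(dim(intensity(fm)), c(12L, 18L))
    expect_equal(as.vector(intensity(fm)), rep(2, 12 * 18))
})

test_that("image scaling does not change the discretized map of a linear extractor", {
    ext <- borderLinearExtractor()
    set.seed(3)
    img <- array(runif(9 * 7 * 3), dim = c(9, 7, 3))
    lvl <- function(im) levelGrid(discretizeLevels(rescaleIntensity(
        smoothGradMap(ext, "lin", im, n_samples = 1, noise_sd = 0))))
    expect_identical(lvl(img), lvl(img * 3.7))
    # and the map itself has genuine spatial structure
    m <- intensity(smoothGradMap(ext, "lin", img, n_samples = 1,
                                 noise_sd = 0))
    expect_gt(max(m), min(m))
})

test_that("feature maps round-trip through the TIFF grid store", {
    fm1 <- genFeatureField(24, 16, 3, seed = 1, stimulus_id = "sA",
                           feature_name = "f1")
    fm2 <- genFeatureField(24, 16, 0, seed = 2, stimulus_id = "sB",
                           feature_name = "f2")
    dir <- withr::local_tempdir()
    writeFeatureMaps(list(fm1, fm2), dir)
    back <- readFeatureMaps(dir)
    expect_length(back, 2L)
    expect_equal(intensity(back[[1L]]), intensity(fm1), tolerance = 1e-6)
    expect_equal(featureName(back[[2L]]), "f2")
})
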