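test_that("occupancy counts and the GA ratio follow the relative-occupancy definition", {
    lev <- matrix(1L, 10, 10); lev[1:5, 1:5] <- 10L
    dm <- new("DiscretizedFeatureMap", stimulus_id = "s", feature_name = "f",
              level = lev, n_levels = 10L)
    mask <- matrix(FALSE, 10, 10); mask[1:2, 1:2] <- TRUE
    cts <- occupancyCounts(dm, 10L, mask)
    expect_equal(c(cts@n_feature_fa, cts@n_all_fa, cts@n_feature_img,
                   cts@n_all_img), c(4, 4, 25, 100))
    expect_equal(gaValue(cts), 4)

    # uniform map: both occupancy rates agree, GA is exactly 1
    dmu <- uniformDmap(10, 10, level = 10L)
    expect_equal(gaValue(occupancyCounts(dmu, 10L, mask)), 1)
    # absent level: 0 pixels in the area, GA 0; absent from image: NA
    expect_equal(gaValue(occupancyCounts(dm, 5L, mask)), NA_real_)
    expect_equal(gaValue(occupancyCounts(dmu, 10L,
        matrix(TRUE, 10, 10)))[1L], 1)
    full <- occupancyCounts(dm, 10L, matrix(TRUE, 10, 10))
    expect_equal(full@n_feature_fa, full@n_feature_img)
    expect_error(gaValue(new("OccupancyCounts", n_feature_fa = 0,
        n_all_fa = 0, n_feature_img = 5, n_all_img = 10)), "n_all_fa")
    expect_error(occupancyCounts(dm, 10L, matrix(TRUE, 5, 5)), "shape")
})

test_that("level-weighted GA values reweight to unity for any fixation", {
    geom <- toyGeometry(30, 30, 6, 6)
    set.seed(14)
    for (i in 1:8) {
        dm <- randomDmap(30, 30, seed = i, smoothness = i %% 3)
        x <- runif(1, 0, 29); y <- runif(1, 0, 29)
        mask <- fixationDiskMask(x, y, geom)
        occ <- levelOccupancy(dm)
        ga <- vapply(1:10, function(l)
            gaValue(occupancyCounts(dm, l, mask)), numeric(1L))
        present <- occ > 0
        expect_equal(sum(ga[present] * occ[present] / sum(occ)), 1)
    }
})

test_that("local-window GA evaluation equals the full-mask computation", {
    geom <- toyGeometry(40, 40, 8, 8)
    r <- pxPerDeg(geom)
    set.seed(6)
    for (i in 1:6) {
        dm <- randomDmap(40, 40, seed = 20 + i, smoothness = 2)
        x <- runif(1, 0, 39); y <- runif(1, 0, 39)
        mask <- fixationDiskMask(x, y, geom)
        occ <- levelOccupancy(dm)
        fast <- GazeBias:::.gaAllLevels(dm, x, y, r)
        slow <- vapply(1:10, function(l)
            gaValue(occupancyCounts(dm, l, mask)), numeric(1L))
        expect_equal(fast, slow)
    }
})

test_that("trial time course writes GA over each fixation's duration", {
    geom <- toyGeometry(10, 10, 5, 5)
    lev <- matrix(1L, 10, 10); lev[1:5, 1:5] <- 10L
    dm <- new("DiscretizedFeatureMap", stimulus_id = "s1",
              feature_name = "f", level = lev, n_levels = 10L)
    tr <- makeTrial(2, 2, 300, 500, geom)
    v <- trialTimeCourse(tr, dm, 10L, geom)
    ga <- GazeBias:::.gaAllLevels(dm, 2, 2, 2)[10L]
    expect_length(v, 5000L)
    expect_equal(sum(v > 0), 200L)
    expect_equal(unique(v[301:500]), ga)
    expect_true(all(v[-(301:500)] == 0))
    expect_false(attr(v, "missing"))

    # no fixations: all-zero series
    tr0 <- filterAnticipatory(makeTrial(2, 2, 10, 50, geom))
    expect_true(all(trialTimeCourse(tr0, dm, 10L, geom) == 0))

    # two disjoint fixations: the writes are disjoint interval writes
    tr2 <- makeTrial(c(2, 8), c(2, 8), c(300, 1000), c(500, 1400), geom)
    v2 <- trialTimeCourse(tr2, dm, 10L, geom)
    ga2 <- GazeBias:::.gaAllLevels(dm, 8, 8, 2)[10L]
    expect_equal(unique(v2[301:500]), ga)
    expect_equal(unique(v2[1001:1400]), ga2)
    expect_equal(sum(v2 > 0) + sum(ga2 == 0) * 400, 600L)

    # absent level marks the trial missing and leaves the series zero
    v3 <- trialTimeCourse(tr, dm, 5L, geom)
    expect_true(attr(v3, "missing"))
    expect_true(all(v3 == 0))

    # uniform map: the course integrates to GA x duration exactly
    dmu <- uniformDmap(10, 10)
    vu <- trialTimeCourse(tr, dmu, 10L, geom)
    expect_equal(sum(vu), 1 * 200)

    # onset-only mode writes a single sample
    vo <- trialTimeCourse(tr, dm, 10L, geom, onset_only = TRUE)
    expect_equal(sum(vo > 0), 1L)
    expect_equal(vo[301L], ga)
})

test_that("mean time course averages over images and honors missing marks", {
    a <- c(2, 0, 2); b <- c(0, 0, 2)
    tc <- meanTimeCourse(list(a, b), "f", 1L, "p", grid_ms = 1)
    expect_equal(gaSeries(tc), c(1, 0, 2))
    m <- c(9, 9, 9); attr(m, "missing") <- TRUE
    tc2 <- meanTimeCourse(list(a, b, m), "f", 1L, "p")
    expect_equal(gaSeries(tc2), c(1, 0, 2))
    expect_equal(tc2@n_images, 2L)
    tc3 <- meanTimeCourse(list(a, a, a), "f", 1L, "p")
    expect_equal(gaSeries(tc3), a)
    # permutation invariance
    tc4 <- meanTimeCourse(list(b, a), "f", 1L, "p")
    expect_equal(gaSeries(tc4), gaSeries(tc))
    expect_error(meanTimeCourse(list()), "no per-image")
})

test_that("participant time courses equal the per-trial/meanTimeCourse route", {
    geom <- toyGeometry(30, 30, 6, 6)
    dms <- list(s1 = randomDmap(30, 30, seed = 31, smoothness = 2,
                                stimulus = "s1"),
                s2 = randomDmap(30, 30, seed = 32, smoothness = 2,
                                stimulus = "s2"))
    set.seed(44)
    trials <- lapply(c("s1", "s2"), function(s)
        makeTrial(runif(3, 2, 27), runif(3, 2, 27),
                  c(200, 1500, 3000), c(800, 2300, 4100), geom,
                  stimulus = s))
    fast <- participantTimeCourses(trials, dms, geom)
    for (lv in c(2L, 5L, 9L)) {
        slow <- meanTimeCourse(lapply(trials, function(tr)
            trialTimeCourse(tr, dms[[stimulusId(tr)]], lv, geom)),
            "f", lv, "p1")
        expect_equal(gaSeries(fast[[lv]]), gaSeries(slow))
        expect_equal(fast[[lv]]@n_images, slow@n_images)
    }
})
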