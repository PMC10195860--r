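test_that("feature fields are reproducible and calibrated when unsmoothed", {
    f1 <- genFeatureField(50, 40, 5, seed = 3)
    f2 <- genFeatureField(50, 40, 5, seed = 3)
    expect_identical(intensity(f1), intensity(f2))
    expect_false(identical(intensity(f1),
                           intensity(genFeatureField(50, 40, 5, seed = 4))))
    expect_true(all(intensity(f1) >= 0 & intensity(f1) <= 1))
    # white noise occupies all ten levels at about 10% each
    share <- levelOccupancy(discretizeLevels(
        genFeatureField(200, 150, 0, seed = 6))) / 30000
    expect_true(all(abs(share - 0.1) < 0.02))
    # an extremely smooth field degenerates to a constant, hence zeros
    expect_warning(
        f3 <- genFeatureField(16, 16, 1000, seed = 1), "constant")
    expect_true(all(intensity(f3) == 0))
})

test_that("scanpath simulation is seed-reproducible and respects the bias gain", {
    geom <- ViewingGeometry(width_px = 100, height_px = 100,
                            width_deg = 20, height_deg = 20)
    fm <- blobFeatureMap()
    dm <- discretizeLevels(fm)
    cfg0 <- simConfig(n_participants = 1, n_stimuli = 1, geometry = geom,
                      feature_names = "f", bias_weights = c(f = 0),
                      temporal_amplitude = 0, anticipatory_rate = 0)
    a <- simulateScanpath(list(f = fm), cfg0, trial_seed = 5)
    b <- simulateScanpath(list(f = fm), cfg0, trial_seed = 5)
    expect_identical(fixations(a), fixations(b))

    # strong gain on a single blob: most fixations land in the level-10 disk
    cfgB <- simConfig(n_participants = 1, n_stimuli = 1, geometry = geom,
                      feature_names = "f", bias_weights = c(f = 40),
                      temporal_amplitude = 0, anticipatory_rate = 0)
    hits <- total <- 0
    for (sd in 1:10) {
        fx <- fixations(simulateScanpath(list(f = fm), cfgB, sd))
        lv <- levelGrid(dm)[cbind(fx$y_px + 1, fx$x_px + 1)]
        hits <- hits + sum(lv == 10L); total <- total + length(lv)
    }
    expect_gte(hits / total, 0.9)

    # unbiased sampling: per-level GA near 1 on average (conservation)
    fmn <- genFeatureField(100, 100, 10, seed = 5, feature_name = "f")
    trials <- lapply(1:60, function(sd)
        filterAnticipatory(simulateScanpath(list(f = fmn), cfg0, sd,
                                            stimulus_id = "s1")))
    tcs <- participantTimeCourses(trials, list(s1 = discretizeLevels(fmn)),
                                  geom)
    occ <- levelOccupancy(discretizeLevels(fmn))
    sp <- vapply(tcs, spatialGazeBias, numeric(1L))
    support <- mean(Reduce(`+`, lapply(trials, function(tr) {
        v <- numeric(5000)
        fx <- fixations(tr)
        for (k in seq_len(nrow(fx)))
            v[GazeBias:::.gridInterval(fx$onset_ms[k],
                min(fx$offset_ms[k], 5000), 1, 5000L)] <- 1
        v
    })) / length(trials))
    # occupancy-weighted mean GA equals 1 exactly, so the weighted
    # spatial biases must recover the mean fixation support
    expect_equal(sum(sp * occ / sum(occ)), support, tolerance = 1e-8)
})

test_that("fixation timing follows the latency, duration and gap models", {
    geom <- ViewingGeometry(width_px = 80, height_px = 80,
                            width_deg = 16, height_deg = 16)
    cfg <- simConfig(n_participants = 1, n_stimuli = 1, geometry = geom,
                     feature_names = "f", bias_weights = c(f = 0),
                     temporal_amplitude = 0, anticipatory_rate = 0)
    fm <- genFeatureField(80, 80, 8, seed = 2, feature_name = "f")
    firsts <- c(); durs <- c()
    for (sd in 1:60) {
        fx <- fixations(simulateScanpath(list(f = fm), cfg, sd))
        firsts <- c(firsts, fx$onset_ms[1L])
        durs <- c(durs, fx$offset_ms - fx$onset_ms)
        expect_true(all(diff(fx$onset_ms) > 0))
        gaps <- fx$onset_ms[-1L] - fx$offset_ms[-nrow(fx)]
        expect_true(all(abs(gaps - 30) < 1e-9))
        expect_true(all(fx$offset_ms <= 5000))
    }
    expect_lt(abs(mean(firsts) - 270), 20)       # latency model: N(270, 40)
    expect_lt(abs(mean(durs) - 250), 25)         # gamma mean 250 ms
})

test_that("cohort generation is deterministic with a per-trial seed ladder", {
    geom <- ViewingGeometry(width_px = 60, height_px = 45,
                            width_deg = 20, height_deg = 15)
    cfg <- simConfig(n_participants = 2, n_stimuli = 3, geometry = geom,
                     master_seed = 42)
    coh1 <- genCohort(cfg)
    coh2 <- genCohort(cfg)
    expect_length(coh1$trials, 6L)
    expect_identical(lapply(coh1$trials, fixations),
                     lapply(coh2$trials, fixations))
    expect_identical(intensity(coh1$feature_maps$s001$feature2),
                     intensity(coh2$feature_maps$s001$feature2))
    # adding participants leaves earlier participants' trials unchanged
    cfg3 <- simConfig(n_participants = 3, n_stimuli = 3, geometry = geom,
                      master_seed = 42)
    coh3 <- genCohort(cfg3)
    expect_identical(fixations(coh3$trials[[4L]]),
                     fixations(coh1$trials[[4L]]))
    # ground-truth sidecar round-trips through CSV
    dir <- withr::local_tempdir()
    writeCohort(coh1, dir)
    truth <- read.csv(file.path(dir, "truth.csv"))
    expect_equal(truth$beta, unname(cfg@bias_weights))
    trials_back <- readFixations(file.path(dir, "fixations.csv"), geom)
    expect_length(trials_back, 6L)
})

test_that("an anticipatory rate of one injects an early fixation in every trial", {
    geom <- ViewingGeometry(width_px = 60, height_px = 60,
                            width_deg = 12, height_deg = 12)
    cfg <- simConfig(n_participants = 1, n_stimuli = 1, geometry = geom,
                     feature_names = "f", bias_weights = c(f = 0),
                     anticipatory_rate = 1)
    fm <- genFeatureField(60, 60, 6, seed = 4, feature_name = "f")
    for (sd in 1:10) {
        fx <- fixations(simulateScanpath(list(f = fm), cfg, sd))
        expect_true(any(fx$onset_ms < 80))
    }
})

test_that("hypothetical courses validate the temporal-bias index", {
    expect_equal(temporalGazeBias(
        hypotheticalGATimeCourse(1, 0, 500, 200, onset_delay_ms = 0)), 0.5)
    tb_peak <- vapply(seq(500, 4500, length.out = 10), function(tp)
        temporalGazeBias(hypotheticalGATimeCourse(1, 2, tp, 200)),
        numeric(1L))
    expect_true(all(diff(tb_peak) < 0))
    tb_amp <- vapply(seq(0.2, 3, length.out = 10), function(A)
        temporalGazeBias(hypotheticalGATimeCourse(1, A, 500, 200)),
        numeric(1L))
    expect_true(all(diff(tb_amp) > 0))
    expect_error(hypotheticalGATimeCourse(1, 2, 500, 0), "s must be > 0")
})

test_that("cohort-level bias recovery is monotone in the generating gain", {
    geom <- ViewingGeometry(width_px = 100, height_px = 75,
                            width_deg = 20, height_deg = 15)
    cfg <- simConfig(n_participants = 4, n_stimuli = 6, geometry = geom,
                     temporal_amplitude = 0, anticipatory_rate = 0,
                     master_seed = 7)
    coh <- genCohort(cfg)
    trials <- lapply(coh$trials, filterAnticipatory)
    pids <- unique(vapply(trials, participantId, character(1L)))
    mean_bias <- vapply(cfg@feature_names, function(f) {
        per <- vapply(pids, function(p) {
            ptr <- Filter(function(tr) participantId(tr) == p, trials)
            tcs <- participantTimeCourses(ptr, lapply(coh$dmaps, `[[`, f),
                                          geom)
            mean(vapply(tcs[8:10], spatialGazeBias, numeric(1L)))
        }, numeric(1L))
        mean(per)
    }, numeric(1L))
    expect_identical(order(mean_bias), order(cfg@bias_weights))
})

test_that("the fixture network is reproducible and silent on zero input", {
    e1 <- tinyConvnetFixture(3)
    e2 <- tinyConvnetFixture(3)
    img <- array(runif(6 * 6 * 3), dim = c(6, 6, 3))
    expect_identical(e1@forward(img), e2@forward(img))
    z <- array(0, dim = c(6, 6, 3))
    expect_equal(sum(e1@forward(z)$conv2), 0)
    expect_true(all(e1@gradientSum(z, "conv2") == 0))
})
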