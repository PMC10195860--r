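test_that("pixels-per-degree conversion averages the two axes and flags mismatch", {
    expect_equal(pxPerDeg(ViewingGeometry()), 40)
    expect_equal(pxPerDeg(toyGeometry(100, 100, 10, 10)), 10)
    expect_warning(
        g <- ViewingGeometry(width_px = 400, height_px = 500,
                             width_deg = 10, height_deg = 10),
        "px/deg")
    expect_warning(expect_equal(pxPerDeg(g), 45), "px/deg")
    expect_error(ViewingGeometry(width_px = -1), "> 0")
})

test_that("loadTrials groups rows into sorted trials and drops bad rows", {
    geom <- toyGeometry(100, 100, 10, 10)
    tab <- data.frame(participant = "p1", stimulus = "s1",
                      x_px = c(30, 10, 20), y_px = c(5, 5, 5),
                      onset_ms = c(900, 100, 400),
                      offset_ms = c(1200, 350, 800))
    trials <- loadTrials(tab, geom)
    expect_length(trials, 1L)
    fx <- fixations(trials[[1L]])
    expect_equal(fx$onset_ms, c(100, 400, 900))
    expect_equal(fx$x_px, c(10, 20, 30))
    expect_equal(fx$order, 1:3)

    oob <- rbind(tab, data.frame(participant = "p1", stimulus = "s1",
                                 x_px = -5, y_px = 5, onset_ms = 2000,
                                 offset_ms = 2100))
    expect_message(tr2 <- loadTrials(oob, geom), "dropped 1")
    expect_equal(nrow(fixations(tr2[[1L]])), 3L)

    expect_identical(loadTrials(tab[0, ], geom), list())
    expect_error(loadTrials(tab[, -1], geom), "participant")
    bad <- tab; bad$offset_ms[1] <- bad$onset_ms[1]
    expect_warning(tr3 <- loadTrials(bad, geom), "offset_ms <= onset_ms")
    expect_equal(nrow(fixations(tr3[[1L]])), 2L)
})

test_that("fixations straddling the trial end are truncated", {
    geom <- toyGeometry(100, 100, 10, 10, trial_ms = 5000)
    tr <- makeTrial(10, 10, 4800, 5400, geom)
    expect_equal(fixations(tr)$offset_ms, 5000)
})

test_that("trial records round-trip through the fixation CSV", {
    geom <- toyGeometry(100, 100, 10, 10)
    set.seed(4)
    tab <- data.frame(
        participant = rep(c("p1", "p2"), each = 4),
        stimulus = rep(rep(c("s1", "s2"), each = 2), times = 2),
        x_px = runif(8, 0, 99), y_px = runif(8, 0, 99),
        onset_ms = rep(c(100, 600), 4),
        offset_ms = rep(c(400, 900), 4))
    trials <- loadTrials(tab, geom)
    path <- withr::local_tempfile(fileext = ".csv")
    writeFixations(trials, path)
    back <- readFixations(path, geom)
    key <- function(ts) vapply(ts, function(t)
        paste(participantId(t), stimulusId(t)), character(1L))
    back <- back[match(key(trials), key(back))]
    for (i in seq_along(trials))
        expect_equal(fixations(back[[i]]), fixations(trials[[i]]))
})

test_that("anticipatory filtering uses a strict 80 ms cut and renumbers orders", {
    geom <- toyGeometry(100, 100, 10, 10)
    tr <- makeTrial(c(10, 20, 30), c(10, 20, 30), c(50, 90, 300),
                    c(70, 200, 500), geom)
    out <- filterAnticipatory(tr)
    expect_equal(fixations(out)$onset_ms, c(90, 300))
    expect_equal(fixations(out)$order, 1:2)

    # boundary onset exactly at the threshold is kept
    tr2 <- makeTrial(c(10, 20), c(10, 20), c(80, 100), c(95, 200), geom)
    expect_equal(nrow(fixations(filterAnticipatory(tr2))), 2L)

    # all-anticipatory trial is retained with an empty fixation list
    tr3 <- makeTrial(c(10, 20), c(10, 20), c(10, 30), c(25, 60), geom)
    expect_equal(nrow(fixations(filterAnticipatory(tr3))), 0L)

    expect_error(filterAnticipatory(tr, -1), ">= 0")
})

test_that("anticipatory filtering is idempotent", {
    geom <- toyGeometry(100, 100, 10, 10)
    set.seed(11)
    for (i in 1:5) {
        on <- sort(runif(6, 0, 4000))
        off <- on + runif(6, 10, 200)
        off <- pmin(off, c(on[-1L], 5000))
        keep <- off > on
        tr <- makeTrial(runif(sum(keep), 0, 99), runif(sum(keep), 0, 99),
                        on[keep], off[keep], geom)
        once <- filterAnticipatory(tr)
        expect_equal(fixations(filterAnticipatory(once)), fixations(once))
    }
})

test_that("fixation disk mask matches a brute-force distance check", {
    geom <- toyGeometry()  # 10 x 10 px, 2 px per degree
    bruteCount <- function(x, y, r) {
        n <- 0L
        for (px in 0:9) for (py in 0:9)
            if ((px - x)^2 + (py - y)^2 <= r^2) n <- n + 1L
        n
    }
    # radius 1 deg = 2 px
    expect_equal(sum(fixationDiskMask(5, 5, geom)), bruteCount(5, 5, 2))
    expect_equal(sum(fixationDiskMask(5, 5, geom)), 13L)
    expect_equal(sum(fixationDiskMask(0, 0, geom)), bruteCount(0, 0, 2))
    expect_equal(sum(fixationDiskMask(0, 0, geom)), 6L)
    set.seed(2)
    for (i in 1:10) {
        x <- runif(1, 0, 9); y <- runif(1, 0, 9); r <- runif(1, 0.5, 3)
        expect_equal(sum(fixationDiskMask(x, y, geom, radius_deg = r / 2)),
                     bruteCount(x, y, r))
    }
    # radius covering the whole image
    expect_true(all(fixationDiskMask(5, 5, geom, radius_deg = 10)))
    expect_error(fixationDiskMask(12, 5, geom), "outside")
})

test_that("disk pixel count grows with radius and is translation invariant inside", {
    geom <- toyGeometry(40, 40, 20, 20)  # 2 px/deg
    counts <- vapply(seq(0.5, 5, by = 0.5), function(r)
        sum(fixationDiskMask(20, 20, geom, radius_deg = r)), numeric(1L))
    expect_true(all(diff(counts) >= 0))
    r_px <- 2  # 1 deg
    ref <- sum(fixationDiskMask(20, 20, geom))
    for (p in list(c(5, 5), c(10, 30), c(33, 17)))
        expect_equal(sum(fixationDiskMask(p[1L], p[2L], geom)), ref)
})
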