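test_that("preprocessing removes background and rejects bad input", {
    pr <- segmentationParams(rollingBallRadius = 10, smoothSigma = 1)
    ## constant frame -> all zero after background subtraction
    out <- preprocessFrame(matrix(0.7, 48, 48), pr)
    expect_lt(max(abs(out)), 1e-12)
    ## non-finite pixels are refused
    bad <- matrix(0, 8, 8); bad[3, 3] <- NA
    expect_error(preprocessFrame(bad, pr), "finite")
})

test_that("rolling-ball background equals brute-force grayscale opening", {
    set.seed(42)
    m <- matrix(runif(24 * 24), 24, 24)
    ## flat-disc limit (the default) and a curved ball, both vs brute force
    expect_equal(StromaQuant:::.rollingBallBackground(m, 5),
                 pmin(oracleGrayOpen(m, 5), m), tolerance = 1e-12)
    expect_equal(StromaQuant:::.grayOpen(m, 5, zScale = 0.1),
                 oracleGrayOpen(m, 5, zScale = 0.1), tolerance = 1e-12)
})

test_that("a blob on a linear ramp survives with its peak in place", {
    nr <- 96
    ramp <- matrix(rep(seq(0, 0.3, length.out = nr), each = nr), nr)
    fr <- ramp + blobFrame(nr, nr, list(list(cx = 48, cy = 48, s = 3,
                                             amp = 1)))
    pr <- segmentationParams(rollingBallRadius = 15, smoothSigma = 1)
    out <- preprocessFrame(fr, pr)
    peak <- arrayInd(which.max(out), dim(out))
    expect_lte(max(abs(peak - c(48, 48))), 1)
    ## ramp gradient removed: corners sit near a common level
    ## compare interior reference points (at least one ball radius from
    ## the frame edge, away from the blob)
    corners <- c(out[20, 20], out[20, 77], out[77, 20], out[77, 77])
    expect_lt(diff(range(corners)), 0.02)
})

test_that("Gaussian smoothing conserves total intensity", {
    fr <- matrix(0, 32, 32); fr[16, 16] <- 1
    sm <- StromaQuant:::.gaussSmooth(fr, 2)
    expect_equal(sum(sm), sum(fr), tolerance = 1e-6)
})

test_that("seed detection finds separated maxima and thins close ones", {
    pr <- segmentationParams(minSeedDistance = 20)
    expect_identical(nrow(detectSeeds(matrix(0, 64, 64), pr,
                                      threshold = 0.1)), 0L)
    ## two blobs 50 px apart -> 2 seeds at the blob centres (+- 1 px)
    fr <- blobFrame(64, 110, list(list(cx = 30, cy = 32, s = 4, amp = 1),
                                  list(cx = 80, cy = 32, s = 4, amp = 0.9)))
    s <- detectSeeds(fr, pr, threshold = 0.2)
    expect_identical(nrow(s), 2L)
    s <- s[order(s$col), ]
    expect_lte(max(abs(s$col - c(30, 80))), 1)
    expect_lte(max(abs(s$row - 32)), 1)
    ## two maxima 5 px apart with min distance 20 -> a single seed
    fr2 <- blobFrame(64, 64, list(list(cx = 30, cy = 32, s = 3, amp = 1),
                                  list(cx = 35, cy = 32, s = 3, amp = 0.95)))
    expect_identical(nrow(detectSeeds(fr2, pr, threshold = 0.2)), 1L)
})

test_that("seed consolidation merges plateau seeds, keeps distinct cells", {
    pr <- segmentationParams(minSeedDistance = 5, consolidationDelta = 0.1)
    one <- data.frame(row = 10L, col = 10L, intensity = 1)
    fr0 <- matrix(1, 24, 24)
    expect_identical(consolidateSeeds(one, fr0, pr), one)
    ## flat-topped cell: dip between the two maxima below delta -> 1 seed
    fr <- blobFrame(48, 96, list(list(cx = 34, cy = 24, s = 8, amp = 1),
                                 list(cx = 52, cy = 24, s = 8, amp = 0.97)))
    s <- detectSeeds(fr, segmentationParams(minSeedDistance = 5),
                     threshold = 0.2)
    expect_gte(nrow(s), 2L)
    dip <- min(s$intensity[1:2]) -
        min(fr[24, 34:52])  # brute-force min along the connecting line
    expect_lt(dip, 0.1)
    expect_identical(nrow(consolidateSeeds(s, fr, pr)), 1L)
    ## distinct cells separated by background: dip >> delta -> both kept
    fr2 <- blobFrame(48, 110, list(list(cx = 30, cy = 24, s = 5, amp = 1),
                                   list(cx = 80, cy = 24, s = 5, amp = 0.9)))
    s2 <- detectSeeds(fr2, segmentationParams(minSeedDistance = 5),
                      threshold = 0.2)
    expect_identical(nrow(consolidateSeeds(s2, fr2, pr)), 2L)
})

test_that("seeded watershed matches the ascent-flood oracle", {
    pr <- segmentationParams(minSeedDistance = 5,
                             consolidationDelta = 0.05, threshold = 0.1)
    fr <- blobFrame(64, 64, list(list(cx = 24, cy = 32, s = 5, amp = 1),
                                 list(cx = 42, cy = 32, s = 5, amp = 0.8)))
    seeds <- consolidateSeeds(detectSeeds(fr, pr, threshold = 0.1), fr, pr)
    expect_identical(nrow(seeds), 2L)
    lab <- segmentCells(fr, seeds, pr, threshold = 0.1)
    expect_identical(max(lab), 2L)
    mask <- fr >= 0.1
    oracle <- oracleAscentFlood(fr, seeds, mask)
    expect_gte(mean(lab[mask] == oracle[mask]), 0.95)
    ## touching blobs: each label close to an isolated blob's area
    iso <- blobFrame(64, 64, list(list(cx = 32, cy = 32, s = 5, amp = 1)))
    isoArea <- sum(iso >= 0.1)
    areas <- tabulate(lab[lab > 0L])
    expect_lt(abs(areas[1L] / isoArea - 1), 0.10)
    ## no seeds -> empty labelling
    lab0 <- segmentCells(fr, seeds[0, ], pr, threshold = 0.1)
    expect_true(all(lab0 == 0L))
    ## label conservation: one label per surviving seed
    expect_identical(max(lab), nrow(attr(lab, "seeds")))
})

test_that("an ellipse thresholded at half-max recovers its analytic area", {
    ps <- 0.25
    fr <- ellipseFrame(400, 640, cxUm = 80, cyUm = 50, aUm = 30, bUm = 10,
                       theta = 0.4, pixelSize = ps)
    pr <- segmentationParams(rollingBallRadius = 60, smoothSigma = 1)
    pp <- preprocessFrame(fr, pr)
    seeds <- data.frame(row = 200L, col = 320L,
                        intensity = pp[200L, 320L])
    lab <- segmentCells(pp, seeds, pr, threshold = 0.5 * max(pp))
    areaPx <- sum(lab == 1L)
    expect_lt(abs(areaPx * ps^2 / (pi * 30 * 10) - 1), 0.05)
    ## measured morphometry: aspect 3.0 +- 2%, area pi*a*b +- 2% is checked
    ## on the same segmented ellipse
    cells <- measureCells(lab, pp, pixelSize = ps, wavelength = 0.6,
                          params = pr)
    expect_lt(abs(cells$aspect_ratio - 3) / 3, 0.02)
    expect_lt(abs(cells$area_um2 - pi * 300) / (pi * 300), 0.05)
})

test_that("morphometry of a disc is isotropic", {
    ps <- 0.5
    fr <- ellipseFrame(160, 160, 40, 40, 15, 15, 0, ps)
    pr <- segmentationParams(rollingBallRadius = 60, smoothSigma = 2)
    pp <- preprocessFrame(fr, pr)
    lab <- (pp >= 0.5 * max(pp)) * 1L
    cells <- measureCells(lab, pp, pixelSize = ps, params = pr)
    expect_lt(abs(cells$aspect_ratio - 1), 0.02)
})

test_that("dry mass follows the closed-form phase integral", {
    ## uniform phase 1 rad over 1000 um^2, lambda 0.6 um, alpha 0.2 um^3/pg
    ps <- 1
    fr <- matrix(0, 60, 60)
    fr[11:50, 16:40] <- 1   # 40 x 25 px = 1000 um^2
    lab <- matrix(0L, 60, 60); lab[fr > 0] <- 1L
    pr <- segmentationParams(dryMassAlpha = 0.2)
    cells <- measureCells(lab, fr, pixelSize = ps, wavelength = 0.6,
                          params = pr)
    expect_equal(cells$dry_mass_pg, 0.6 * 1000 / (2 * pi * 0.2),
                 tolerance = 1e-9)
    ## linearity: scaling phase by c scales dry mass by c exactly
    cells2 <- measureCells(lab, 2.5 * fr, pixelSize = ps, wavelength = 0.6,
                           params = pr)
    expect_equal(cells2$dry_mass_pg, 2.5 * cells$dry_mass_pg,
                 tolerance = 1e-12)
})

test_that("tiny labels are skipped with a warning", {
    fr <- matrix(1, 10, 10)
    lab <- matrix(0L, 10, 10); lab[1, 1:3] <- 1L; lab[5:8, 5:8] <- 2L
    expect_warning(cells <- measureCells(lab, fr, pixelSize = 1),
                   "fewer than 4")
    expect_identical(cells$label, 2L)
})

test_that("physical measurements are pixel-size equivariant", {
    ## the smoothing kernel is held at the same physical width (1 um) so
    ## the preprocessed images are comparable across pixel sizes
    run <- function(nr, nc, ps) {
        pr <- segmentationParams(rollingBallRadius = 60 * 0.5 / ps,
                                 smoothSigma = 1 / ps)
        fr <- ellipseFrame(nr, nc, 60, 40, 24, 8, 0.9, ps)
        pp <- preprocessFrame(fr, pr)
        lab <- (pp >= 0.5 * max(pp)) * 1L
        measureCells(lab, pp, pixelSize = ps, params = pr)
    }
    fine <- run(160, 240, 0.5)
    coarse <- run(80, 120, 1.0)
    expect_lt(abs(coarse$n_px / fine$n_px - 0.25), 0.02)
    for (f in c("area_um2", "length_um", "width_um", "aspect_ratio"))
        expect_lt(abs(coarse[[f]] / fine[[f]] - 1), 0.03)
})

test_that("the full stack pipeline recovers two morphometric populations", {
    pops <- list(
        populationSpec(5L, 3.59, 0.36, meanArea = 2500, sdArea = 375,
                       meanDryMass = 400, sdDryMass = 60,
                       label = "spindle"),
        populationSpec(5L, 2.016, 0.20, meanArea = 4000, sdArea = 600,
                       meanDryMass = 480, sdDryMass = 70, label = "flat"))
    pr <- segmentationParams(rollingBallRadius = 60)
    ars <- list(spindle = c(), flat = c())
    for (s in 1:4) {
        tl <- generateTimelapse(timelapseSpec(pops, duration = 0,
                                              fieldSize = c(560L, 560L),
                                              pixelSize = 1.4,
                                              seed = 300L + s))
        cells <- suppressMessages(segmentStack(tl$stack, pr))
        tr <- tl$truth$tracks
        for (i in seq_len(nrow(cells))) {
            d <- sqrt((tr$x_um - cells$x_um[i])^2 +
                      (tr$y_um - cells$y_um[i])^2)
            if (min(d) < 20)
                ars[[tr$population[which.min(d)]]] <-
                    c(ars[[tr$population[which.min(d)]]],
                      cells$aspect_ratio[i])
        }
    }
    expect_gte(length(ars$spindle), 15L)
    expect_gte(length(ars$flat), 15L)
    expect_lt(abs(mean(ars$spindle) / 3.59 - 1), 0.05)
    expect_lt(abs(mean(ars$flat) / 2.016 - 1), 0.05)
    ## the two populations differ sharply
    expect_lt(t.test(ars$spindle, ars$flat)$p.value, 0.001)
})
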