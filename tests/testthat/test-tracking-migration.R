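## Build a detection table from straight-line motion specs.
linearDetections <- function(paths, nframes, interval = 24) {
    do.call(rbind, lapply(seq_along(paths), function(i) {
        p <- paths[[i]]
        n <- if (is.null(p$frames)) nframes else p$frames
        data.frame(frame = seq_len(n), t_min = (seq_len(n) - 1) * interval,
                   x_um = p$x0 + (seq_len(n) - 1) * p$vx,
                   y_um = p$y0 + (seq_len(n) - 1) * p$vy,
                   truth = i)
    }))
}

test_that("linking follows cells across frames", {
    g <- gateParams(maxLinkDistance = 10)
    one <- linearDetections(list(list(x0 = 5, y0 = 5, vx = 0, vy = 0)), 30)
    lt <- linkTracks(one, g)
    expect_identical(length(unique(lt$track_id)), 1L)
    expect_identical(nrow(lt), 30L)
    ## two non-crossing linear paths reproduce the ground truth exactly
    two <- linearDetections(list(list(x0 = 0, y0 = 0, vx = 2, vy = 0),
                                 list(x0 = 100, y0 = 100, vx = 0, vy = 2)),
                            25)
    lt2 <- linkTracks(two[sample.int(nrow(two)), ], g)
    expect_identical(length(unique(lt2$track_id)), 2L)
    expect_true(all(tapply(lt2$truth, lt2$track_id,
                           function(v) length(unique(v))) == 1L))
    ## a cell vanishing at frame 10 of 30 leaves a 10-frame track
    mix <- linearDetections(list(list(x0 = 0, y0 = 0, vx = 1, vy = 0,
                                      frames = 10),
                                 list(x0 = 200, y0 = 0, vx = 1, vy = 0,
                                      frames = 30)), 30)
    lt3 <- linkTracks(mix, g)
    expect_setequal(as.integer(table(lt3$track_id)), c(10L, 30L))
    ## empty input stays empty
    expect_identical(nrow(linkTracks(one[0, ], g)), 0L)
})

test_that("exclusion gates remove debris and short tracks with an audit", {
    g <- gateParams()
    obj <- data.frame(
        dry_mass_pg = c(200, 200, 400, 400, 500),
        area_um2 = c(900, 2000, 900, 26000, 2000))
    res <- applyGates(obj, g)
    ## OR-combination: below either floor is removed; ceiling always
    expect_identical(nrow(res$kept), 1L)
    expect_identical(res$kept$dry_mass_pg, 500)
    expect_identical(nrow(res$audit), 4L)
    expect_identical(nrow(res$kept) + nrow(res$audit), nrow(obj))
    ## the stricter AND variant only removes joint failures
    resAnd <- applyGates(obj, gateParams(combine = "and"))
    expect_identical(nrow(resAnd$kept), 3L)
    ## idempotence
    res2 <- applyGates(res$kept, g)
    expect_identical(res2$kept, res$kept)
    expect_identical(nrow(res2$audit), 0L)
})

test_that("tracks below the minimum frame count are gated", {
    g <- gateParams(minFrames = 20L)
    tr <- data.frame(
        track_id = rep(1:2, c(19L, 20L)),
        dry_mass_pg = 400, area_um2 = 2000)
    res <- applyGates(tr, g)
    expect_setequal(unique(res$kept$track_id), 2L)
    expect_true(all(res$audit$reason == "track below minimum frame count"))
    expect_identical(nrow(res$audit), 19L)
})

test_that("migration metrics follow their definitions", {
    still <- data.frame(track_id = 1, t_min = c(0, 24, 48),
                        x_um = 5, y_um = 5)
    m <- migrationMetrics(still)
    expect_identical(m$mean_speed_um_per_h, 0)
    expect_identical(m$displacement_um, 0)
    ## straight path: 1 um per 24-min frame, 21 frames -> 20 um in 8 h
    straight <- data.frame(track_id = 1, t_min = (0:20) * 24,
                           x_um = 0:20, y_um = 0)
    m2 <- migrationMetrics(straight)
    expect_equal(m2$mean_speed_um_per_h, 2.5)
    expect_equal(m2$displacement_um, 20)
    expect_equal(m2$path_length_um, 20)
    ## closed square: displacement 0, speed = perimeter / elapsed
    sq <- data.frame(track_id = 1, t_min = (0:4) * 15,
                     x_um = c(0, 10, 10, 0, 0), y_um = c(0, 0, 10, 10, 0))
    m3 <- migrationMetrics(sq)
    expect_equal(m3$displacement_um, 0)
    expect_equal(m3$mean_speed_um_per_h, 40 / 1)
    expect_true(all(m3$displacement_um <= m3$path_length_um))
    expect_error(migrationMetrics(still[1L, ]), "at least 2")
})

test_that("rose export is origin-centred and translation invariant", {
    tr <- data.frame(track_id = c(1, 1, 2, 2), t_min = c(0, 24, 0, 24),
                     x_um = c(100, 110, 7, 3), y_um = c(50, 45, 8, 20))
    r <- roseData(tr)
    expect_identical(r$x_um[r$t_min == 0], c(0, 0))
    expect_identical(r$y_um[r$t_min == 0], c(0, 0))
    shifted <- transform(tr, x_um = x_um + 31.7, y_um = y_um - 12)
    expect_identical(roseData(shifted), r)
})

test_that("an isotropic PRW ensemble is directionally unbiased", {
    sp <- timelapseSpec(populationSpec(200L, 3, meanArea = 2000,
                                       meanSpeed = 15,
                                       persistenceTime = 60),
                        duration = 24, frameInterval = 24,
                        fieldSize = c(6000L, 6000L), pixelSize = 1.4,
                        seed = 17L)
    tl <- generateTimelapse(sp, render = FALSE)
    tr <- tl$truth$tracks
    tr$track_id <- tr$cell
    rose <- roseData(tr)
    fin <- rose[rose$t_min == max(rose$t_min), ]
    for (v in list(fin$x_um, fin$y_um))
        expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))
})

test_that("ensemble speed recovers the generator value and order", {
    pops <- list(populationSpec(40L, 3, meanArea = 2000, meanSpeed = 20,
                                persistenceTime = 60, label = "fast"),
                 populationSpec(40L, 2, meanArea = 3000, meanSpeed = 10,
                                persistenceTime = 60, label = "slow"))
    sp <- timelapseSpec(pops, duration = 48, frameInterval = 24,
                        fieldSize = c(6000L, 6000L), pixelSize = 1.4,
                        seed = 23L)
    tl <- generateTimelapse(sp, render = FALSE)
    tr <- tl$truth$tracks
    tr$track_id <- tr$cell
    mm <- migrationMetrics(tr)
    pop <- tl$truth$cells$label[match(mm$track_id, tl$truth$cells$cell)]
    expect_lt(abs(mean(mm$mean_speed_um_per_h[pop == "fast"]) / 20 - 1),
              0.1)
    expect_lt(abs(mean(mm$mean_speed_um_per_h[pop == "slow"]) / 10 - 1),
              0.1)
    expect_gt(median(mm$mean_speed_um_per_h[pop == "fast"]),
              median(mm$mean_speed_um_per_h[pop == "slow"]))
})
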