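test_that("frame count follows duration and interval", {
    sp <- timelapseSpec(populationSpec(1L, 3), duration = 96,
                        frameInterval = 24, fieldSize = c(256L, 256L),
                        seed = 1L)
    tl <- generateTimelapse(sp, render = FALSE)
    expect_identical(max(tl$truth$tracks$frame),
                     as.integer(floor(96 * 60 / 24) + 1))   # 241
    sp0 <- timelapseSpec(populationSpec(1L, 3, meanArea = 500),
                         duration = 0, fieldSize = c(96L, 96L), seed = 1L)
    expect_identical(nFrames(generateTimelapse(sp0)$stack), 1L)
})

test_that("zero cells give pure background and empty truth", {
    sp <- timelapseSpec(list(), duration = 0, fieldSize = c(128L, 128L),
                        backgroundRampAmplitude = 0.1, noiseSd = 0.02,
                        seed = 3L)
    tl <- generateTimelapse(sp)
    expect_identical(nrow(tl$truth$tracks), 0L)
    expect_identical(nrow(tl$truth$cells), 0L)
    expect_lt(max(getFrame(tl$stack, 1)), 0.1 + 6 * 0.02)
})

test_that("ground-truth aspect ratios match the population parameters", {
    pops <- list(populationSpec(200L, 3.59, 0.072, label = "p1"),
                 populationSpec(200L, 2.016, 0.051, label = "p2"))
    tl <- generateTimelapse(timelapseSpec(pops, duration = 0,
                                          fieldSize = c(4000L, 4000L),
                                          pixelSize = 1.4, seed = 9L),
                            render = FALSE)
    cells <- tl$truth$cells
    for (p in list(c("p1", 3.59), c("p2", 2.016))) {
        x <- cells$aspect_ratio[cells$label == p[1L]]
        se <- sd(x) / sqrt(length(x))
        expect_lt(abs(mean(x) - as.numeric(p[2L])), 2 * se + 1e-9)
    }
})

test_that("generation is deterministic and conserves cell counts", {
    sp <- timelapseSpec(populationSpec(3L, 2.5, 0.2, meanArea = 1800),
                        duration = 1, frameInterval = 20,
                        fieldSize = c(256L, 256L), seed = 21L)
    a <- generateTimelapse(sp); b <- generateTimelapse(sp)
    expect_identical(a$truth, b$truth)
    expect_identical(a$stack@frames, b$stack@frames)
    expect_identical(length(unique(a$truth$tracks$cell)), 3L)
})

test_that("rendered phase encodes dry mass within 2%", {
    sp <- timelapseSpec(populationSpec(1L, 3, meanArea = 2000,
                                       meanDryMass = 400),
                        duration = 0, fieldSize = c(300L, 300L),
                        pixelSize = 1.4, backgroundRampAmplitude = 0,
                        noiseSd = 0, wavelength = 0.55, seed = 5L)
    tl <- generateTimelapse(sp)
    phi <- sum(getFrame(tl$stack, 1)) * 1.4^2
    mass <- 0.55 / (2 * pi * 0.2) * phi
    expect_lt(abs(mass / 400 - 1), 0.02)
})

test_that("an overfull field raises a placement error", {
    sp <- timelapseSpec(populationSpec(30L, 3, meanArea = 2500),
                        duration = 0, fieldSize = c(128L, 128L),
                        pixelSize = 1, seed = 2L)
    expect_error(generateTimelapse(sp, render = FALSE), "field too small")
})

test_that("plate scans carry faithful colony ground truth", {
    plates <- plateSuite()
    for (p in plates) {
        expect_identical(sum(p$truth$objects$is_colony),
                         sum(p$spec@colonyCountPerWell))
        expect_identical(sum(!p$truth$objects$is_colony),
                         p$spec@debrisCount)
        ## debris is below the 60 px detection window
        expect_true(all(2 * p$truth$objects$radius_px[
            !p$truth$objects$is_colony] < 60))
        ## per-object truth area is consistent with its radius
        expect_equal(p$truth$objects$area_px2,
                     pi * p$truth$objects$radius_px^2)
        ## masks labelled per colony
        expect_identical(max(p$truth$masks),
                         max(p$truth$objects$id[p$truth$objects$is_colony]))
    }
})

test_that("plate generation contracts hold", {
    expect_error(generatePlateScan(
        plateScanSpec(colonyDiameterRange = c(100, 1040))),
        "colony diameter")
    empty <- generatePlateScan(plateScanSpec(colonyCountPerWell = 0L,
                                             seed = 12L))
    expect_identical(nrow(empty$truth$objects), 0L)
    ## rims only: blue channel has near-black rim pixels, interior stays
    ## bright
    expect_lt(min(empty$image[, , 3L]), 0.05)
    w <- empty$truth$wells[1L, ]
    expect_gt(empty$image[round(w$cy_px), round(w$cx_px), 1L], 0.8)
    ## determinism
    again <- generatePlateScan(plateScanSpec(colonyCountPerWell = 0L,
                                             seed = 12L))
    expect_identical(empty$image, again$image)
})

test_that("abundance tables plant exact fold changes at zero noise", {
    pe <- data.frame(protein = c("P0001", "P0002", "P0003"),
                     fold = c(71, 104, 9.7),
                     direction = c("Y201", "Y201", "Y202"))
    tab <- generateAbundanceTable(abundanceSpec(nProteins = 50L,
                                                nMatrisome = 10L, cv = 0,
                                                plantedEffects = pe,
                                                seed = 4L))
    m <- SummarizedExperiment::assay(tab$se, "abundance")
    g <- SummarizedExperiment::colData(tab$se)$group
    r <- rowMeans(m[, g == "Y201"]) / rowMeans(m[, g == "Y202"])
    expect_equal(unname(r[c("P0001", "P0002")]), c(71, 104),
                 tolerance = 1e-12)
    expect_equal(unname(1 / r["P0003"]), 9.7, tolerance = 1e-12)
    expect_true(all(abs(r[-(1:3)] - 1) < 1e-12))
    expect_equal(tab$truth$effects$fold_group1[1:3], c(71, 104, 1 / 9.7))
    ## duplicate planted ids are rejected
    bad <- rbind(pe, pe[1L, ])
    expect_error(abundanceSpec(nProteins = 50L, nMatrisome = 5L,
                               plantedEffects = bad), "duplicate")
})

test_that("gene-set collections sample the universe reproducibly", {
    uni <- sprintf("G%03d", 1:600)
    full <- generateGeneSetCollection(1L, c(600L, 600L), uni, seed = 1L)
    expect_setequal(full[[1L]], uni)
    big <- generateGeneSetCollection(2L, c(501L, 501L), uni, seed = 2L)
    expect_true(all(lengths(big) == 501L))
    expect_identical(generateGeneSetCollection(5L, c(3L, 10L), uni,
                                               seed = 3L),
                     generateGeneSetCollection(5L, c(3L, 10L), uni,
                                               seed = 3L))
    expect_error(generateGeneSetCollection(1L, c(601L, 601L), uni,
                                           seed = 1L), "universe")
})
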