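## Per-frame quantitative-phase morphometry: background removal, smoothing,
## seed detection/consolidation, seeded segmentation, per-cell measurement.

#' Preprocess a phase frame
#'
#' Removes the slowly varying background with a rolling-ball estimator
#' (grayscale opening with a ball structuring element; the ball radius must
#' exceed the half-width of the largest cell, otherwise cells are absorbed
#' into the background), then applies normalised Gaussian smoothing to
#' suppress pixel noise before seed detection.
#'
#' @param frame numeric matrix of phase values (rad).
#' @param params a [SegmentationParams-class] object.
#' @return A background-subtracted, smoothed matrix of the same size.
#' @examples
#' fr <- matrix(0.1, 64, 64); fr[30:34, 30:34] <- 1
#' pp <- preprocessFrame(fr, segmentationParams(rollingBallRadius = 10))
#' @export
preprocessFrame <- function(frame, params = segmentationParams()) {
    stopifnot(is.matrix(frame))
    if (!all(is.finite(frame)))
        stop("frame contains non-finite phase values")
    bg <- .rollingBallBackground(frame, params@rollingBallRadius)
    .gaussSmooth(frame - bg, params@smoothSigma)
}

## Resolve the segmentation threshold. "auto" = robust background: the
## histogram mode of the preprocessed frame (background-dominated) plus 6
## robust SDs (1.4826 x MAD). This keeps faint flat/spread cells above
## threshold in fields that also contain bright spindle cells, where a
## global Otsu threshold lands above the faint-cell peak.
.resolveThreshold <- function(frame, params) {
    if (!is.na(params@threshold)) return(params@threshold)
    v <- as.numeric(frame)
    .histMode(v) + 6 * stats::mad(v)
}

## Resolve the consolidation tolerance (auto = 10% of frame maximum).
.resolveDelta <- function(frame, params) {
    if (is.na(params@consolidationDelta)) 0.1 * max(frame)
    else params@consolidationDelta
}

#' Detect seed points in a preprocessed frame
#'
#' Seeds are points of maximal brightness (high phase contrast, typically
#' over the nucleus): local maxima within a disc of radius `minSeedDistance`
#' that exceed the segmentation threshold. Plateau maxima are reduced to one
#' representative, and remaining seeds closer than `minSeedDistance` are
#' thinned greedily, brightest first.
#'
#' @param frame preprocessed phase matrix (see [preprocessFrame()]).
#' @param params a [SegmentationParams-class].
#' @param threshold optional explicit threshold (rad); default resolves
#'   `params@threshold` (robust background when `NA`).
#' @return data.frame with columns `row`, `col` (pixel indices, 1-based) and
#'   `intensity`, ordered by decreasing intensity. Zero rows when no maxima
#'   qualify.
#' @examples
#' fr <- matrix(0, 64, 64); fr[20, 20] <- 1; fr[20, 50] <- 0.8
#' detectSeeds(fr, segmentationParams(minSeedDistance = 8),
#'             threshold = 0.5)
#' @export
detectSeeds <- function(frame, params = segmentationParams(),
                        threshold = NULL) {
    if (is.null(threshold)) threshold <- .resolveThreshold(frame, params)
    elem <- .ballElement(params@minSeedDistance, flat = TRUE)
    mx <- .grayMorph(frame, elem, "dilate")
    idx <- which(frame >= mx & frame >= threshold)
    if (!length(idx))
        return(data.frame(row = integer(), col = integer(),
                          intensity = numeric()))
    rc <- arrayInd(idx, dim(frame))
    seeds <- data.frame(row = rc[, 1L], col = rc[, 2L],
                        intensity = frame[idx])
    seeds <- seeds[order(-seeds$intensity, seeds$row, seeds$col), ]
    ## greedy minimum-distance thinning, brightest first
    keep <- logical(nrow(seeds))
    for (i in seq_len(nrow(seeds))) {
        if (!any(keep)) { keep[i] <- TRUE; next }
        d2 <- (seeds$row[keep] - seeds$row[i])^2 +
              (seeds$col[keep] - seeds$col[i])^2
        if (min(d2) >= params@minSeedDistance^2) keep[i] <- TRUE
    }
    out <- seeds[keep, ]
    rownames(out) <- NULL
    out
}

## Minimum intensity along the straight pixel path between two seeds
## (nearest-pixel sampling at sub-pixel steps).
.pathMinIntensity <- function(frame, r1, c1, r2, c2) {
    n <- max(2L, ceiling(2 * sqrt((r2 - r1)^2 + (c2 - c1)^2)))
    t <- seq(0, 1, length.out = n)
    rr <- pmin(pmax(round(r1 + t * (r2 - r1)), 1L), nrow(frame))
    cc <- pmin(pmax(round(c1 + t * (c2 - c1)), 1L), ncol(frame))
    min(frame[cbind(rr, cc)])
}

#' Consolidate seed points lying on the same cell
#'
#' Two seeds whose connecting intensity profile never dips more than
#' `consolidationDelta` below the dimmer seed sit on one intensity plateau
#' (one cell); only the brighter of the pair is retained. Applied greedily
#' from the brightest seed down, so a cell with several spurious maxima
#' collapses to its brightest point while seeds on distinct cells, separated
#' by background, survive.
#'
#' @param seeds data.frame from [detectSeeds()].
#' @param frame the preprocessed frame the seeds were detected in.
#' @param params a [SegmentationParams-class]; `consolidationDelta = NA`
#'   resolves to 10% of the frame maximum.
#' @return The retained subset of `seeds`, brightest first.
#' @export
consolidateSeeds <- function(seeds, frame, params = segmentationParams()) {
    if (nrow(seeds) <= 1L) return(seeds)
    delta <- .resolveDelta(frame, params)
    seeds <- seeds[order(-seeds$intensity), ]
    keep <- rep(TRUE, nrow(seeds))
    for (i in seq_len(nrow(seeds) - 1L)) {
        if (!keep[i]) next
        for (j in seq.int(i + 1L, nrow(seeds))) {
            if (!keep[j]) next
            dip <- min(seeds$intensity[i], seeds$intensity[j]) -
                .pathMinIntensity(frame, seeds$row[i], seeds$col[i],
                                  seeds$row[j], seeds$col[j])
            if (dip < delta) keep[j] <- FALSE
        }
    }
    out <- seeds[keep, ]
    rownames(out) <- NULL
    out
}

#' Segment cells from consolidated seeds
#'
#' Seeded watershed segmentation: the above-threshold foreground is
#' partitioned among the seeds by ordered flooding from the brightest
#' intensity level downwards, so label boundaries form along intensity
#' valleys between cells. One label per surviving seed. Seeds falling below
#' the threshold yield no region and are reported via a message.
#'
#' @param frame preprocessed phase matrix.
#' @param seeds data.frame from [consolidateSeeds()] (or [detectSeeds()]).
#' @param params a [SegmentationParams-class].
#' @param threshold optional explicit threshold; default as in
#'   [detectSeeds()].
#' @return Integer label matrix; background is 0 and label `i` corresponds to
#'   row `i` of the surviving seed table (attribute `"seeds"`).
#' @export
segmentCells <- function(frame, seeds, params = segmentationParams(),
                         threshold = NULL) {
    if (is.null(threshold)) threshold <- .resolveThreshold(frame, params)
    mask <- frame >= threshold
    lab <- matrix(0L, nrow(frame), ncol(frame))
    if (nrow(seeds)) {
        below <- frame[cbind(seeds$row, seeds$col)] < threshold
        if (any(below))
            message(sum(below), " seed(s) below threshold yield no region")
        seeds <- seeds[!below, , drop = FALSE]
    }
    if (!nrow(seeds)) {
        attr(lab, "seeds") <- seeds
        return(lab)
    }
    seedimg <- matrix(0L, nrow(frame), ncol(frame))
    seedimg[cbind(seeds$row, seeds$col)] <- seq_len(nrow(seeds))
    lab <- .seededWatershed(frame, seedimg, mask)
    attr(lab, "seeds") <- seeds
    lab
}

#' Measure segmented cells
#'
#' Per-label morphometry and dry mass. Area is the pixel count times the
#' pixel area. Length and width are `4 * sigma` along the major and minor
#' axes of the intensity-weighted second-moment ellipse (so a uniform
#' ellipse of semi-axes a >= b yields length `2a` and width `2b`), and the
#' aspect ratio is their quotient. Because `frame` is expected to be the
#' preprocessed (Gaussian-smoothed) image, the smoothing variance
#' `(smoothSigma * pixelSize)^2` is subtracted from the second moments
#' before the axes are formed, removing the blur bias that would otherwise
#' shrink measured aspect ratios. Dry mass applies the standard QPI
#' relation `m = lambda / (2 * pi * alpha) * sum(phi) * pixelArea` with the
#' specific refractive increment `alpha` from `params`.
#'
#' @param labels integer label matrix from [segmentCells()].
#' @param frame the preprocessed phase matrix the labels refer to.
#' @param pixelSize um/px.
#' @param wavelength illumination wavelength, um.
#' @param params a [SegmentationParams-class] (supplies `dryMassAlpha`).
#' @param frameIndex frame number recorded in the output.
#' @param timestamp acquisition time (min) recorded in the output.
#' @return data.frame with one row per cell: `frame`, `t_min`, `label`,
#'   `x_um`, `y_um` (intensity-weighted centroid), `n_px`, `area_um2`,
#'   `length_um`, `width_um`, `aspect_ratio`, `mean_phase`, `dry_mass_pg`.
#'   Labels with fewer than 4 pixels are skipped with a warning.
#' @export
measureCells <- function(labels, frame, pixelSize, wavelength = 0.55,
                         params = segmentationParams(), frameIndex = 1L,
                         timestamp = 0) {
    idx <- which(labels > 0L)
    empty <- data.frame(frame = integer(), t_min = numeric(),
                        label = integer(), x_um = numeric(), y_um = numeric(),
                        n_px = integer(), area_um2 = numeric(),
                        length_um = numeric(), width_um = numeric(),
                        aspect_ratio = numeric(), mean_phase = numeric(),
                        dry_mass_pg = numeric())
    if (!length(idx)) return(empty)
    lab <- labels[idx]
    npx <- tabulate(lab)
    ids <- which(npx > 0L)
    tiny <- ids[npx[ids] < 4L]
    if (length(tiny)) {
        warning(length(tiny), " label(s) with fewer than 4 px skipped")
        keep <- !(lab %in% tiny)
        idx <- idx[keep]; lab <- lab[keep]
        ids <- setdiff(ids, tiny)
        if (!length(ids)) return(empty)
    }
    rc <- arrayInd(idx, dim(labels))
    x <- (rc[, 2L] - 0.5) * pixelSize
    y <- (rc[, 1L] - 0.5) * pixelSize
    phi <- frame[idx]
    w <- pmax(phi, 0)
    sumw <- rowsum(w, lab)[, 1L]
    n <- rowsum(rep(1, length(lab)), lab)[, 1L]
    sumphi <- rowsum(phi, lab)[, 1L]
    ## fall back to uniform weights for labels with no positive phase
    zw <- sumw <= 0
    if (any(zw)) {
        w[lab %in% as.integer(names(sumw)[zw])] <- 1
        sumw <- rowsum(w, lab)[, 1L]
    }
    cx <- rowsum(w * x, lab)[, 1L] / sumw
    cy <- rowsum(w * y, lab)[, 1L] / sumw
    labIds <- as.integer(names(sumw))
    ord <- match(lab, labIds)
    dx <- x - cx[ord]; dy <- y - cy[ord]
    sxx <- rowsum(w * dx * dx, lab)[, 1L] / sumw
    syy <- rowsum(w * dy * dy, lab)[, 1L] / sumw
    sxy <- rowsum(w * dx * dy, lab)[, 1L] / sumw
    ## deconvolve the Gaussian smoothing applied during preprocessing from
    ## the second moments (it adds sigma^2 to both axes); floor at the
    ## single-pixel variance
    smoothVar <- (params@smoothSigma * pixelSize)^2
    pxVar <- pixelSize^2 / 12
    sxx <- pmax(sxx - smoothVar, pxVar)
    syy <- pmax(syy - smoothVar, pxVar)
    tr <- sxx + syy
    det <- sxx * syy - sxy^2
    disc <- sqrt(pmax(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc
    l2 <- pmax(tr / 2 - disc, pxVar)
    len <- 4 * sqrt(l1)
    wid <- 4 * sqrt(l2)
    massScale <- wavelength / (2 * pi * params@dryMassAlpha) * pixelSize^2
    data.frame(
        frame = as.integer(frameIndex), t_min = as.numeric(timestamp),
        label = labIds, x_um = as.numeric(cx), y_um = as.numeric(cy),
        n_px = as.integer(n), area_um2 = n * pixelSize^2,
        length_um = as.numeric(len), width_um = as.numeric(wid),
        aspect_ratio = as.numeric(len / pmax(wid, .Machine$double.eps)),
        mean_phase = as.numeric(sumphi / n),
        dry_mass_pg = pmax(as.numeric(sumphi) * massScale, 0),
        row.names = NULL)
}

#' Segment and measure every frame of a phase stack
#'
#' Runs the full per-frame chain ([preprocessFrame()], [detectSeeds()],
#' [consolidateSeeds()], [segmentCells()], [measureCells()]) over a
#' [PhaseStack-class] and concatenates the per-cell tables.
#'
#' @param stack a [PhaseStack-class].
#' @param params a [SegmentationParams-class].
#' @return data.frame of cell measurements for all frames (see
#'   [measureCells()]); frames are numbered from 1 and `t_min` carries the
#'   stack's frame times.
#' @examples
#' \donttest{
#' sp <- timelapseSpec(populationSpec(3, 3.0, meanArea = 2000),
#'                     duration = 0, fieldSize = c(256L, 256L), seed = 2)
#' tl <- generateTimelapse(sp)
#' cells <- segmentStack(tl$stack, segmentationParams(rollingBallRadius = 60))
#' }
#' @export
segmentStack <- function(stack, params = segmentationParams()) {
    stopifnot(is(stack, "PhaseStack"))
    res <- vector("list", nFrames(stack))
    for (i in seq_len(nFrames(stack))) {
        fr <- preprocessFrame(getFrame(stack, i), params)
        thr <- .resolveThreshold(fr, params)
        seeds <- detectSeeds(fr, params, threshold = thr)
        seeds <- consolidateSeeds(seeds, fr, params)
        lab <- segmentCells(fr, seeds, params, threshold = thr)
        res[[i]] <- measureCells(lab, fr, pixelSize(stack),
                                 wavelength(stack), params,
                                 frameIndex = i,
                                 timestamp = frameTimes(stack)[i])
    }
    do.call(rbind, res)
}
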