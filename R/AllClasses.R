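#' @import methods
NULL

## ---------------------------------------------------------------------------
## PhaseStack
## ---------------------------------------------------------------------------

#' Calibrated quantitative-phase time-lapse stack
#'
#' A `PhaseStack` holds a time-ordered list of single-channel phase images
#' (matrices of optical phase shift in radians) together with the physical
#' calibration needed downstream: the lateral pixel size (micrometres per
#' pixel), the acquisition time of each frame (minutes from the start of the
#' experiment) and the illumination wavelength (micrometres), which enters the
#' dry-mass conversion.
#'
#' Pixel coordinates are column-major with origin at the top-left pixel; the
#' physical position of the pixel in row `r`, column `c` is
#' `((c - 0.5) * pixelSize, (r - 0.5) * pixelSize)` micrometres.
#'
#' @slot frames list of numeric matrices, all of identical dimension, phase in
#'   radians.
#' @slot pixelSize numeric(1), micrometres per pixel.
#' @slot frameTimes numeric vector, one timestamp (minutes) per frame,
#'   strictly increasing.
#' @slot wavelength numeric(1), illumination wavelength in micrometres.
#'
#' @seealso [phaseStack()], [segmentStack()], [readPhaseStack()]
#' @export
setClass("PhaseStack",
    representation(
        frames = "list",
        pixelSize = "numeric",
        frameTimes = "numeric",
        wavelength = "numeric"
    )
)

setValidity("PhaseStack", function(object) {
    msg <- character()
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive number (um/px)")
    if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
        object@wavelength <= 0)
        msg <- c(msg, "wavelength must be a single positive number (um)")
    if (length(object@frames) != length(object@frameTimes))
        msg <- c(msg, "one frame time per frame is required")
    if (length(object@frameTimes) > 1L && any(diff(object@frameTimes) <= 0))
        msg <- c(msg, "frameTimes must be strictly increasing")
    for (f in object@frames) {
        if (!is.matrix(f) || !is.numeric(f)) {
            msg <- c(msg, "all frames must be numeric matrices")
            break
        }
        if (!all(is.finite(f))) {
            msg <- c(msg, "frames must contain only finite phase values")
            break
        }
    }
    if (length(object@frames) > 1L) {
        d <- dim(object@frames[[1L]])
        if (!all(vapply(object@frames,
                        function(f) identical(dim(f), d), logical(1L))))
            msg <- c(msg, "all frames must share the same dimensions")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PhaseStack
#'
#' @param frames list of numeric phase matrices (radians), or a single matrix.
#' @param pixelSize micrometres per pixel.
#' @param frameTimes acquisition times in minutes; defaults to
#'   `0, interval, 2*interval, ...` when `frameInterval` is given.
#' @param frameInterval frame interval in minutes, used to build `frameTimes`
#'   when those are not supplied.
#' @param wavelength illumination wavelength in micrometres.
#' @return A [PhaseStack-class] object.
#' @examples
#' ps <- phaseStack(matrix(0, 8, 8), pixelSize = 0.5, wavelength = 0.55)
#' nFrames(ps)
#' @export
phaseStack <- function(frames, pixelSize, frameTimes = NULL,
                       frameInterval = 24, wavelength = 0.55) {
    if (is.matrix(frames)) frames <- list(frames)
    if (is.null(frameTimes))
        frameTimes <- (seq_along(frames) - 1) * frameInterval
    new("PhaseStack", frames = frames, pixelSize = pixelSize,
        frameTimes = as.numeric(frameTimes), wavelength = wavelength)
}

#' @describeIn PhaseStack-class number of frames
#' @param x,object a `PhaseStack`
#' @export
setMethod("length", "PhaseStack", function(x) length(x@frames))

setMethod("show", "PhaseStack", function(object) {
    d <- if (length(object@frames)) dim(object@frames[[1L]]) else c(0L, 0L)
    cat("PhaseStack with", length(object@frames), "frame(s) of",
        d[1L], "x", d[2L], "px\n")
    cat("  pixel size:", object@pixelSize, "um/px; wavelength:",
        object@wavelength, "um\n")
    if (length(object@frameTimes))
        cat("  time range:", min(object@frameTimes), "-",
            max(object@frameTimes), "min\n")
    invisible(NULL)
})

#' @rdname PhaseStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname PhaseStack-class
#' @export
setMethod("nFrames", "PhaseStack", function(x) length(x@frames))

#' @rdname PhaseStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname PhaseStack-class
#' @export
setMethod("pixelSize", "PhaseStack", function(x) x@pixelSize)

#' @rdname PhaseStack-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname PhaseStack-class
#' @export
setMethod("frameTimes", "PhaseStack", function(x) x@frameTimes)

#' @rdname PhaseStack-class
#' @export
setGeneric("wavelength", function(x) standardGeneric("wavelength"))
#' @rdname PhaseStack-class
#' @export
setMethod("wavelength", "PhaseStack", function(x) x@wavelength)

#' @rdname PhaseStack-class
#' @param i frame index
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname PhaseStack-class
#' @export
setMethod("getFrame", "PhaseStack", function(x, i) x@frames[[i]])

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Segmentation parameters for phase-image morphometry
#'
#' Bundles the tunables of the per-frame processing chain: rolling-ball
#' background removal, Gaussian smoothing, local-maximum seed detection,
#' seed consolidation, thresholding/segmentation, and dry-mass conversion.
#'
#' @slot rollingBallRadius numeric(1), radius in pixels of the rolling-ball
#'   background estimator; must exceed the half-width of the largest cell.
#' @slot smoothSigma numeric(1), Gaussian smoothing sigma in pixels.
#' @slot minSeedDistance numeric(1), minimum separation (pixels) between
#'   retained seed points.
#' @slot consolidationDelta numeric(1), phase (rad) plateau tolerance used to
#'   merge multiple seeds on one cell; `NA` means 10% of the frame maximum.
#' @slot threshold numeric(1) phase threshold (rad) separating cell from
#'   background, or `NA` for an automatic robust-background threshold (mode + 6 robust SD).
#' @slot dryMassAlpha numeric(1), specific refractive increment
#'   (um^3/pg) used in the dry-mass relation; typical cellular values are
#'   0.18-0.21.
#' @seealso [segmentationParams()]
#' @export
setClass("SegmentationParams",
    representation(
        rollingBallRadius = "numeric",
        smoothSigma = "numeric",
        minSeedDistance = "numeric",
        consolidationDelta = "numeric",
        threshold = "numeric",
        dryMassAlpha = "numeric"
    )
)

setValidity("SegmentationParams", function(object) {
    msg <- character()
    pos1 <- function(v) length(v) == 1L && is.finite(v) && v > 0
    if (!pos1(object@rollingBallRadius))
        msg <- c(msg, "rollingBallRadius must be a single positive number")
    if (!pos1(object@smoothSigma))
        msg <- c(msg, "smoothSigma must be a single positive number")
    if (!pos1(object@minSeedDistance))
        msg <- c(msg, "minSeedDistance must be a single positive number")
    if (!(length(object@consolidationDelta) == 1L &&
          (is.na(object@consolidationDelta) || object@consolidationDelta > 0)))
        msg <- c(msg, "consolidationDelta must be positive or NA (auto)")
    if (!(length(object@threshold) == 1L &&
          (is.na(object@threshold) || is.finite(object@threshold))))
        msg <- c(msg, "threshold must be a number or NA (auto)")
    if (!pos1(object@dryMassAlpha))
        msg <- c(msg, "dryMassAlpha must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Construct segmentation parameters
#'
#' @param rollingBallRadius rolling-ball radius (px); default 50.
#' @param smoothSigma Gaussian sigma (px); default 2.
#' @param minSeedDistance minimum seed separation (px); default 10.
#' @param consolidationDelta plateau tolerance (rad); `NA` (default) means
#'   10% of the preprocessed frame maximum.
#' @param threshold segmentation threshold (rad); `NA` (default) selects an
#'   robust-background threshold per frame.
#' @param dryMassAlpha specific refractive increment (um^3/pg); default 0.2.
#' @return A [SegmentationParams-class] object.
#' @examples
#' segmentationParams(rollingBallRadius = 40, smoothSigma = 1.5)
#' @export
segmentationParams <- function(rollingBallRadius = 50, smoothSigma = 2,
                               minSeedDistance = 10,
                               consolidationDelta = NA_real_,
                               threshold = NA_real_, dryMassAlpha = 0.2) {
    new("SegmentationParams",
        rollingBallRadius = as.numeric(rollingBallRadius),
        smoothSigma = as.numeric(smoothSigma),
        minSeedDistance = as.numeric(minSeedDistance),
        consolidationDelta = as.numeric(consolidationDelta),
        threshold = as.numeric(threshold),
        dryMassAlpha = as.numeric(dryMassAlpha))
}

setMethod("show", "SegmentationParams", function(object) {
    cat("SegmentationParams\n",
        " rollingBallRadius:", object@rollingBallRadius, "px\n",
        " smoothSigma:", object@smoothSigma, "px\n",
        " minSeedDistance:", object@minSeedDistance, "px\n",
        " consolidationDelta:",
        if (is.na(object@consolidationDelta)) "auto (10% of max)"
        else paste(object@consolidationDelta, "rad"), "\n",
        " threshold:",
        if (is.na(object@threshold)) "auto (robust background)"
        else paste(object@threshold, "rad"), "\n",
        " dryMassAlpha:", object@dryMassAlpha, "um^3/pg\n")
    invisible(NULL)
})

#' Exclusion gates for tracked objects
#'
#' Debris and artefact gates applied to measured objects and tracks: objects
#' below the dry-mass floor or the area floor (small debris), or above the
#' area ceiling (doublets, large debris), are removed, as are tracks observed
#' for fewer than the minimum number of frames.
#'
#' @slot minDryMass numeric(1), dry-mass floor in pg (default 250).
#' @slot minArea numeric(1), area floor in um^2 (default 1000).
#' @slot maxArea numeric(1), area ceiling in um^2 (default 25000).
#' @slot minFrames integer(1), minimum track length in frames (default 20).
#' @slot maxLinkDistance numeric(1), maximum frame-to-frame link distance (um).
#' @slot combine character(1), `"or"` (default) removes an object when either
#'   floor condition holds; `"and"` requires both.
#' @seealso [gateParams()], [applyGates()]
#' @export
setClass("GateParams",
    representation(
        minDryMass = "numeric",
        minArea = "numeric",
        maxArea = "numeric",
        minFrames = "integer",
        maxLinkDistance = "numeric",
        combine = "character"
    )
)

setValidity("GateParams", function(object) {
    msg <- character()
    if (object@minArea >= object@maxArea)
        msg <- c(msg, "minArea must be smaller than maxArea")
    if (object@minFrames < 1L)
        msg <- c(msg, "minFrames must be >= 1")
    if (!(object@combine %in% c("or", "and")))
        msg <- c(msg, "combine must be 'or' or 'and'")
    if (!is.finite(object@maxLinkDistance) || object@maxLinkDistance <= 0)
        msg <- c(msg, "maxLinkDistance must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct exclusion-gate parameters
#'
#' @param minDryMass dry-mass floor, pg.
#' @param minArea area floor, um^2.
#' @param maxArea area ceiling, um^2.
#' @param minFrames minimum track length, frames.
#' @param maxLinkDistance maximum frame-to-frame link distance, um.
#' @param combine `"or"` or `"and"` for the two debris floors.
#' @return A [GateParams-class] object.
#' @examples
#' gateParams(minFrames = 20)
#' @export
gateParams <- function(minDryMass = 250, minArea = 1000, maxArea = 25000,
                       minFrames = 20L, maxLinkDistance = 50,
                       combine = c("or", "and")) {
    combine <- match.arg(combine)
    new("GateParams", minDryMass = as.numeric(minDryMass),
        minArea = as.numeric(minArea), maxArea = as.numeric(maxArea),
        minFrames = as.integer(minFrames),
        maxLinkDistance = as.numeric(maxLinkDistance), combine = combine)
}

setMethod("show", "GateParams", function(object) {
    cat("GateParams: dry mass >=", object@minDryMass, "pg",
        paste0("(", object@combine, ")"), "area in [",
        object@minArea, ",", object@maxArea, "] um^2, >=",
        object@minFrames, "frames, link <=", object@maxLinkDistance, "um\n")
    invisible(NULL)
})

#' Colony-detection parameters for scanned CFU-F plates
#'
#' Parameters of the plate pipeline: well-rim detection on the blue channel,
#' colour unmixing into a crystal-violet stain image, block-based illumination
#' correction, Sobel edge enhancement, diamond closing, and robust-background
#' thresholding with an equivalent-diameter filter.
#'
#' @slot wellThreshold numeric(1), darkness threshold on the inverted blue
#'   channel used for well rims (default 0.99, i.e. near-black pixels).
#' @slot wellDiameterRange numeric(2), admissible rim outer diameters (px).
#' @slot illumBlockSize integer(1), block size (px) for illumination
#'   estimation (default 20).
#' @slot illumObjectSize integer(1), object-size scale (px) of the median
#'   filter applied to the block image (default 80).
#' @slot closingReach integer(1), reach (px) of the diamond closing that
#'   merges dispersed cells into their colony (default 10).
#' @slot colonyDiameterRange numeric(2), admissible colony equivalent
#'   diameters (px), default 60-800.
#' @slot backgroundK numeric(1), multiplier on the robust spread
#'   (1.4826 x MAD) added to the background mode to form the stain threshold.
#' @seealso [colonyParams()], [detectColonies()]
#' @export
setClass("ColonyParams",
    representation(
        wellThreshold = "numeric",
        wellDiameterRange = "numeric",
        illumBlockSize = "integer",
        illumObjectSize = "integer",
        closingReach = "integer",
        colonyDiameterRange = "numeric",
        backgroundK = "numeric"
    )
)

setValidity("ColonyParams", function(object) {
    msg <- character()
    if (diff(object@wellDiameterRange) <= 0)
        msg <- c(msg, "wellDiameterRange must be increasing")
    if (diff(object@colonyDiameterRange) <= 0)
        msg <- c(msg, "colonyDiameterRange must be increasing")
    if (any(c(object@illumBlockSize, object@illumObjectSize,
              object@closingReach) <= 0))
        msg <- c(msg, "block, object and closing sizes must be positive")
    if (object@backgroundK <= 0)
        msg <- c(msg, "backgroundK must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct colony-detection parameters
#'
#' @param wellThreshold rim darkness threshold on `1 - blue`; default 0.99.
#' @param wellDiameterRange rim outer-diameter range, px.
#' @param illumBlockSize illumination block size, px.
#' @param illumObjectSize illumination median-filter object size, px.
#' @param closingReach diamond closing reach, px.
#' @param colonyDiameterRange colony equivalent-diameter range, px.
#' @param backgroundK robust-background threshold multiplier.
#' @return A [ColonyParams-class] object.
#' @examples
#' colonyParams()
#' @export
colonyParams <- function(wellThreshold = 0.99,
                         wellDiameterRange = c(1000, 2000),
                         illumBlockSize = 20L, illumObjectSize = 80L,
                         closingReach = 10L,
                         colonyDiameterRange = c(60, 800),
                         backgroundK = 3) {
    new("ColonyParams", wellThreshold = as.numeric(wellThreshold),
        wellDiameterRange = as.numeric(wellDiameterRange),
        illumBlockSize = as.integer(illumBlockSize),
        illumObjectSize = as.integer(illumObjectSize),
        closingReach = as.integer(closingReach),
        colonyDiameterRange = as.numeric(colonyDiameterRange),
        backgroundK = as.numeric(backgroundK))
}

setMethod("show", "ColonyParams", function(object) {
    cat("ColonyParams: rims", object@wellDiameterRange[1L], "-",
        object@wellDiameterRange[2L], "px at threshold",
        object@wellThreshold, "; colonies",
        object@colonyDiameterRange[1L], "-", object@colonyDiameterRange[2L],
        "px; closing reach", object@closingReach,
        "px; background mode +", object@backgroundK, "x robust SD\n")
    invisible(NULL)
})

## ---------------------------------------------------------------------------
## Synthetic-data specification classes
## ---------------------------------------------------------------------------

#' Specification of one synthetic cell population
#'
#' Describes the morphometric and motility distribution of a cell
#' subpopulation rendered by [generateTimelapse()] or sampled by
#' [sampleMorphometry()]. Aspect ratios are drawn log-normally with median
#' `meanAspectRatio` and log-sd `sdAspectRatio / meanAspectRatio`; areas and
#' dry masses are drawn the same way. Motion follows a persistent random walk
#' (Ornstein-Uhlenbeck velocity) whose stationary mean speed equals
#' `meanSpeed`.
#'
#' @slot nCells integer(1), number of cells.
#' @slot meanAspectRatio numeric(1), dimensionless, >= 1.
#' @slot sdAspectRatio numeric(1), dispersion of the aspect ratio.
#' @slot meanArea numeric(1), um^2.
#' @slot sdArea numeric(1), um^2.
#' @slot meanSpeed numeric(1), um/h.
#' @slot persistenceTime numeric(1), min; velocity decorrelation time.
#' @slot meanDryMass numeric(1), pg.
#' @slot sdDryMass numeric(1), pg.
#' @slot label character(1), population label carried into ground truth.
#' @seealso [populationSpec()], [referencePopulations()]
#' @export
setClass("PopulationSpec",
    representation(
        nCells = "integer",
        meanAspectRatio = "numeric",
        sdAspectRatio = "numeric",
        meanArea = "numeric",
        sdArea = "numeric",
        meanSpeed = "numeric",
        persistenceTime = "numeric",
        meanDryMass = "numeric",
        sdDryMass = "numeric",
        label = "character"
    )
)

setValidity("PopulationSpec", function(object) {
    msg <- character()
    if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
    if (object@meanAspectRatio < 1)
        msg <- c(msg, "meanAspectRatio must be >= 1")
    means <- c(object@meanArea, object@meanSpeed, object@persistenceTime,
               object@meanDryMass)
    if (any(!is.finite(means)) || any(means <= 0))
        msg <- c(msg, "all means and the persistence time must be positive")
    sds <- c(object@sdAspectRatio, object@sdArea, object@sdDryMass)
    if (any(!is.finite(sds)) || any(sds < 0))
        msg <- c(msg, "all sds must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a population specification
#'
#' @param nCells number of cells.
#' @param meanAspectRatio,sdAspectRatio aspect-ratio (length:width) centre and
#'   spread.
#' @param meanArea,sdArea spread-area centre and spread, um^2.
#' @param meanSpeed mean migration speed, um/h.
#' @param persistenceTime velocity persistence time, min.
#' @param meanDryMass,sdDryMass dry-mass centre and spread, pg.
#' @param label population label.
#' @return A [PopulationSpec-class] object.
#' @examples
#' populationSpec(50, meanAspectRatio = 3.59, sdAspectRatio = 0.072,
#'                label = "spindle")
#' @export
populationSpec <- function(nCells, meanAspectRatio, sdAspectRatio = 0,
                           meanArea = 2500, sdArea = 0, meanSpeed = 15,
                           persistenceTime = 60, meanDryMass = 400,
                           sdDryMass = 0, label = "population") {
    new("PopulationSpec", nCells = as.integer(nCells),
        meanAspectRatio = as.numeric(meanAspectRatio),
        sdAspectRatio = as.numeric(sdAspectRatio),
        meanArea = as.numeric(meanArea), sdArea = as.numeric(sdArea),
        meanSpeed = as.numeric(meanSpeed),
        persistenceTime = as.numeric(persistenceTime),
        meanDryMass = as.numeric(meanDryMass),
        sdDryMass = as.numeric(sdDryMass), label = as.character(label))
}

setMethod("show", "PopulationSpec", function(object) {
    cat("PopulationSpec '", object@label, "': ", object@nCells,
        " cells, aspect ", object@meanAspectRatio, " +/- ",
        object@sdAspectRatio, ", area ", object@meanArea, " um^2, speed ",
        object@meanSpeed, " um/h\n", sep = "")
    invisible(NULL)
})

#' Specification of a synthetic phase time-lapse
#'
#' @slot populations list of [PopulationSpec-class] objects.
#' @slot frameInterval numeric(1), min between frames (acquisitions are
#'   typically taken every 20-26 min).
#' @slot duration numeric(1), h; the stack has
#'   `floor(duration * 60 / frameInterval) + 1` frames.
#' @slot fieldSize integer(2), image size in pixels (rows, cols).
#' @slot pixelSize numeric(1), um/px.
#' @slot backgroundRampAmplitude numeric(1), amplitude (rad) of the
#'   low-frequency background ramp.
#' @slot noiseSd numeric(1), Gaussian phase noise sd (rad).
#' @slot wavelength numeric(1), um.
#' @slot seed integer(1), RNG seed.
#' @seealso [timelapseSpec()], [generateTimelapse()]
#' @export
setClass("TimelapseSpec",
    representation(
        populations = "list",
        frameInterval = "numeric",
        duration = "numeric",
        fieldSize = "integer",
        pixelSize = "numeric",
        backgroundRampAmplitude = "numeric",
        noiseSd = "numeric",
        wavelength = "numeric",
        seed = "integer"
    )
)

setValidity("TimelapseSpec", function(object) {
    msg <- character()
    if (!all(vapply(object@populations, is, logical(1L), "PopulationSpec")))
        msg <- c(msg, "populations must be a list of PopulationSpec objects")
    if (object@frameInterval <= 0)
        msg <- c(msg, "frameInterval must be positive")
    if (object@duration < 0) msg <- c(msg, "duration must be >= 0")
    if (length(object@fieldSize) != 2L || any(object@fieldSize < 8L))
        msg <- c(msg, "fieldSize must be two pixel counts >= 8")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a time-lapse specification
#'
#' Defaults follow the acquisition regime the pipeline is designed for:
#' frames every 24 min (within the usual 20-26 min range) for up to 96 h.
#'
#' @param populations list of [PopulationSpec-class] (or a single one).
#' @param frameInterval min between frames; default 24.
#' @param duration experiment duration, h; default 96.
#' @param fieldSize image size, px (rows, cols).
#' @param pixelSize um/px.
#' @param backgroundRampAmplitude background ramp amplitude, rad.
#' @param noiseSd Gaussian phase-noise sd, rad.
#' @param wavelength illumination wavelength, um.
#' @param seed RNG seed.
#' @return A [TimelapseSpec-class] object.
#' @examples
#' sp <- timelapseSpec(populationSpec(5, 3.59), duration = 2, seed = 1)
#' @export
timelapseSpec <- function(populations, frameInterval = 24, duration = 96,
                          fieldSize = c(512L, 512L), pixelSize = 1.4,
                          backgroundRampAmplitude = 0.15, noiseSd = 0.02,
                          wavelength = 0.55, seed = 1L) {
    if (is(populations, "PopulationSpec")) populations <- list(populations)
    new("TimelapseSpec", populations = populations,
        frameInterval = as.numeric(frameInterval),
        duration = as.numeric(duration),
        fieldSize = as.integer(fieldSize), pixelSize = as.numeric(pixelSize),
        backgroundRampAmplitude = as.numeric(backgroundRampAmplitude),
        noiseSd = as.numeric(noiseSd), wavelength = as.numeric(wavelength),
        seed = as.integer(seed))
}

setMethod("show", "TimelapseSpec", function(object) {
    cat("TimelapseSpec:", length(object@populations), "population(s),",
        sum(vapply(object@populations, slot, integer(1L), "nCells")),
        "cells;", object@duration, "h at", object@frameInterval,
        "min/frame (", floor(object@duration * 60 / object@frameInterval) + 1,
        "frames );", object@fieldSize[1L], "x", object@fieldSize[2L],
        "px at", object@pixelSize, "um/px\n")
    invisible(NULL)
})

#' Specification of a synthetic scanned CFU-F plate
#'
#' @slot wells integer(1), number of wells (2 x 3 grid).
#' @slot wellDiameter numeric(1), inner well diameter in px (rim outer
#'   diameters must land in the 1000-2000 px detection window).
#' @slot colonyCountPerWell integer vector, colonies per well (recycled).
#' @slot colonyDiameterRange numeric(2), colony diameters, px.
#' @slot dispersedCellFraction numeric(1), fraction of colonies that carry a
#'   halo of dispersed cells just outside their rim.
#' @slot debrisCount integer(1), number of sub-detection-size debris specks.
#' @slot rimDarkness numeric(1), intensity of rim pixels (near 0 = black).
#' @slot illuminationAmplitude numeric(1), relative amplitude of a smooth
#'   illumination gradient across the scan.
#' @slot seed integer(1), RNG seed.
#' @seealso [plateScanSpec()], [generatePlateScan()]
#' @export
setClass("PlateScanSpec",
    representation(
        wells = "integer",
        wellDiameter = "numeric",
        colonyCountPerWell = "integer",
        colonyDiameterRange = "numeric",
        dispersedCellFraction = "numeric",
        debrisCount = "integer",
        rimDarkness = "numeric",
        illuminationAmplitude = "numeric",
        seed = "integer"
    )
)

setValidity("PlateScanSpec", function(object) {
    msg <- character()
    if (object@wells != 6L)
        msg <- c(msg, "wells must be 6 (2 x 3 grid)")
    if (object@wellDiameter < 900 || object@wellDiameter > 2000)
        msg <- c(msg, "wellDiameter must lie within the scanner convention")
    if (any(object@colonyCountPerWell < 0L))
        msg <- c(msg, "colony counts must be >= 0")
    if (any(object@colonyDiameterRange <= 0) ||
        diff(object@colonyDiameterRange) < 0)
        msg <- c(msg, "colonyDiameterRange must be positive and ordered")
    if (object@colonyDiameterRange[2L] >= object@wellDiameter)
        msg <- c(msg, "colony diameter must not exceed the well diameter")
    if (object@dispersedCellFraction < 0 || object@dispersedCellFraction > 1)
        msg <- c(msg, "dispersedCellFraction must be in [0,1]")
    if (object@rimDarkness < 0 || object@rimDarkness > 1)
        msg <- c(msg, "rimDarkness must be in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Construct a plate-scan specification
#'
#' @param wells number of wells; 6 (a 2 x 3 plate).
#' @param wellDiameter inner well diameter, px (default 1030 so rims fall in
#'   the 1000-2000 px window at 1200 dpi).
#' @param colonyCountPerWell per-well colony counts, recycled to `wells`.
#' @param colonyDiameterRange colony diameter range, px.
#' @param dispersedCellFraction fraction of colonies with dispersed-cell halo.
#' @param debrisCount number of small (< 60 px) debris specks.
#' @param rimDarkness rim pixel intensity; default 0.005 (near black).
#' @param illuminationAmplitude relative illumination-gradient amplitude.
#' @param seed RNG seed.
#' @return A [PlateScanSpec-class] object.
#' @examples
#' plateScanSpec(colonyCountPerWell = 2, seed = 7)
#' @export
plateScanSpec <- function(wells = 6L, wellDiameter = 1030,
                          colonyCountPerWell = 3L,
                          colonyDiameterRange = c(100, 300),
                          dispersedCellFraction = 0.3, debrisCount = 0L,
                          rimDarkness = 0.005, illuminationAmplitude = 0,
                          seed = 1L) {
    new("PlateScanSpec", wells = as.integer(wells),
        wellDiameter = as.numeric(wellDiameter),
        colonyCountPerWell = as.integer(rep_len(colonyCountPerWell,
                                                as.integer(wells))),
        colonyDiameterRange = as.numeric(colonyDiameterRange),
        dispersedCellFraction = as.numeric(dispersedCellFraction),
        debrisCount = as.integer(debrisCount),
        rimDarkness = as.numeric(rimDarkness),
        illuminationAmplitude = as.numeric(illuminationAmplitude),
        seed = as.integer(seed))
}

setMethod("show", "PlateScanSpec", function(object) {
    cat("PlateScanSpec:", object@wells, "wells of", object@wellDiameter,
        "px;", sum(object@colonyCountPerWell), "colonies of",
        object@colonyDiameterRange[1L], "-", object@colonyDiameterRange[2L],
        "px;", object@debrisCount, "debris\n")
    invisible(NULL)
})

#' Specification of a synthetic protein-abundance experiment
#'
#' Two groups with `replicatesPerGroup` biological replicates each;
#' per-protein baselines are log-normal across the proteome and multiplicative
#' log-normal noise with coefficient of variation `cv` is applied per sample.
#' `plantedEffects` scales selected proteins by a fold change in one group.
#'
#' @slot nProteins integer(1), proteins in the table.
#' @slot nMatrisome integer(1), how many carry a matrisome annotation.
#' @slot replicatesPerGroup integer(1), >= 2 (default 3).
#' @slot cv numeric(1), per-sample coefficient of variation.
#' @slot plantedEffects data.frame with columns `protein`, `fold`,
#'   `direction` (one of the group names).
#' @slot groups character(2), group names.
#' @slot seed integer(1), RNG seed.
#' @seealso [abundanceSpec()], [generateAbundanceTable()]
#' @export
setClass("AbundanceSpec",
    representation(
        nProteins = "integer",
        nMatrisome = "integer",
        replicatesPerGroup = "integer",
        cv = "numeric",
        plantedEffects = "data.frame",
        groups = "character",
        seed = "integer"
    )
)

setValidity("AbundanceSpec", function(object) {
    msg <- character()
    if (object@nMatrisome > object@nProteins)
        msg <- c(msg, "nMatrisome must be <= nProteins")
    if (object@replicatesPerGroup < 2L)
        msg <- c(msg, "replicatesPerGroup must be >= 2")
    if (object@cv < 0) msg <- c(msg, "cv must be >= 0")
    pe <- object@plantedEffects
    if (nrow(pe)) {
        if (!all(c("protein", "fold", "direction") %in% names(pe)))
            msg <- c(msg,
                     "plantedEffects needs columns protein, fold, direction")
        else {
            if (anyDuplicated(pe$protein))
                msg <- c(msg, "duplicate planted protein ids")
            if (any(pe$fold <= 0)) msg <- c(msg, "planted folds must be > 0")
            if (!all(pe$direction %in% object@groups))
                msg <- c(msg, "planted directions must name a group")
        }
    }
    if (length(object@groups) != 2L || anyDuplicated(object@groups))
        msg <- c(msg, "exactly two distinct group names are required")
    if (length(msg)) msg else TRUE
})

#' Construct an abundance-experiment specification
#'
#' @param nProteins number of proteins; default 861 (a secretome-scale table).
#' @param nMatrisome number of matrisome-annotated proteins; default 175.
#' @param replicatesPerGroup biological replicates per group; default 3.
#' @param cv per-sample coefficient of variation; default 0.1.
#' @param plantedEffects data.frame(protein, fold, direction).
#' @param groups two group names.
#' @param seed RNG seed.
#' @return An [AbundanceSpec-class] object.
#' @examples
#' abundanceSpec(nProteins = 100, nMatrisome = 20,
#'               plantedEffects = data.frame(protein = "P1", fold = 71,
#'                                           direction = "Y201"))
#' @export
abundanceSpec <- function(nProteins = 861L, nMatrisome = 175L,
                          replicatesPerGroup = 3L, cv = 0.1,
                          plantedEffects = data.frame(
                              protein = character(), fold = numeric(),
                              direction = character()),
                          groups = c("Y201", "Y202"), seed = 1L) {
    new("AbundanceSpec", nProteins = as.integer(nProteins),
        nMatrisome = as.integer(nMatrisome),
        replicatesPerGroup = as.integer(replicatesPerGroup),
        cv = as.numeric(cv), plantedEffects = plantedEffects,
        groups = as.character(groups), seed = as.integer(seed))
}

setMethod("show", "AbundanceSpec", function(object) {
    cat("AbundanceSpec:", object@nProteins, "proteins (",
        object@nMatrisome, "matrisome ),", object@replicatesPerGroup,
        "replicates x", paste(object@groups, collapse = "/"),
        ", cv", object@cv, ",", nrow(object@plantedEffects),
        "planted effect(s)\n")
    invisible(NULL)
})

## ---------------------------------------------------------------------------
## Classification classes
## ---------------------------------------------------------------------------

#' Morphometric reference profile
#'
#' Mean vector and covariance of (log aspect ratio, log area) fitted on a
#' reference cell population, used for Mahalanobis-distance classification.
#'
#' @slot label character(1), reference name.
#' @slot center numeric(2), feature means.
#' @slot covariance 2 x 2 covariance matrix (positive definite).
#' @slot nReference integer(1), reference sample size (>= 30).
#' @seealso [fitReferenceProfiles()], [classifyPopulation()]
#' @export
setClass("ReferenceProfile",
    representation(
        label = "character",
        center = "numeric",
        covariance = "matrix",
        nReference = "integer"
    )
)

setValidity("ReferenceProfile", function(object) {
    msg <- character()
    if (length(object@center) != 2L)
        msg <- c(msg, "center must have two features")
    cv <- object@covariance
    if (!identical(dim(cv), c(2L, 2L)))
        msg <- c(msg, "covariance must be 2 x 2")
    else {
        ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
        if (any(ev <= 0) || min(ev) / max(ev) < 1e-10)
            msg <- c(msg, "covariance must be positive definite")
    }
    if (object@nReference < 30L)
        msg <- c(msg, "at least 30 reference cells are required")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceProfile", function(object) {
    cat("ReferenceProfile '", object@label, "' (n = ", object@nReference,
        "): geometric mean aspect ratio ", round(exp(object@center[1L]), 3),
        ", geometric mean area ", round(exp(object@center[2L]), 1),
        " um^2\n", sep = "")
    invisible(NULL)
})

#' Subtype classification report
#'
#' @slot counts named integer vector, cells per class.
#' @slot fractions named numeric vector summing to 1.
#' @slot assignments data.frame with one row per cell: distances to each
#'   reference and the assigned class.
#' @slot margin numeric(1), distance-difference margin used.
#' @slot dMax numeric(1), maximum accepted Mahalanobis distance.
#' @seealso [classifyPopulation()]
#' @export
setClass("ClassificationReport",
    representation(
        counts = "integer",
        fractions = "numeric",
        assignments = "data.frame",
        margin = "numeric",
        dMax = "numeric"
    )
)

setValidity("ClassificationReport", function(object) {
    msg <- character()
    if (abs(sum(object@fractions) - 1) > 1e-9)
        msg <- c(msg, "fractions must sum to 1")
    if (!identical(names(object@counts), names(object@fractions)))
        msg <- c(msg, "counts and fractions must share class names")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ClassificationReport", function(object) {
    cat("ClassificationReport over", sum(object@counts), "cells",
        "(margin", object@margin, ", dMax", object@dMax, ")\n")
    for (cl in names(object@counts))
        cat(sprintf("  %-20s %6d  (%.1f%%)\n", cl, object@counts[[cl]],
                    100 * object@fractions[[cl]]))
    invisible(NULL)
})

#' Accessor generics for reports
#'
#' `classCounts()` and `classFractions()` extract per-class counts and
#' fractions from a [ClassificationReport-class];
#' `assignments()` returns the per-cell table.
#'
#' @param x a `ClassificationReport`
#' @return named vector or data.frame
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))
#' @rdname classCounts
#' @export
setMethod("classCounts", "ClassificationReport", function(x) x@counts)
#' @rdname classCounts
#' @export
setGeneric("classFractions", function(x) standardGeneric("classFractions"))
#' @rdname classCounts
#' @export
setMethod("classFractions", "ClassificationReport", function(x) x@fractions)
#' @rdname classCounts
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname classCounts
#' @export
setMethod("assignments", "ClassificationReport", function(x) x@assignments)
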