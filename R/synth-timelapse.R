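## Synthetic quantitative-phase time-lapse generator with ground truth.
## Cells are elliptical super-Gaussian phase blobs whose integrated phase
## encodes their dry mass; motion is a persistent random walk
## (Ornstein-Uhlenbeck velocity). The generator's alpha matches the
## measurement default so rendered mass and measured mass agree.

.GEN_ALPHA <- 0.2       # specific refractive increment used when rendering
.GEN_SUPERGAUSS_P <- 2  # super-Gaussian exponent of the cell profile
.GEN_QMAX <- 3          # profile rendered out to q <= .GEN_QMAX

#' Sample per-cell morphometry from a population specification
#'
#' Aspect ratio, area and dry mass are drawn log-normally with median equal
#' to the population mean and log-sd equal to `sd/mean` (so the coefficient
#' of variation matches the spread parameter and the support respects the
#' positivity/ratio constraints). Used both by [generateTimelapse()] and as
#' a standalone sampler for classifier fixtures.
#'
#' @param pop a [PopulationSpec-class].
#' @param n number of cells; defaults to `pop@nCells`.
#' @param seed optional RNG seed; when `NULL` the caller's RNG state is used.
#' @return data.frame with columns `label`, `aspect_ratio`, `area_um2`,
#'   `dry_mass_pg`.
#' @examples
#' sampleMorphometry(populationSpec(5, 3.59, 0.36, meanArea = 2500,
#'                                  sdArea = 250), seed = 1)
#' @export
sampleMorphometry <- function(pop, n = pop@nCells, seed = NULL) {
    draw <- function() {
        rln <- function(n, m, s) {
            if (s <= 0) rep(m, n)
            else stats::rlnorm(n, meanlog = log(m), sdlog = s / m)
        }
        data.frame(
            label = rep(pop@label, n),
            aspect_ratio = pmax(rln(n, pop@meanAspectRatio,
                                    pop@sdAspectRatio), 1),
            area_um2 = rln(n, pop@meanArea, pop@sdArea),
            dry_mass_pg = rln(n, pop@meanDryMass, pop@sdDryMass))
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

## One OU (persistent random walk) trajectory. Velocity is held constant
## within a frame interval, so the stationary mean frame-to-frame speed
## equals meanSpeed (sigma_v = meanSpeed * sqrt(2/pi) per component).
.prwTrack <- function(x0, y0, nframes, dtMin, meanSpeed, persistenceMin,
                      bounds = NULL) {
    dtH <- dtMin / 60
    sv <- meanSpeed * sqrt(2 / pi)
    rho <- exp(-dtMin / persistenceMin)
    innov <- sv * sqrt(1 - rho^2)
    vx <- stats::rnorm(1L, 0, sv); vy <- stats::rnorm(1L, 0, sv)
    x <- numeric(nframes); y <- numeric(nframes)
    x[1L] <- x0; y[1L] <- y0
    if (nframes > 1L) for (k in 2:nframes) {
        x[k] <- x[k - 1L] + vx * dtH
        y[k] <- y[k - 1L] + vy * dtH
        if (!is.null(bounds)) {
            if (x[k] < bounds[1L]) { x[k] <- 2 * bounds[1L] - x[k]; vx <- -vx }
            if (x[k] > bounds[2L]) { x[k] <- 2 * bounds[2L] - x[k]; vx <- -vx }
            if (y[k] < bounds[3L]) { y[k] <- 2 * bounds[3L] - y[k]; vy <- -vy }
            if (y[k] > bounds[4L]) { y[k] <- 2 * bounds[4L] - y[k]; vy <- -vy }
        }
        vx <- rho * vx + stats::rnorm(1L, 0, innov)
        vy <- rho * vy + stats::rnorm(1L, 0, innov)
    }
    cbind(x = x, y = y)
}

## Add one super-Gaussian elliptical phase blob to a frame (in place value).
.renderCell <- function(frame, cxUm, cyUm, aUm, bUm, theta, mass,
                        pixelSize, wavelength) {
    p <- .GEN_SUPERGAUSS_P
    phi0 <- mass * 2 * pi * .GEN_ALPHA /
        (wavelength * pi * aUm * bUm * gamma(1 + 1 / p))
    ext <- sqrt(.GEN_QMAX) * aUm
    nr <- nrow(frame); nc <- ncol(frame)
    c1 <- max(1L, floor((cxUm - ext) / pixelSize))
    c2 <- min(nc, ceiling((cxUm + ext) / pixelSize))
    r1 <- max(1L, floor((cyUm - ext) / pixelSize))
    r2 <- min(nr, ceiling((cyUm + ext) / pixelSize))
    if (c2 < c1 || r2 < r1) return(frame)
    xs <- ((c1:c2) - 0.5) * pixelSize - cxUm
    ys <- ((r1:r2) - 0.5) * pixelSize - cyUm
    X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
    u <- (cos(theta) * X + sin(theta) * Y) / aUm
    v <- (-sin(theta) * X + cos(theta) * Y) / bUm
    q <- u^2 + v^2
    blob <- ifelse(q <= .GEN_QMAX, phi0 * exp(-q^p), 0)
    frame[r1:r2, c1:c2] <- frame[r1:r2, c1:c2] + blob
    frame
}

#' Generate a synthetic phase time-lapse with ground truth
#'
#' Each cell is rendered as an elliptical super-Gaussian phase blob whose
#' integrated phase encodes its dry mass via the standard QPI relation
#' (alpha = 0.2 um^3/pg, matching the measurement default), placed without
#' initial overlap by rejection sampling, and moved by a persistent random
#' walk at its population's mean speed. The background is a static
#' low-frequency phase ramp plus per-frame Gaussian noise. The frame count
#' is `floor(duration * 60 / frameInterval) + 1`.
#'
#' @param spec a [TimelapseSpec-class]; all randomness flows from
#'   `spec@seed`.
#' @param render if `FALSE`, only the ground-truth tracks are simulated
#'   (`stack` is `NULL`); useful for tracking studies where the rasterised
#'   frames are not needed.
#' @return list with elements
#'   \describe{
#'     \item{stack}{a [PhaseStack-class] (or `NULL` when `render = FALSE`)}
#'     \item{truth}{list with `cells` (one row per cell: population label,
#'       drawn aspect ratio, area (um^2), dry mass, semi-axes and
#'       orientation) and `tracks` (long table: `cell`, `population`,
#'       `frame`, `t_min`, `x_um`, `y_um`)}
#'   }
#' @examples
#' tl <- generateTimelapse(timelapseSpec(populationSpec(2, 3, meanArea = 1500),
#'                         duration = 0, fieldSize = c(200L, 200L), seed = 3))
#' nFrames(tl$stack)
#' @export
generateTimelapse <- function(spec, render = TRUE) {
    stopifnot(is(spec, "TimelapseSpec"))
    withr::with_seed(spec@seed, .generateTimelapseImpl(spec, render))
}

.generateTimelapseImpl <- function(spec, render) {
    nframes <- floor(spec@duration * 60 / spec@frameInterval) + 1L
    times <- (seq_len(nframes) - 1L) * spec@frameInterval
    fieldUm <- spec@fieldSize * spec@pixelSize  # (rows=y, cols=x)

    cells <- do.call(rbind, lapply(spec@populations, function(p)
        sampleMorphometry(p, seed = NULL)))
    emptyTracks <- data.frame(cell = integer(), population = character(),
                              frame = integer(), t_min = numeric(),
                              x_um = numeric(), y_um = numeric())
    if (is.null(cells) || nrow(cells) == 0L) {
        cells <- data.frame(cell = integer(), label = character(),
                            aspect_ratio = numeric(), area_um2 = numeric(),
                            dry_mass_pg = numeric(), a_um = numeric(),
                            b_um = numeric(), theta = numeric())
        stack <- if (render)
            .renderStack(cells, emptyTracks, spec, nframes, times) else NULL
        return(list(stack = stack,
                    truth = list(cells = cells, tracks = emptyTracks)))
    }
    ncell <- nrow(cells)
    cells$cell <- seq_len(ncell)
    cells$a_um <- sqrt(cells$area_um2 * cells$aspect_ratio / pi)
    cells$b_um <- sqrt(cells$area_um2 / (cells$aspect_ratio * pi))
    cells$theta <- stats::runif(ncell, 0, pi)
    cells <- cells[, c("cell", "label", "aspect_ratio", "area_um2",
                       "dry_mass_pg", "a_um", "b_um", "theta")]

    ## rejection-sampled non-overlapping initial placement
    margin <- cells$a_um + 2 * spec@pixelSize
    if (any(2 * margin >= fieldUm[1L]) || any(2 * margin >= fieldUm[2L]))
        stop("field too small to place cells of this size")
    px <- numeric(ncell); py <- numeric(ncell)
    maxTry <- 2000L
    for (i in seq_len(ncell)) {
        ok <- FALSE
        for (t in seq_len(maxTry)) {
            cx <- stats::runif(1L, margin[i], fieldUm[2L] - margin[i])
            cy <- stats::runif(1L, margin[i], fieldUm[1L] - margin[i])
            if (i == 1L ||
                all((px[seq_len(i - 1L)] - cx)^2 +
                    (py[seq_len(i - 1L)] - cy)^2 >
                    (1.2 * (cells$a_um[seq_len(i - 1L)] + cells$a_um[i]))^2)) {
                px[i] <- cx; py[i] <- cy; ok <- TRUE; break
            }
        }
        if (!ok)
            stop("field too small to place ", ncell,
                 " cells without overlap; enlarge fieldSize")
    }

    speeds <- unlist(lapply(spec@populations,
                            function(p) rep(p@meanSpeed, p@nCells)))
    persist <- unlist(lapply(spec@populations,
                             function(p) rep(p@persistenceTime, p@nCells)))
    tracks <- vector("list", ncell)
    for (i in seq_len(ncell)) {
        xy <- .prwTrack(px[i], py[i], nframes, spec@frameInterval,
                        speeds[i], persist[i],
                        bounds = c(margin[i], fieldUm[2L] - margin[i],
                                   margin[i], fieldUm[1L] - margin[i]))
        tracks[[i]] <- data.frame(cell = i, population = cells$label[i],
                                  frame = seq_len(nframes), t_min = times,
                                  x_um = xy[, "x"], y_um = xy[, "y"])
    }
    tracks <- do.call(rbind, tracks)
    stack <- if (render) .renderStack(cells, tracks, spec, nframes, times)
             else NULL
    list(stack = stack, truth = list(cells = cells, tracks = tracks))
}

.renderStack <- function(cells, tracks, spec, nframes, times) {
    nr <- spec@fieldSize[1L]; nc <- spec@fieldSize[2L]
    ## static low-frequency background: tilted plane plus a broad sinusoid
    u <- matrix(seq(0, 1, length.out = nr), nr, nc)
    v <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
    dirw <- stats::runif(2L, -1, 1)
    ramp <- spec@backgroundRampAmplitude *
        (0.5 * (dirw[1L] * u + dirw[2L] * v) +
         0.5 * sin(pi * u) * sin(pi * v))
    frames <- vector("list", nframes)
    for (f in seq_len(nframes)) {
        fr <- ramp + matrix(stats::rnorm(nr * nc, 0, spec@noiseSd), nr, nc)
        sub <- tracks[tracks$frame == f, , drop = FALSE]
        for (k in seq_len(nrow(sub))) {
            i <- sub$cell[k]
            fr <- .renderCell(fr, sub$x_um[k], sub$y_um[k], cells$a_um[i],
                              cells$b_um[i], cells$theta[i],
                              cells$dry_mass_pg[i], spec@pixelSize,
                              spec@wavelength)
        }
        frames[[f]] <- fr
    }
    phaseStack(frames, pixelSize = spec@pixelSize, frameTimes = times,
               wavelength = spec@wavelength)
}
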