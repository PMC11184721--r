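## Synthetic scanned CFU-F plate generator with ground truth.
## Colonies are rendered in optical-density space with crystal-violet-like
## absorbance in the red and green channels (no blue absorbance), converted
## to RGB by transmittance 10^(-OD); well rims are near-black annuli.

.PLATE_RIM_PX <- 12L     # rim thickness
.PLATE_GAP_PX <- 60L     # gap between well rims
.PLATE_MARGIN_PX <- 40L  # image margin
.PLATE_BASE <- 0.94      # background (scanner bed) intensity
.PLATE_NOISE_SD <- 0.004 # additive intensity noise

## Logistic-edged disc OD profile added into a matrix patch.
.renderDiscOD <- function(od, cx, cy, radius, amplitude, edge = 1.5) {
    nr <- nrow(od); nc <- ncol(od)
    ext <- ceiling(radius + 6 * edge)
    c1 <- max(1L, floor(cx - ext)); c2 <- min(nc, ceiling(cx + ext))
    r1 <- max(1L, floor(cy - ext)); r2 <- min(nr, ceiling(cy + ext))
    if (c2 < c1 || r2 < r1) return(od)
    xs <- (c1:c2) - cx; ys <- (r1:r2) - cy
    D <- sqrt(outer(ys^2, xs^2, "+"))
    od[r1:r2, c1:c2] <- od[r1:r2, c1:c2] +
        amplitude / (1 + exp((D - radius) / edge))
    od
}

#' Generate a synthetic scanned CFU-F plate with ground truth
#'
#' Renders a 2 x 3 plate: near-black circular well rims at known centres,
#' crystal-violet colonies as soft-edged discs absorbing in the red and
#' green channels (blue transmitted, as in the stain's unmixing convention),
#' optional halos of dispersed cells just outside a colony's rim, sub-size
#' debris specks, a smooth illumination gradient, and pixel noise.
#'
#' @param spec a [PlateScanSpec-class]; all randomness flows from
#'   `spec@seed`.
#' @return list with
#'   \describe{
#'     \item{image}{numeric array `rows x cols x 3`, RGB in `[0, 1]`}
#'     \item{truth}{list: `wells` (centre/radius per well), `objects` (one
#'       row per planted colony or debris: well, centre, radius, area,
#'       `is_colony`), `masks` (integer label matrix over planted colony
#'       discs, labels matching `objects$id`)}
#'   }
#' @examples
#' \donttest{ps <- generatePlateScan(plateScanSpec(colonyCountPerWell = 1,
#'                                                 seed = 4))}
#' @export
generatePlateScan <- function(spec) {
    stopifnot(is(spec, "PlateScanSpec"))
    withr::with_seed(spec@seed, .generatePlateScanImpl(spec))
}

.generatePlateScanImpl <- function(spec) {
    if (spec@colonyDiameterRange[2L] >= spec@wellDiameter)
        stop("colony diameter exceeds the well diameter")
    layout <- c(2L, 3L)
    R <- spec@wellDiameter / 2
    outerR <- R + .PLATE_RIM_PX
    pitch <- 2 * outerR + .PLATE_GAP_PX
    nr <- as.integer(2 * .PLATE_MARGIN_PX + 2 * outerR +
                     (layout[1L] - 1L) * pitch)
    nc <- as.integer(2 * .PLATE_MARGIN_PX + 2 * outerR +
                     (layout[2L] - 1L) * pitch)
    centers <- expand.grid(row = seq_len(layout[1L]),
                           col = seq_len(layout[2L]))
    centers <- centers[order(centers$row, centers$col), ]
    centers$cy <- .PLATE_MARGIN_PX + outerR + (centers$row - 1L) * pitch
    centers$cx <- .PLATE_MARGIN_PX + outerR + (centers$col - 1L) * pitch
    centers$well <- paste0(LETTERS[centers$row], centers$col)

    odr <- matrix(0, nr, nc)
    objects <- list(); masks <- matrix(0L, nr, nc)
    objId <- 0L
    drange <- spec@colonyDiameterRange
    for (w in seq_len(nrow(centers))) {
        ncol_w <- spec@colonyCountPerWell[w]
        if (ncol_w == 0L) next
        placed <- matrix(numeric(0), ncol = 3L)  # cx, cy, r
        for (k in seq_len(ncol_w)) {
            rad <- stats::runif(1L, drange[1L], drange[2L]) / 2
            maxOff <- R - 5 - rad - 30
            if (maxOff <= 0)
                stop("colony diameter too large for the well interior")
            for (t in seq_len(500L)) {
                ang <- stats::runif(1L, 0, 2 * pi)
                off <- sqrt(stats::runif(1L)) * maxOff
                cx <- centers$cx[w] + off * cos(ang)
                cy <- centers$cy[w] + off * sin(ang)
                ## keep edge gaps > 2 x closing reach + halo extent so
                ## distinct colonies are never bridged by the closing step
                if (!nrow(placed) ||
                    all((placed[, 1L] - cx)^2 + (placed[, 2L] - cy)^2 >
                        (placed[, 3L] + rad + 80)^2)) break
                if (t == 500L) stop("could not place colonies without overlap")
            }
            placed <- rbind(placed, c(cx, cy, rad))
            amp <- stats::runif(1L, 0.5, 0.9)
            odr <- .renderDiscOD(odr, cx, cy, rad, amp)
            if (stats::runif(1L) < spec@dispersedCellFraction) {
                ndots <- sample(5:10, 1L)
                for (d in seq_len(ndots)) {
                    dang <- stats::runif(1L, 0, 2 * pi)
                    doff <- rad + stats::runif(1L, 5, 14)
                    odr <- .renderDiscOD(odr, cx + doff * cos(dang),
                                         cy + doff * sin(dang),
                                         stats::runif(1L, 2, 4), amp * 0.8,
                                         edge = 1)
                }
            }
            objId <- objId + 1L
            objects[[objId]] <- data.frame(
                id = objId, well = centers$well[w], cx_px = cx, cy_px = cy,
                radius_px = rad, area_px2 = pi * rad^2, is_colony = TRUE)
            ## truth mask: the colony disc
            ext <- ceiling(rad)
            rr <- max(1L, floor(cy - ext)):min(nr, ceiling(cy + ext))
            cc <- max(1L, floor(cx - ext)):min(nc, ceiling(cx + ext))
            D2 <- outer((rr - cy)^2, (cc - cx)^2, "+")
            blockSel <- D2 <= rad^2
            masks[rr, cc][blockSel] <- objId
        }
    }
    ## debris: sub-detection-size specks inside random wells
    for (d in seq_len(spec@debrisCount)) {
        w <- sample(nrow(centers), 1L)
        rad <- stats::runif(1L, 30, 50) / 2
        ang <- stats::runif(1L, 0, 2 * pi)
        off <- sqrt(stats::runif(1L)) * (R - 5 - rad - 30)
        cx <- centers$cx[w] + off * cos(ang)
        cy <- centers$cy[w] + off * sin(ang)
        odr <- .renderDiscOD(odr, cx, cy, rad, stats::runif(1L, 0.5, 0.9))
        objId <- objId + 1L
        objects[[objId]] <- data.frame(
            id = objId, well = centers$well[w], cx_px = cx, cy_px = cy,
            radius_px = rad, area_px2 = pi * rad^2, is_colony = FALSE)
    }
    objects <- if (length(objects)) do.call(rbind, objects) else
        data.frame(id = integer(), well = character(), cx_px = numeric(),
                   cy_px = numeric(), radius_px = numeric(),
                   area_px2 = numeric(), is_colony = logical())

    ## illumination gradient and conversion to RGB
    u <- matrix(seq(0, 1, length.out = nr), nr, nc)
    v <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
    wdir <- stats::runif(2L, -1, 1)
    g <- wdir[1L] * u + wdir[2L] * v
    if (diff(range(g)) > 0) g <- (g - min(g)) / diff(range(g)) - 0.5
    L <- 1 - spec@illuminationAmplitude * g
    trans <- 10^(-odr)
    img <- array(0, dim = c(nr, nc, 3L))
    img[, , 1L] <- .PLATE_BASE * L * trans
    img[, , 2L] <- .PLATE_BASE * L * trans
    img[, , 3L] <- .PLATE_BASE * L
    ## rims overwrite all channels
    for (w in seq_len(nrow(centers))) {
        ext <- ceiling(outerR)
        rr <- max(1L, floor(centers$cy[w] - ext)):
              min(nr, ceiling(centers$cy[w] + ext))
        cc <- max(1L, floor(centers$cx[w] - ext)):
              min(nc, ceiling(centers$cx[w] + ext))
        D2 <- outer((rr - centers$cy[w])^2, (cc - centers$cx[w])^2, "+")
        rim <- D2 >= R^2 & D2 <= outerR^2
        for (ch in 1:3) {
            sl <- img[rr, cc, ch]
            sl[rim] <- spec@rimDarkness
            img[rr, cc, ch] <- sl
        }
    }
    img <- img + array(stats::rnorm(length(img), 0, .PLATE_NOISE_SD),
                       dim = dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1

    wells <- data.frame(well = centers$well, row = centers$row,
                        col = centers$col, cx_px = centers$cx,
                        cy_px = centers$cy, radius_px = R)
    list(image = img,
         truth = list(wells = wells, objects = objects, masks = masks))
}
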