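## CFU-F plate analysis: well location, stain preprocessing, colony
## detection and measurement.

## Well naming for a rows x cols layout.
.wellNames <- function(layout) {
    g <- expand.grid(col = seq_len(layout[2L]), row = seq_len(layout[1L]))
    paste0(LETTERS[g$row], g$col)
}

#' Locate wells in a scanned plate
#'
#' Well rims are detected as near-black objects on the blue channel
#' (`1 - blue >= wellThreshold`) whose outer diameter falls in
#' `wellDiameterRange`. A regular 2 x 3 lattice is least-squares fitted to
#' the rim centroids and perfect circles are placed at the lattice nodes;
#' the analysis radius is the fitted inner rim radius minus 5 px (the rim
#' circle shrunk by 10 px in diameter, keeping measurements off the well
#' edge).
#'
#' @param image RGB array (`rows x cols x 3`, values in `[0, 1]`).
#' @param params a [ColonyParams-class].
#' @param layout wells as `c(rows, cols)`; default 2 x 3.
#' @return data.frame with one row per well: `well`, `row`, `col`, `cx_px`,
#'   `cy_px`, `radius_px`, `analysis_radius_px`.
#' @examples
#' \donttest{
#' ps <- generatePlateScan(plateScanSpec(colonyCountPerWell = 0, seed = 5))
#' locateWells(ps$image)
#' }
#' @export
locateWells <- function(image, params = colonyParams(),
                        layout = c(2L, 3L)) {
    stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
    blue <- image[, , 3L]
    rimMask <- (1 - blue) >= params@wellThreshold
    lab <- EBImage::bwlabel(rimMask)
    lab <- matrix(as.integer(lab), nrow(blue), ncol(blue))
    nlab <- max(lab)
    allWells <- .wellNames(layout)
    if (nlab == 0L)
        stop("no well rims found; missing wells: ",
             paste(allWells, collapse = ", "))
    idx <- which(lab > 0L)
    rc <- arrayInd(idx, dim(lab))
    li <- lab[idx]
    comp <- data.frame(
        id = seq_len(nlab),
        n = tabulate(li, nlab),
        cy = rowsum(rc[, 1L], li)[, 1L] / tabulate(li, nlab),
        cx = rowsum(rc[, 2L], li)[, 1L] / tabulate(li, nlab),
        rmin = vapply(seq_len(nlab), function(k) {
            s <- li == k
            stats::quantile(sqrt((rc[s, 1L] -
                                  sum(rc[s, 1L]) / sum(s))^2 +
                                 (rc[s, 2L] - sum(rc[s, 2L]) / sum(s))^2),
                            0.02, names = FALSE)
        }, numeric(1L)),
        rmax = vapply(seq_len(nlab), function(k) {
            s <- li == k
            max(sqrt((rc[s, 1L] - sum(rc[s, 1L]) / sum(s))^2 +
                     (rc[s, 2L] - sum(rc[s, 2L]) / sum(s))^2))
        }, numeric(1L)))
    comp$outerDiam <- 2 * comp$rmax
    rims <- comp[comp$outerDiam >= params@wellDiameterRange[1L] &
                 comp$outerDiam <= params@wellDiameterRange[2L] &
                 comp$n > 100L, , drop = FALSE]
    if (nrow(rims) < 4L) {
        found <- nrow(rims)
        stop("only ", found, " well rim(s) of ", length(allWells),
             " found; at least 4 are needed to fit the grid; ",
             "missing wells: ", paste(allWells, collapse = ", "))
    }
    ## assign rim centroids to lattice rows/columns and fit the lattice
    rowIdx <- .latticeIndex(rims$cy, layout[1L])
    colIdx <- .latticeIndex(rims$cx, layout[2L])
    fy <- stats::lm(cy ~ rowIdx, data = cbind(rims, rowIdx = rowIdx))
    fx <- stats::lm(cx ~ colIdx, data = cbind(rims, colIdx = colIdx))
    radius <- stats::median(rims$rmin)
    grid <- expand.grid(row = seq_len(layout[1L]), col = seq_len(layout[2L]))
    grid <- grid[order(grid$row, grid$col), ]
    cy <- stats::predict(fy, data.frame(rowIdx = grid$row))
    cx <- stats::predict(fx, data.frame(colIdx = grid$col))
    out <- data.frame(well = paste0(LETTERS[grid$row], grid$col),
                      row = grid$row, col = grid$col,
                      cx_px = as.numeric(cx), cy_px = as.numeric(cy),
                      radius_px = radius,
                      analysis_radius_px = radius - 5)
    rownames(out) <- NULL
    out
}

## Map coordinates to 1..k lattice indices by equal-width binning.
.latticeIndex <- function(x, k) {
    if (k == 1L) return(rep(1L, length(x)))
    rg <- range(x)
    if (diff(rg) == 0) return(rep(1L, length(x)))
    pmin(pmax(1L + as.integer(round((x - rg[1L]) / diff(rg) * (k - 1L))),
              1L), k)
}

## logical mask of pixels inside any analysis circle
.wellInteriorMask <- function(dims, wells) {
    m <- matrix(FALSE, dims[1L], dims[2L])
    for (w in seq_len(nrow(wells))) {
        ar <- wells$analysis_radius_px[w]
        rr <- max(1L, floor(wells$cy_px[w] - ar)):
              min(dims[1L], ceiling(wells$cy_px[w] + ar))
        cc <- max(1L, floor(wells$cx_px[w] - ar)):
              min(dims[2L], ceiling(wells$cx_px[w] + ar))
        D2 <- outer((rr - wells$cy_px[w])^2, (cc - wells$cx_px[w])^2, "+")
        m[rr, cc] <- m[rr, cc] | (D2 <= ar^2)
    }
    m
}

#' Unmix and illumination-correct a plate scan
#'
#' Converts the RGB scan to per-channel optical density
#' (`OD = -log10(intensity)`, zero-intensity pixels clipped to a small
#' epsilon with a warning) and projects onto the crystal-violet absorbance
#' direction `(1, 1, 0) / sqrt(2)` (red and green absorb, blue does not),
#' yielding a stain image. Pixels outside the wells' analysis circles are
#' zeroed. The illumination surface is estimated from per-block medians
#' (block size `illumBlockSize`), median-filtered at the
#' `illumObjectSize` scale and summarised by a robust quadratic surface
#' fit, then subtracted within the wells.
#'
#' @param image RGB array in `[0, 1]`.
#' @param wells data.frame from [locateWells()].
#' @param params a [ColonyParams-class].
#' @return Stain matrix (OD units) with attribute `"illumination"` (the
#'   subtracted surface) and `"interior"` (the analysis-circle mask).
#' @export
preprocessPlate <- function(image, wells, params = colonyParams()) {
    eps <- 1e-3
    if (any(image[, , 1:2] < eps))
        warning("zero-intensity pixels clipped to epsilon before log")
    odr <- -log10(pmax(image[, , 1L], eps))
    odg <- -log10(pmax(image[, , 2L], eps))
    stain <- (odr + odg) / sqrt(2)
    interior <- .wellInteriorMask(dim(stain), wells)
    stain[!interior] <- 0
    illum <- .illuminationSurface(stain, interior, params)
    stain[interior] <- stain[interior] - illum[interior]
    attr(stain, "illumination") <- illum
    attr(stain, "interior") <- interior
    stain
}

## Robust smooth illumination surface from block medians. Blocks fully
## outside the wells are ignored; the median-filtered block image is fed to
## a bisquare rlm quadratic fit so colony-scale features cannot enter the
## surface, only the smooth illumination trend does.
.illuminationSurface <- function(stain, interior, params) {
    bs <- params@illumBlockSize
    nr <- nrow(stain); nc <- ncol(stain)
    nrb <- floor(nr / bs); ncb <- floor(nc / bs)
    sm <- stain[seq_len(nrb * bs), seq_len(ncb * bs)]
    im <- interior[seq_len(nrb * bs), seq_len(ncb * bs)]
    sm[!im] <- NA_real_
    A <- array(sm, dim = c(bs, nrb, bs, ncb))
    blockMed <- apply(A, c(2L, 4L), stats::median, na.rm = TRUE)
    ## median filter at the object-size scale (in blocks)
    half <- max(1L, floor(params@illumObjectSize / bs / 2))
    blockMed <- .medianFilterNA(blockMed, half)
    bi <- which(is.finite(blockMed), arr.ind = TRUE)
    if (nrow(bi) < 12L) return(matrix(0, nr, nc))
    df <- data.frame(z = blockMed[bi],
                     x = (bi[, 2L] - 0.5) * bs, y = (bi[, 1L] - 0.5) * bs)
    fit <- MASS::rlm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), data = df,
                     psi = MASS::psi.bisquare, maxit = 50)
    X <- matrix(rep((seq_len(nc)) - 0.5, each = nr), nr, nc)
    Y <- matrix(rep((seq_len(nr)) - 0.5, nc), nr, nc)
    co <- stats::coef(fit)
    co[!is.finite(co)] <- 0
    matrix(co[1L] + co[2L] * X + co[3L] * Y + co[4L] * X^2 +
           co[5L] * Y^2 + co[6L] * X * Y, nr, nc)
}

## NA-tolerant square median filter with half-width h.
.medianFilterNA <- function(m, h) {
    nr <- nrow(m); nc <- ncol(m)
    out <- m
    for (i in seq_len(nr)) {
        ri <- max(1L, i - h):min(nr, i + h)
        for (j in seq_len(nc)) {
            cj <- max(1L, j - h):min(nc, j + h)
            v <- m[ri, cj]
            out[i, j] <- if (all(is.na(v))) NA_real_ else
                stats::median(v, na.rm = TRUE)
        }
    }
    out
}

#' Detect colonies in a preprocessed stain image
#'
#' Sobel gradient magnitude (scaled to the stain image's dynamic range) is
#' added to the stain image to enhance feature edges, a per-well binary mask
#' is formed by robust-background thresholding (background mode plus
#' `backgroundK` times the robust SD, 1.4826 x MAD, of the in-well pixels),
#' a diamond-shaped closing with the configured reach merges dispersed-cell
#' halos into their colony, and connected components are filtered to
#' half-maximum core equivalent diameters within `colonyDiameterRange`
#' (see [measureColonies()] for the core-area convention).
#'
#' @param stain stain matrix from [preprocessPlate()].
#' @param wells data.frame from [locateWells()].
#' @param params a [ColonyParams-class].
#' @return Integer label matrix of detected colonies (0 = background) with
#'   attribute `"wellOf"`: a character vector mapping label to well id.
#' @export
detectColonies <- function(stain, wells, params = colonyParams()) {
    interior <- attr(stain, "interior")
    if (is.null(interior)) interior <- .wellInteriorMask(dim(stain), wells)
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L)
    gx <- matrix(as.numeric(EBImage::filter2(stain, kx)), nrow(stain))
    gy <- matrix(as.numeric(EBImage::filter2(stain, t(kx))), nrow(stain))
    sob <- sqrt(gx^2 + gy^2)
    if (max(sob) > 0) sob <- sob / max(sob) * max(stain)
    combined <- stain + sob
    labels <- matrix(0L, nrow(stain), ncol(stain))
    wellOf <- character()
    nextLab <- 0L
    brush <- EBImage::makeBrush(2L * params@closingReach + 1L,
                                shape = "diamond")
    for (w in seq_len(nrow(wells))) {
        ar <- wells$analysis_radius_px[w]
        rr <- max(1L, floor(wells$cy_px[w] - ar)):
              min(nrow(stain), ceiling(wells$cy_px[w] + ar))
        cc <- max(1L, floor(wells$cx_px[w] - ar)):
              min(ncol(stain), ceiling(wells$cx_px[w] + ar))
        inside <- outer((rr - wells$cy_px[w])^2,
                        (cc - wells$cx_px[w])^2, "+") <= ar^2
        sub <- combined[rr, cc]
        vals <- sub[inside]
        md <- .histMode(vals)
        ## floor the robust spread at a small fraction of the dynamic range
        ## so a (near) noise-free background cannot collapse the threshold
        ## onto the mode
        spread <- max(stats::mad(vals),
                      0.05 * (max(vals) - md) / params@backgroundK)
        thr <- md + params@backgroundK * spread
        mask <- sub > thr & inside
        mask <- EBImage::closing(mask, brush)
        mask <- matrix(as.logical(mask > 0), nrow(sub)) & inside
        lab <- EBImage::bwlabel(mask)
        lab <- matrix(as.integer(lab), nrow(sub))
        if (max(lab) > 0L) {
            ## size-filter on the half-maximum core diameter (the stained
            ## core, insensitive to the edge-enhancement ring)
            stainSub <- stain[rr, cc]
            eqd <- vapply(seq_len(max(lab)), function(k) {
                v <- stainSub[lab == k]
                if (!length(v)) return(0)
                core <- sum(v >= 0.5 * stats::quantile(v, 0.95,
                                                       names = FALSE))
                2 * sqrt(core / pi)
            }, numeric(1L))
            keep <- which(eqd >= params@colonyDiameterRange[1L] &
                          eqd <= params@colonyDiameterRange[2L])
            if (length(keep)) {
                remap <- integer(max(lab))
                remap[keep] <- nextLab + seq_along(keep)
                newlab <- matrix(0L, nrow(sub), ncol(sub))
                sel <- lab > 0L & lab %in% keep
                newlab[sel] <- remap[lab[sel]]
                old <- labels[rr, cc]
                old[newlab > 0L] <- newlab[newlab > 0L]
                labels[rr, cc] <- old
                wellOf <- c(wellOf, rep(wells$well[w], length(keep)))
                nextLab <- nextLab + length(keep)
            }
        }
    }
    attr(labels, "wellOf") <- wellOf
    labels
}

#' Measure detected colonies and summarise per well
#'
#' Per-colony area (px^2 and mm^2 via the scan resolution), equivalent
#' circular diameter, eccentricity of the second-moment ellipse, centroid
#' and integrated stain intensity, plus a per-well report with colony count
#' and mean colony area.
#'
#' The detected component (its footprint, reported as `footprint_px2`)
#' includes the edge-enhancement ring and closed dispersed-cell gaps, so
#' colony area is refined to the stained core: pixels of the component
#' whose stain reaches half of the colony's plateau intensity (95th
#' percentile), the full-width-at-half-maximum convention. For a stained
#' disc this recovers the disc area irrespective of edge softness.
#'
#' @param labels label matrix from [detectColonies()].
#' @param stain stain matrix from [preprocessPlate()].
#' @param wells data.frame from [locateWells()].
#' @param dpi scan resolution (pixels per inch); default 1200.
#' @return list with `colonies` (one row per colony) and `wells` (per-well
#'   report incl. wells with zero colonies).
#' @export
measureColonies <- function(labels, stain, wells, dpi = 1200) {
    wellOf <- attr(labels, "wellOf")
    pxMm <- 25.4 / dpi
    idx <- which(labels > 0L)
    if (length(idx)) {
        li <- labels[idx]
        rc <- arrayInd(idx, dim(labels))
        n <- tabulate(li)
        ids <- which(n > 0L)
        cy <- rowsum(rc[, 1L], li)[, 1L] / n[ids]
        cx <- rowsum(rc[, 2L], li)[, 1L] / n[ids]
        ord <- match(li, ids)
        dy <- rc[, 1L] - cy[ord]; dx <- rc[, 2L] - cx[ord]
        syy <- rowsum(dy * dy, li)[, 1L] / n[ids]
        sxx <- rowsum(dx * dx, li)[, 1L] / n[ids]
        sxy <- rowsum(dx * dy, li)[, 1L] / n[ids]
        tr <- sxx + syy; det <- sxx * syy - sxy^2
        disc <- sqrt(pmax(tr^2 / 4 - det, 0))
        l1 <- tr / 2 + disc; l2 <- pmax(tr / 2 - disc, 0)
        ecc <- sqrt(pmax(1 - l2 / pmax(l1, .Machine$double.eps), 0))
        sv <- stain[idx]
        intint <- rowsum(sv, li)[, 1L]
        ## half-maximum core area per colony
        core <- vapply(ids, function(id) {
            v <- sv[li == id]
            sum(v >= 0.5 * stats::quantile(v, 0.95, names = FALSE))
        }, numeric(1L))
        colonies <- data.frame(
            colony = ids, well = wellOf[ids],
            cx_px = as.numeric(cx), cy_px = as.numeric(cy),
            area_px2 = as.numeric(core),
            area_mm2 = as.numeric(core) * pxMm^2,
            footprint_px2 = as.numeric(n[ids]),
            equivalent_diameter_px = 2 * sqrt(core / pi),
            eccentricity = as.numeric(ecc),
            integrated_od = as.numeric(intint))
    } else {
        colonies <- data.frame(
            colony = integer(), well = character(), cx_px = numeric(),
            cy_px = numeric(), area_px2 = numeric(), area_mm2 = numeric(),
            equivalent_diameter_px = numeric(), eccentricity = numeric(),
            integrated_od = numeric())
    }
    rep <- do.call(rbind, lapply(seq_len(nrow(wells)), function(w) {
        sub <- colonies[colonies$well == wells$well[w], , drop = FALSE]
        data.frame(well = wells$well[w], n_colonies = nrow(sub),
                   mean_area_px2 = if (nrow(sub)) mean(sub$area_px2)
                                   else NA_real_,
                   mean_area_mm2 = if (nrow(sub)) mean(sub$area_mm2)
                                   else NA_real_,
                   total_od = if (nrow(sub)) sum(sub$integrated_od) else 0)
    }))
    rownames(colonies) <- rownames(rep) <- NULL
    list(colonies = colonies, wells = rep)
}

#' Full plate analysis
#'
#' Convenience wrapper: [locateWells()], [preprocessPlate()],
#' [detectColonies()], [measureColonies()]. Colonies listed in `exclude`
#' (by label) are dropped after detection, replacing the interactive manual
#' correction step of scanner pipelines.
#'
#' @param image RGB array in `[0, 1]`.
#' @param params a [ColonyParams-class].
#' @param dpi scan resolution; default 1200.
#' @param exclude integer labels to drop from the result.
#' @return list with `wells` (geometry), `colonies`, `wellReport` and
#'   `labels` (the label matrix).
#' @export
analyzePlate <- function(image, params = colonyParams(), dpi = 1200,
                         exclude = integer()) {
    wells <- locateWells(image, params)
    stain <- preprocessPlate(image, wells, params)
    labels <- detectColonies(stain, wells, params)
    if (length(exclude)) {
        wellOf <- attr(labels, "wellOf")
        labels[labels %in% exclude] <- 0L
        attr(labels, "wellOf") <- wellOf
    }
    meas <- measureColonies(labels, stain, wells, dpi = dpi)
    if (length(exclude))
        meas$colonies <- meas$colonies[!(meas$colonies$colony %in% exclude),
                                       , drop = FALSE]
    list(wells = wells, colonies = meas$colonies, wellReport = meas$wells,
         labels = labels)
}
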