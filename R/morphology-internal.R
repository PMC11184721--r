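## Internal grayscale morphology and background-estimation primitives.
## These back preprocessFrame() and detectSeeds(); no installed package
## provides a rolling-ball background estimator, so it lives here.

## Offsets and structuring-element heights for a ball (spherical cap) or a
## flat disc of the given radius. Heights are <= 0 with h(0) = 0 so that the
## opening of a flat image is the image itself.
.ballElement <- function(radius, flat = FALSE) {
    r <- max(1L, ceiling(radius))
    dd <- expand.grid(dr = -r:r, dc = -r:r)
    d2 <- dd$dr^2 + dd$dc^2
    keep <- d2 <= radius^2
    dd <- dd[keep, , drop = FALSE]
    h <- if (flat) rep(0, nrow(dd)) else
        sqrt(pmax(radius^2 - d2[keep], 0)) - radius
    list(dr = dd$dr, dc = dd$dc, h = h, r = r)
}

## Pad a matrix by edge replication.
.padReplicate <- function(m, r) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
    ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
    m[ri, ci, drop = FALSE]
}

## Grayscale erosion (op = "erode") or dilation (op = "dilate") with an
## arbitrary structuring element, vectorised over shifts.
.grayMorph <- function(m, elem, op = c("erode", "dilate")) {
    op <- match.arg(op)
    nr <- nrow(m); nc <- ncol(m); r <- elem$r
    pad <- .padReplicate(m, r)
    out <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
    for (k in seq_along(elem$h)) {
        sub <- pad[(1L + r + elem$dr[k]):(nr + r + elem$dr[k]),
                   (1L + r + elem$dc[k]):(nc + r + elem$dc[k]), drop = FALSE]
        out <- if (op == "erode") pmin(out, sub - elem$h[k])
               else pmax(out, sub + elem$h[k])
    }
    out
}

## Grayscale opening with a ball of the given radius whose vertical
## (intensity) semi-axis is radius * zScale. zScale = 0 is the flat-disc
## limit: the appropriate regime when the image's dynamic range is small
## compared to the ball radius (a ball with its full curvature expressed in
## phase units would fit inside cell-scale bumps and track them instead of
## rolling under them).
.grayOpen <- function(m, radius, zScale = 0) {
    elem <- .ballElement(radius, flat = zScale == 0)
    elem$h <- elem$h * zScale
    .grayMorph(.grayMorph(m, elem, "erode"), elem, "dilate")
}

## Block-minimum downsampling by an integer factor (edge blocks padded by
## replication so dimensions round up).
.blockMin <- function(m, f) {
    if (f <= 1L) return(m)
    nr <- nrow(m); nc <- ncol(m)
    nr2 <- ceiling(nr / f) * f; nc2 <- ceiling(nc / f) * f
    mp <- m[c(seq_len(nr), rep(nr, nr2 - nr)),
            c(seq_len(nc), rep(nc, nc2 - nc)), drop = FALSE]
    out <- matrix(Inf, nr2 / f, nc2 / f)
    for (i in seq_len(f)) for (j in seq_len(f)) {
        out <- pmin(out, mp[seq(i, nr2, by = f), seq(j, nc2, by = f),
                            drop = FALSE])
    }
    out
}

## Rolling-ball background: grayscale opening with a ball structuring
## element in the flat-disc limit (see .grayOpen), computed on a shrunken
## copy for large radii (the classic speed-up) and resized back with
## bilinear interpolation. The returned background never exceeds the image.
.rollingBallBackground <- function(m, radius, zScale = 0) {
    stopifnot(radius > 0)
    shrink <- if (radius <= 16) 1L else if (radius <= 48) 4L else 8L
    if (shrink == 1L) {
        bg <- .grayOpen(m, radius, zScale = zScale)
    } else {
        small <- .blockMin(m, shrink)
        bg <- .grayOpen(small, radius / shrink, zScale = zScale * shrink)
        bg <- .resizeBilinear(bg, nrow(m), ncol(m))
    }
    pmin(bg, m)
}

## Bilinear resize via EBImage (antialias-free, deterministic).
.resizeBilinear <- function(m, nr, nc) {
    out <- EBImage::resize(m, w = nr, h = nc, filter = "bilinear")
    matrix(as.numeric(out), nr, nc)
}

## Normalised Gaussian smoothing; replicated boundary avoids wrap-around
## artefacts on frames with background gradients, and the unit-sum kernel
## conserves total intensity away from the frame edge.
.gaussSmooth <- function(m, sigma) {
    size <- 2L * ceiling(3 * sigma) + 1L
    br <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
    br <- br / sum(br)
    matrix(as.numeric(EBImage::filter2(m, br, boundary = "replicate")),
           nrow(m), ncol(m))
}

## Seeded watershed by ordered flooding: intensity levels are processed
## from brightest to darkest; within each level, unlabelled foreground
## pixels adjacent to a labelled pixel take the label of their brightest
## labelled neighbour, iterating until the level is exhausted. Boundaries
## therefore form along intensity valleys, as in the classic
## watershed-from-markers construction.
.seededWatershed <- function(frame, seedimg, mask, nbins = 64L) {
    nr <- nrow(frame); nc <- ncol(frame)
    labv <- as.integer(ifelse(mask, seedimg, 0L))
    intv <- as.numeric(frame)
    remaining <- which(as.logical(mask) & labv == 0L)
    if (!length(remaining)) return(matrix(labv, nr, nc))
    rg <- range(intv[as.logical(mask)])
    lev <- if (diff(rg) > 0)
        pmin(nbins, 1L + as.integer(floor((intv - rg[1L]) / diff(rg) *
                                          (nbins - 1L)) + 0L))
        else rep(1L, length(intv))
    drs <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dcs <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
    for (l in seq.int(nbins, 1L)) {
        sel <- lev[remaining] >= l
        act <- remaining[sel]
        remaining <- remaining[!sel]
        while (length(act)) {
            aRow <- ((act - 1L) %% nr) + 1L
            aCol <- ((act - 1L) %/% nr) + 1L
            bestInt <- rep(-Inf, length(act))
            bestLab <- integer(length(act))
            for (k in 1:8) {
                ok <- aRow + drs[k] >= 1L & aRow + drs[k] <= nr &
                      aCol + dcs[k] >= 1L & aCol + dcs[k] <= nc
                nb <- act[ok] + drs[k] + dcs[k] * nr
                nl <- labv[nb]
                ni <- intv[nb]
                upd <- nl > 0L & ni > bestInt[ok]
                if (any(upd)) {
                    w <- which(ok)[upd]
                    bestInt[w] <- ni[upd]
                    bestLab[w] <- nl[upd]
                }
            }
            newly <- bestLab > 0L
            if (!any(newly)) break
            labv[act[newly]] <- bestLab[newly]
            act <- act[!newly]
        }
        remaining <- c(remaining, act)
    }
    matrix(labv, nr, nc)
}

## Histogram mode of a numeric vector (density peak).
.histMode <- function(x) {
    if (length(x) < 2L || diff(range(x)) == 0) return(x[1L])
    d <- stats::density(x, n = 512L)
    d$x[which.max(d$y)]
}
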