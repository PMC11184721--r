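## Independent brute-force oracles and shared fixtures. Oracles are written
## directly from the defining formulas/constructions and never call the
## implementation paths they check.

## Grayscale opening with a ball (or flat-disc) structuring element,
## computed by direct double loops over pixels and element offsets.
oracleGrayOpen <- function(m, radius, zScale = 0) {
    r <- ceiling(radius)
    dd <- expand.grid(dr = -r:r, dc = -r:r)
    dd <- dd[dd$dr^2 + dd$dc^2 <= radius^2, ]
    h <- zScale * (sqrt(pmax(radius^2 - dd$dr^2 - dd$dc^2, 0)) - radius)
    nr <- nrow(m); nc <- ncol(m)
    clamp <- function(i, n) pmin(pmax(i, 1L), n)
    er <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        er[i, j] <- min(m[cbind(clamp(i + dd$dr, nr),
                                clamp(j + dd$dc, nc))] - h)
    }
    op <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        op[i, j] <- max(er[cbind(clamp(i + dd$dr, nr),
                                 clamp(j + dd$dc, nc))] + h)
    }
    op
}

## Steepest-ascent flooding: every foreground pixel climbs to its local
## maximum and takes the label of the seed nearest to the terminus.
oracleAscentFlood <- function(frame, seeds, mask) {
    nr <- nrow(frame); nc <- ncol(frame)
    out <- matrix(0L, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (!mask[i, j]) next
        ci <- i; cj <- j
        repeat {
            bi <- ci; bj <- cj; bv <- frame[ci, cj]
            for (di in -1:1) for (dj in -1:1) {
                ni <- ci + di; nj <- cj + dj
                if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
                    frame[ni, nj] > bv) {
                    bv <- frame[ni, nj]; bi <- ni; bj <- nj
                }
            }
            if (bi == ci && bj == cj) break
            ci <- bi; cj <- bj
        }
        out[i, j] <- which.min((seeds$row - ci)^2 + (seeds$col - cj)^2)
    }
    out
}

## Exact hypergeometric upper tail by enumeration over overlap outcomes.
oracleHyperUpper <- function(k, K, N, n) {
    js <- k:min(K, n)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## Two-category Pearson goodness-of-fit statistic, closed form.
oracleChi2 <- function(k, n, K, N) {
    e <- n * K / N
    (k - e)^2 / e + ((n - k) - (n - e))^2 / (n - e)
}

## Gaussian blob field for seed/segmentation fixtures.
blobFrame <- function(nr, nc, blobs) {
    x <- matrix(rep(seq_len(nc), each = nr), nr)
    y <- matrix(rep(seq_len(nr), nc), nr)
    fr <- matrix(0, nr, nc)
    for (b in blobs)
        fr <- fr + b$amp * exp(-((x - b$cx)^2 + (y - b$cy)^2) / (2 * b$s^2))
    fr
}

## Sharp-edged ellipse indicator (value 1 inside) on a pixel grid; physical
## semi-axes a >= b in um at the given pixel size, axis along theta.
ellipseFrame <- function(nr, nc, cxUm, cyUm, aUm, bUm, theta, pixelSize) {
    xs <- (seq_len(nc) - 0.5) * pixelSize
    ys <- (seq_len(nr) - 0.5) * pixelSize
    X <- matrix(xs, nr, nc, byrow = TRUE) - cxUm
    Y <- matrix(ys, nr, nc) - cyUm
    u <- (cos(theta) * X + sin(theta) * Y) / aUm
    v <- (-sin(theta) * X + cos(theta) * Y) / bUm
    (u^2 + v^2 <= 1) * 1.0
}

## Shared synthetic plate suite (generated and analysed once per session).
.fixtureCache <- new.env(parent = emptyenv())

plateSuite <- function() {
    if (!is.null(.fixtureCache$plates)) return(.fixtureCache$plates)
    specs <- list(
        plateScanSpec(colonyCountPerWell = c(3L, 2L, 4L, 1L, 2L, 3L),
                      debrisCount = 3L, dispersedCellFraction = 0.4,
                      seed = 7L),
        plateScanSpec(colonyCountPerWell = c(2L, 3L, 1L, 3L, 2L, 2L),
                      debrisCount = 2L, dispersedCellFraction = 0.4,
                      illuminationAmplitude = 0.15, seed = 8L))
    plates <- lapply(specs, function(sp) {
        gen <- generatePlateScan(sp)
        res <- suppressWarnings(analyzePlate(gen$image))
        list(spec = sp, truth = gen$truth, image = gen$image, result = res)
    })
    .fixtureCache$plates <- plates
    plates
}

## Match detected colonies to planted truth; returns per-truth best match
## and the false-positive count.
matchColonies <- function(colonies, truth) {
    truth <- truth[truth$is_colony, , drop = FALSE]
    used <- integer()
    hits <- data.frame(truthId = truth$id, detected = NA_integer_,
                       relAreaErr = NA_real_)
    for (i in seq_len(nrow(truth))) {
        if (!nrow(colonies)) break
        d <- sqrt((colonies$cx_px - truth$cx_px[i])^2 +
                  (colonies$cy_px - truth$cy_px[i])^2)
        j <- which.min(d)
        if (d[j] < truth$radius_px[i]) {
            hits$detected[i] <- colonies$colony[j]
            hits$relAreaErr[i] <-
                colonies$area_px2[j] / truth$area_px2[i] - 1
            used <- c(used, j)
        }
    }
    list(hits = hits, falsePositives = nrow(colonies) - length(unique(used)))
}
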