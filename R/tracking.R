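## Track linking, exclusion gates, migration metrics and rose-plot export.

#' Link per-frame cell detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames:
#' detection pairs that are each other's nearest neighbour and closer than
#' `maxLinkDistance` are linked, iterating until no mutual pair remains.
#' Unmatched detections start new tracks; tracks left unmatched end. An
#' optional single-frame gap closing can bridge one missed detection.
#'
#' @param cells data.frame of per-frame detections with columns `frame`,
#'   `x_um`, `y_um` (as produced by [measureCells()] / [segmentStack()]).
#' @param gates a [GateParams-class]; supplies `maxLinkDistance` (um).
#' @param maxGap number of frames a track may skip (0, the default, or 1).
#' @return The input with a `track_id` column appended, ordered by
#'   `track_id` then `frame`. Empty input yields an empty table.
#' @examples
#' det <- data.frame(frame = rep(1:5, each = 1), x_um = 1:5, y_um = 0)
#' linkTracks(det, gateParams(maxLinkDistance = 2))
#' @export
linkTracks <- function(cells, gates = gateParams(), maxGap = 0L) {
    stopifnot(all(c("frame", "x_um", "y_um") %in% names(cells)))
    if (!nrow(cells)) {
        cells$track_id <- integer()
        return(cells)
    }
    maxGap <- as.integer(maxGap)
    cells <- cells[order(cells$frame), , drop = FALSE]
    cells$track_id <- NA_integer_
    frames <- sort(unique(cells$frame))
    nextId <- 1L
    ## active tracks: id, last x, y, last frame
    act <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      lastFrame = integer())
    rows <- split(seq_len(nrow(cells)), cells$frame)
    for (f in frames) {
        ri <- rows[[as.character(f)]]
        det <- cells[ri, , drop = FALSE]
        live <- act[f - act$lastFrame <= 1L + maxGap, , drop = FALSE]
        assigned <- rep(NA_integer_, length(ri))
        if (nrow(live) && length(ri)) {
            D <- outer(live$x, det$x_um, "-")^2 +
                 outer(live$y, det$y_um, "-")^2
            D[D > gates@maxLinkDistance^2] <- Inf
            freeT <- rep(TRUE, nrow(live)); freeD <- rep(TRUE, length(ri))
            repeat {
                Dm <- D
                Dm[!freeT, ] <- Inf; Dm[, !freeD] <- Inf
                if (!any(is.finite(Dm))) break
                linked <- FALSE
                for (ti in which(freeT)) {
                    j <- which.min(Dm[ti, ])
                    if (!is.finite(Dm[ti, j])) next
                    if (which.min(Dm[, j]) == ti) {
                        assigned[j] <- live$id[ti]
                        freeT[ti] <- FALSE; freeD[j] <- FALSE
                        linked <- TRUE
                    }
                }
                if (!linked) break
            }
        }
        newTrack <- which(is.na(assigned))
        if (length(newTrack)) {
            assigned[newTrack] <- seq.int(nextId,
                                          length.out = length(newTrack))
            nextId <- nextId + length(newTrack)
        }
        cells$track_id[ri] <- assigned
        upd <- data.frame(id = assigned, x = det$x_um, y = det$y_um,
                          lastFrame = f)
        act <- rbind(act[!(act$id %in% assigned), , drop = FALSE], upd)
        act <- act[f - act$lastFrame <= maxGap, , drop = FALSE]
    }
    cells <- cells[order(cells$track_id, cells$frame), , drop = FALSE]
    rownames(cells) <- NULL
    cells
}

#' Apply debris and track-length exclusion gates
#'
#' Removes small debris (below the dry-mass floor and/or the area floor,
#' combined with `gates@combine`), oversized objects (doublets and large
#' debris above the area ceiling) and, when a `track_id` column is present,
#' whole tracks observed in fewer than `minFrames` frames. Every removal is
#' recorded in an audit log with its reason, so
#' `nrow(input) == nrow(kept) + nrow(audit)`.
#'
#' @param objects data.frame of measured objects (columns `dry_mass_pg`,
#'   `area_um2`; optionally `track_id`, `frame`).
#' @param gates a [GateParams-class].
#' @return list with `kept` (surviving rows) and `audit` (removed rows with
#'   a `reason` column).
#' @examples
#' obj <- data.frame(dry_mass_pg = c(200, 400), area_um2 = c(900, 2000))
#' applyGates(obj, gateParams())$audit
#' @export
applyGates <- function(objects, gates = gateParams()) {
    stopifnot(all(c("dry_mass_pg", "area_um2") %in% names(objects)))
    lowMass <- objects$dry_mass_pg < gates@minDryMass
    lowArea <- objects$area_um2 < gates@minArea
    debris <- if (gates@combine == "or") lowMass | lowArea
              else lowMass & lowArea
    tooBig <- objects$area_um2 > gates@maxArea
    reason <- rep(NA_character_, nrow(objects))
    reason[debris] <- ifelse(lowMass[debris] & lowArea[debris],
                             "below dry-mass and area floors",
                             ifelse(lowMass[debris], "below dry-mass floor",
                                    "below area floor"))
    reason[tooBig & is.na(reason)] <- "above area ceiling"
    if ("track_id" %in% names(objects)) {
        keptSoFar <- is.na(reason)
        span <- table(objects$track_id[keptSoFar])
        short <- as.integer(names(span)[span < gates@minFrames])
        shortSel <- keptSoFar & objects$track_id %in% short
        reason[shortSel] <- "track below minimum frame count"
    }
    removed <- !is.na(reason)
    audit <- objects[removed, , drop = FALSE]
    audit$reason <- reason[removed]
    kept <- objects[!removed, , drop = FALSE]
    rownames(kept) <- rownames(audit) <- NULL
    list(kept = kept, audit = audit)
}

#' Migration metrics per track
#'
#' For each track: total path length (sum of stepwise Euclidean distances,
#' um), mean speed (path length over elapsed time, um/h) and displacement
#' (straight-line distance from the first to the last tracked position, um).
#' Displacement never exceeds path length.
#'
#' @param tracks data.frame with columns `track_id`, `t_min`, `x_um`,
#'   `y_um`; every track must have at least two time points.
#' @return data.frame with one row per track: `track_id`, `n_frames`,
#'   `elapsed_h`, `path_length_um`, `mean_speed_um_per_h`,
#'   `displacement_um`.
#' @examples
#' tr <- data.frame(track_id = 1, t_min = c(0, 24, 48),
#'                  x_um = c(0, 1, 2), y_um = 0)
#' migrationMetrics(tr)
#' @export
migrationMetrics <- function(tracks) {
    stopifnot(all(c("track_id", "t_min", "x_um", "y_um") %in% names(tracks)))
    sp <- split(tracks[, c("t_min", "x_um", "y_um")], tracks$track_id)
    if (any(vapply(sp, nrow, integer(1L)) < 2L))
        stop("every track needs at least 2 time points")
    res <- lapply(names(sp), function(id) {
        tr <- sp[[id]][order(sp[[id]]$t_min), ]
        steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
        elapsed <- (tr$t_min[nrow(tr)] - tr$t_min[1L]) / 60
        data.frame(track_id = utils::type.convert(id, as.is = TRUE),
                   n_frames = nrow(tr), elapsed_h = elapsed,
                   path_length_um = sum(steps),
                   mean_speed_um_per_h = sum(steps) / elapsed,
                   displacement_um = sqrt(
                       (tr$x_um[nrow(tr)] - tr$x_um[1L])^2 +
                       (tr$y_um[nrow(tr)] - tr$y_um[1L])^2))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Origin-centred track export for rose plots
#'
#' Translates every track so that its first point lies at the origin and
#' returns the long-form table used for rose plots (overlaid trajectories
#' visualising migration magnitude and isotropy). Invariant under any global
#' translation of the input coordinates.
#'
#' @param tracks data.frame with columns `track_id`, `t_min`, `x_um`,
#'   `y_um`.
#' @return data.frame `track_id`, `t_min`, `x_um`, `y_um` with each track's
#'   first point at (0, 0).
#' @examples
#' roseData(data.frame(track_id = 1, t_min = c(0, 24),
#'                     x_um = c(100, 110), y_um = c(50, 45)))
#' @export
roseData <- function(tracks) {
    stopifnot(all(c("track_id", "t_min", "x_um", "y_um") %in% names(tracks)))
    ord <- order(tracks$track_id, tracks$t_min)
    tr <- tracks[ord, c("track_id", "t_min", "x_um", "y_um"), drop = FALSE]
    first <- !duplicated(tr$track_id)
    x0 <- tr$x_um[first][match(tr$track_id, tr$track_id[first])]
    y0 <- tr$y_um[first][match(tr$track_id, tr$track_id[first])]
    tr$x_um <- tr$x_um - x0
    tr$y_um <- tr$y_um - y0
    rownames(tr) <- NULL
    tr
}
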