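## Readers/writers: phase stacks (multi-page float TIFF + JSON sidecar),
## plate images (PNG), GMT gene-set collections, CSV/JSON reports with a
## run manifest.

.SCHEMA_VERSION <- 1L

#' Write a phase stack to multi-page TIFF
#'
#' Frames are stored as 32-bit float pages. Because float TIFF storage is
#' only defined on `[0, 1]`, the stack is min/max-normalised on write and a
#' JSON sidecar (`<path>.json`) records the offset/scale together with the
#' pixel size, frame times and wavelength, so [readPhaseStack()] restores
#' calibrated values within float precision.
#'
#' @param stack a [PhaseStack-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writePhaseStack <- function(stack, path) {
    stopifnot(is(stack, "PhaseStack"))
    rg <- range(unlist(lapply(stack@frames, range)))
    offset <- rg[1L]
    scale <- if (diff(rg) > 0) diff(rg) else 1
    frames <- lapply(stack@frames, function(f) (f - offset) / scale)
    tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE,
                    compression = "none")
    meta <- list(schema_version = .SCHEMA_VERSION, offset = offset,
                 scale = scale, pixel_size_um = stack@pixelSize,
                 frame_times_min = stack@frameTimes,
                 wavelength_um = stack@wavelength)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read a phase stack from multi-page TIFF
#'
#' Reads float frames and, when present, the JSON sidecar written by
#' [writePhaseStack()] carrying calibration. Explicit arguments override
#' sidecar values; a missing pixel size is an error (phase morphometry is
#' meaningless without it). Multi-channel (e.g. RGB) TIFFs are rejected.
#'
#' @param path TIFF path.
#' @param pixelSize um/px; required when no sidecar is present.
#' @param frameInterval min between frames, used when no frame times are
#'   known.
#' @param wavelength um; default 0.55 when unknown.
#' @return A [PhaseStack-class].
#' @export
readPhaseStack <- function(path, pixelSize = NULL, frameInterval = NULL,
                           wavelength = NULL) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1L))))
        stop("expected single-channel phase stack, got multi-channel TIFF")
    meta <- NULL
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar))
        meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixelSize)) pixelSize <- meta$pixel_size_um
    if (is.null(pixelSize))
        stop("pixel size unknown: supply pixelSize= explicitly (um/px)")
    if (is.null(wavelength))
        wavelength <- if (!is.null(meta$wavelength_um)) meta$wavelength_um
                      else 0.55
    frames <- lapply(pages, function(p) {
        m <- matrix(as.numeric(p), nrow(p), ncol(p))
        if (!is.null(meta)) m * meta$scale + meta$offset else m
    })
    times <- if (!is.null(meta$frame_times_min) &&
                 length(meta$frame_times_min) == length(frames))
        meta$frame_times_min
    else (seq_along(frames) - 1) *
        (if (is.null(frameInterval)) 24 else frameInterval)
    phaseStack(frames, pixelSize = pixelSize, frameTimes = times,
               wavelength = wavelength)
}

#' Write an RGB plate image to PNG
#'
#' @param image array `rows x cols x 3` in `[0, 1]`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writePlateImage <- function(image, path) {
    png::writePNG(image, path)
    invisible(path)
}

#' Read an RGB plate image
#'
#' @param path PNG path.
#' @return array `rows x cols x 3` in `[0, 1]` (an alpha channel, if
#'   present, is dropped).
#' @export
readPlateImage <- function(path) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L)
        stop("expected an RGB plate scan, got a grayscale image")
    img[, , 1:3, drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member ids. Duplicate
#' members within a set are deduplicated with a warning; lines with fewer
#' than three fields raise an error naming the line.
#'
#' @param path GMT file path.
#' @return named list of character vectors; set descriptions in attribute
#'   `"descriptions"`. An empty file yields an empty collection with a
#'   warning.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        warning("empty GMT file: ", path)
        out <- list()
        attr(out, "descriptions") <- character()
        return(out)
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3L))
        stop("GMT line ", which(nf < 3L)[1L],
             " has fewer than 3 tab-separated fields")
    sets <- lapply(parts, function(p) {
        mem <- p[-(1:2)]
        if (anyDuplicated(mem)) {
            warning("duplicate member(s) in set '", p[1L],
                    "' deduplicated")
            mem <- unique(mem)
        }
        mem
    })
    names(sets) <- vapply(parts, `[`, character(1L), 1L)
    attr(sets, "descriptions") <- vapply(parts, `[`, character(1L), 2L)
    sets
}

#' Write a gene-set collection to GMT
#'
#' @param collection named list of character vectors.
#' @param path output path.
#' @param descriptions per-set description strings (recycled).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(collection, path, descriptions = "na") {
    descriptions <- rep_len(descriptions, length(collection))
    lines <- vapply(seq_along(collection), function(i)
        paste(c(names(collection)[i], descriptions[i], collection[[i]]),
              collapse = "\t"), character(1L))
    writeLines(lines, path)
    invisible(path)
}

#' Write stage results with a run manifest
#'
#' Writes every data.frame in `results` as `<name>.csv` (preceded by a
#' schema-version comment line) and every other element as `<name>.json`,
#' then emits `manifest.json` capturing the schema version, package
#' version, seed, configuration snapshot, input checksums and file list —
#' enough to reproduce a deterministic run. CSV bytes are deterministic for
#' identical inputs.
#'
#' @param results named list of data.frames and/or list-like objects.
#' @param outDir output directory (created if absent).
#' @param seed the run's RNG seed, recorded in the manifest.
#' @param config arbitrary configuration list snapshot.
#' @param inputs character vector of input file paths to checksum (md5).
#' @return Paths of the written files, invisibly.
#' @export
writeReports <- function(results, outDir, seed = NA_integer_,
                         config = list(), inputs = character()) {
    stopifnot(is.list(results), !is.null(names(results)),
              all(nzchar(names(results))))
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    if (file.access(outDir, 2L) != 0L)
        stop("output directory is not writable: ", outDir)
    written <- character()
    for (nm in names(results)) {
        x <- results[[nm]]
        if (is.data.frame(x)) {
            f <- file.path(outDir, paste0(nm, ".csv"))
            con <- file(f, "w")
            writeLines(paste0("# StromaQuant schema ", .SCHEMA_VERSION), con)
            utils::write.csv(x, con, row.names = FALSE)
            close(con)
        } else {
            f <- file.path(outDir, paste0(nm, ".json"))
            jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                                 force = TRUE)
        }
        written <- c(written, f)
    }
    manifest <- list(
        schema_version = .SCHEMA_VERSION,
        package = "StromaQuant",
        version = as.character(utils::packageVersion("StromaQuant")),
        seed = seed,
        config = config,
        inputs = if (length(inputs))
            stats::setNames(as.list(tools::md5sum(inputs)), inputs)
        else list(),
        files = basename(written),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    mf <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
    invisible(c(written, mf))
}

#' Read a report CSV written by [writeReports()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readReportCSV <- function(path) {
    utils::read.csv(path, comment.char = "#")
}
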