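## Reference-based morphometric subtype classification.

#' Canned reference population specifications
#'
#' Two reference BMSC phenotypes used throughout the examples and the
#' synthetic validation suite: a multipotent spindle-shaped phenotype
#' (elongated, length:width around 3.59, faster-moving) and a nullipotent
#' flat/spread phenotype (length:width around 2.016, larger spread area,
#' roughly half the speed). Spread parameters and motility are the
#' generator's own defaults (see the methods vignette for the rationale).
#'
#' @param n cells per population.
#' @return named list of two [PopulationSpec-class] objects
#'   (`spindle`, `flat`).
#' @examples
#' referencePopulations(100)
#' @export
referencePopulations <- function(n = 200L) {
    list(
        spindle = populationSpec(n, meanAspectRatio = 3.59,
                                 sdAspectRatio = 0.36, meanArea = 2500,
                                 sdArea = 375, meanSpeed = 20,
                                 persistenceTime = 60, meanDryMass = 400,
                                 sdDryMass = 60, label = "spindle"),
        flat = populationSpec(n, meanAspectRatio = 2.016,
                              sdAspectRatio = 0.20, meanArea = 4000,
                              sdArea = 600, meanSpeed = 10,
                              persistenceTime = 60, meanDryMass = 480,
                              sdDryMass = 70, label = "flat"))
}

#' Population of cells between two reference phenotypes
#'
#' Builds a [PopulationSpec-class] at the geometric midpoint of two
#' reference populations in (aspect ratio, area), with spread reduced to a
#' fraction of the references' relative spread. This emulates the
#' morphologically intermediate, "between categories" cells that a
#' margin-based classifier should report as unclassified.
#'
#' @param pop1,pop2 reference [PopulationSpec-class] objects.
#' @param nCells number of cells.
#' @param widthFraction spread relative to the references' mean relative
#'   spread; default 0.25 (intermediate cells are a tight band between the
#'   two phenotypes).
#' @return A [PopulationSpec-class] labelled `"between"`.
#' @examples
#' pops <- referencePopulations()
#' betweenPopulation(pops$spindle, pops$flat, 100)
#' @export
betweenPopulation <- function(pop1, pop2, nCells, widthFraction = 0.25) {
    gmid <- function(a, b) exp((log(a) + log(b)) / 2)
    relsd <- function(p) mean(c(p@sdAspectRatio / p@meanAspectRatio,
                                p@sdArea / p@meanArea))
    mAsp <- gmid(pop1@meanAspectRatio, pop2@meanAspectRatio)
    mArea <- gmid(pop1@meanArea, pop2@meanArea)
    w <- widthFraction * mean(c(relsd(pop1), relsd(pop2)))
    populationSpec(nCells, meanAspectRatio = mAsp,
                   sdAspectRatio = w * mAsp, meanArea = mArea,
                   sdArea = w * mArea,
                   meanSpeed = gmid(pop1@meanSpeed, pop2@meanSpeed),
                   persistenceTime = gmid(pop1@persistenceTime,
                                          pop2@persistenceTime),
                   meanDryMass = gmid(pop1@meanDryMass, pop2@meanDryMass),
                   sdDryMass = w * gmid(pop1@meanDryMass, pop2@meanDryMass),
                   label = "between")
}

.classFeatures <- function(cells) {
    stopifnot(all(c("aspect_ratio", "area_um2") %in% names(cells)))
    cbind(logAspect = log(cells$aspect_ratio), logArea = log(cells$area_um2))
}

#' Fit morphometric reference profiles
#'
#' Computes the mean vector and covariance of (log aspect ratio, log area)
#' for each of two reference populations. Both features are right-skewed
#' ratios/areas, hence the log transform. Degenerate references (singular
#' covariance, e.g. identical cells) raise an error.
#'
#' @param ref1,ref2 data.frames of reference cells with columns
#'   `aspect_ratio` and `area_um2` (at least 30 rows each).
#' @param labels character(2), names for the two references.
#' @return list of two [ReferenceProfile-class] objects.
#' @examples
#' pops <- referencePopulations(100)
#' r1 <- sampleMorphometry(pops$spindle, seed = 1)
#' r2 <- sampleMorphometry(pops$flat, seed = 2)
#' fitReferenceProfiles(r1, r2, labels = c("spindle", "flat"))
#' @export
fitReferenceProfiles <- function(ref1, ref2, labels = c("ref1", "ref2")) {
    mk <- function(cells, label) {
        ft <- .classFeatures(cells)
        if (nrow(ft) < 30L)
            stop("reference '", label, "' has fewer than 30 cells")
        cv <- stats::cov(ft)
        ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
        if (any(ev <= 0) || min(ev) / max(ev) < 1e-10)
            stop("singular covariance for reference '", label,
                 "'; the reference population is degenerate")
        new("ReferenceProfile", label = label, center = colMeans(ft),
            covariance = cv, nReference = nrow(ft))
    }
    list(mk(ref1, labels[1L]), mk(ref2, labels[2L]))
}

#' Classify cells against two reference profiles
#'
#' Each cell's Mahalanobis distance to both reference profiles is computed
#' in (log aspect ratio, log area) space. A cell is assigned to the nearer
#' reference only when the distances are clearly separated
#' (`|d1 - d2| >= margin`) and the nearer distance does not exceed `dMax`;
#' otherwise it is between categories and reported as unclassified. Ties
#' (`d1 == d2`) are always unclassified.
#'
#' @param cells data.frame with columns `aspect_ratio`, `area_um2`.
#' @param profiles list of two [ReferenceProfile-class] objects from
#'   [fitReferenceProfiles()].
#' @param margin minimum distance difference for assignment; default 1.
#' @param dMax maximum accepted Mahalanobis distance; default 3.
#' @return A [ClassificationReport-class]; classes are
#'   `<label1>-like`, `<label2>-like` and `unclassified`.
#' @examples
#' pops <- referencePopulations(100)
#' prof <- fitReferenceProfiles(sampleMorphometry(pops$spindle, seed = 1),
#'                              sampleMorphometry(pops$flat, seed = 2),
#'                              labels = c("spindle", "flat"))
#' classifyPopulation(sampleMorphometry(pops$spindle, 50, seed = 3), prof)
#' @export
classifyPopulation <- function(cells, profiles, margin = 1, dMax = 3) {
    if (!nrow(cells)) stop("no cells to classify")
    ft <- .classFeatures(cells)
    d1 <- sqrt(stats::mahalanobis(ft, profiles[[1L]]@center,
                                  profiles[[1L]]@covariance))
    d2 <- sqrt(stats::mahalanobis(ft, profiles[[2L]]@center,
                                  profiles[[2L]]@covariance))
    cls1 <- paste0(profiles[[1L]]@label, "-like")
    cls2 <- paste0(profiles[[2L]]@label, "-like")
    classes <- c(cls1, cls2, "unclassified")
    nearer <- ifelse(d1 < d2, cls1, cls2)
    ok <- abs(d1 - d2) >= margin & pmin(d1, d2) <= dMax & d1 != d2
    assigned <- ifelse(ok, nearer, "unclassified")
    counts <- vapply(classes, function(cl) sum(assigned == cl), integer(1L))
    new("ClassificationReport",
        counts = counts, fractions = counts / sum(counts),
        assignments = data.frame(cell = seq_len(nrow(cells)),
                                 d1 = d1, d2 = d2, class = assigned),
        margin = as.numeric(margin), dMax = as.numeric(dMax))
}
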