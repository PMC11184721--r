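## Synthetic protein-abundance tables and gene-set collections with
## ground truth.

#' Generate a synthetic abundance table with planted fold changes
#'
#' Per-protein baselines are log-normal across the proteome (median 1e6,
#' log-sd 1.5, mimicking the dynamic range of normalised peak areas);
#' per-sample multiplicative log-normal noise has coefficient of variation
#' `spec@cv` (so `cv = 0` gives exactly equal group means for unplanted
#' proteins). Planted proteins are scaled by their fold change in the
#' designated group. The first `nMatrisome` proteins carry a matrisome
#' annotation, split roughly evenly between core matrisome and
#' matrisome-associated divisions.
#'
#' @param spec an [AbundanceSpec-class]; all randomness flows from
#'   `spec@seed`.
#' @return list with
#'   \describe{
#'     \item{se}{`SummarizedExperiment` (assay `"abundance"`, colData
#'       `group`, rowData `division`/`category`)}
#'     \item{annotation}{matrisome annotation data.frame (`protein`,
#'       `division`, `category`)}
#'     \item{truth}{`effects` data.frame: per protein the true fold
#'       (group 1 over group 2)}
#'   }
#' @examples
#' tab <- generateAbundanceTable(abundanceSpec(nProteins = 20,
#'                                             nMatrisome = 5, seed = 1))
#' SummarizedExperiment::assay(tab$se)[1:3, ]
#' @export
generateAbundanceTable <- function(spec) {
    stopifnot(is(spec, "AbundanceSpec"))
    withr::with_seed(spec@seed, .generateAbundanceImpl(spec))
}

.generateAbundanceImpl <- function(spec) {
    nP <- spec@nProteins
    proteins <- sprintf("P%04d", seq_len(nP))
    pe <- spec@plantedEffects
    if (nrow(pe)) {
        bad <- setdiff(pe$protein, proteins)
        if (length(bad))
            stop("planted protein id(s) not in table: ",
                 paste(bad, collapse = ", "))
    }
    reps <- spec@replicatesPerGroup
    groups <- rep(spec@groups, each = reps)
    samples <- paste0(groups, "_", rep(seq_len(reps), 2L))
    base <- stats::rlnorm(nP, meanlog = log(1e6), sdlog = 1.5)
    ## true fold of group1 relative to group2
    foldG1 <- rep(1, nP)
    if (nrow(pe)) {
        i <- match(pe$protein, proteins)
        foldG1[i] <- ifelse(pe$direction == spec@groups[1L],
                            pe$fold, 1 / pe$fold)
    }
    mu <- cbind(matrix(base * foldG1, nP, reps),
                matrix(base, nP, reps))
    sdlog <- sqrt(log(1 + spec@cv^2))
    noise <- if (sdlog > 0)
        matrix(stats::rlnorm(nP * 2L * reps, meanlog = -sdlog^2 / 2,
                             sdlog = sdlog), nP)
        else matrix(1, nP, 2L * reps)
    mat <- mu * noise
    dimnames(mat) <- list(proteins, samples)

    nM <- spec@nMatrisome
    division <- rep("non-matrisome", nP)
    category <- rep(NA_character_, nP)
    if (nM > 0L) {
        nCore <- ceiling(nM * 85 / 175)   # core:associated split
        coreCats <- c("Collagens", "ECM Glycoproteins", "Proteoglycans")
        assocCats <- c("ECM Regulators", "ECM-affiliated Proteins",
                       "Secreted Factors")
        division[seq_len(nCore)] <- "core matrisome"
        category[seq_len(nCore)] <- sample(coreCats, nCore, replace = TRUE)
        if (nM > nCore) {
            division[(nCore + 1L):nM] <- "matrisome-associated"
            category[(nCore + 1L):nM] <- sample(assocCats, nM - nCore,
                                                replace = TRUE)
        }
    }
    annotation <- data.frame(protein = proteins, division = division,
                             category = category)
    annotation <- annotation[annotation$division != "non-matrisome", ,
                             drop = FALSE]
    rownames(annotation) <- NULL
    se <- makeAbundanceTable(mat, groups,
                             rowData = data.frame(division = division,
                                                  category = category))
    list(se = se, annotation = annotation,
         truth = list(effects = data.frame(protein = proteins,
                                           fold_group1 = foldG1)))
}

#' Generate a random gene-set collection
#'
#' Named sets sampled without replacement from a universe of ids; a fixture
#' generator for over-representation analyses (including over-size sets to
#' exercise the `K > 500` exclusion filter).
#'
#' @param nSets number of sets.
#' @param sizeRange integer range of set sizes (inclusive); sizes above the
#'   universe size raise an error.
#' @param universe character vector of ids.
#' @param seed RNG seed.
#' @return named list of character vectors, writable with [writeGMT()].
#' @examples
#' generateGeneSetCollection(3, c(2, 4), letters, seed = 1)
#' @export
generateGeneSetCollection <- function(nSets, sizeRange, universe,
                                      seed = 1L) {
    sizeRange <- as.integer(rep_len(sizeRange, 2L))
    if (max(sizeRange) > length(universe))
        stop("set size exceeds the universe size")
    withr::with_seed(seed, {
        sets <- lapply(seq_len(nSets), function(i) {
            sz <- if (sizeRange[1L] == sizeRange[2L]) sizeRange[1L]
                  else sample(seq.int(sizeRange[1L], sizeRange[2L]), 1L)
            sample(universe, sz)
        })
        names(sets) <- sprintf("SET_%03d", seq_len(nSets))
        sets
    })
}
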