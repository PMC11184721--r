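## Secretome statistics: normalisation, differential abundance, matrisome
## annotation, chi-square enrichment, gene-set over-representation.

#' Build an abundance table
#'
#' Wraps a protein x sample matrix of (non-negative) normalised peak areas
#' in a `SummarizedExperiment` with the sample group labels in `colData`.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns.
#' @param groups character/factor of length `ncol(values)`; at least two
#'   samples per group.
#' @param rowData optional data.frame of per-protein annotation.
#' @return A `SummarizedExperiment` with assay `"abundance"`.
#' @examples
#' m <- matrix(rlnorm(24), 4, 6,
#'             dimnames = list(paste0("P", 1:4), paste0("s", 1:6)))
#' makeAbundanceTable(m, rep(c("A", "B"), each = 3))
#' @export
makeAbundanceTable <- function(values, groups, rowData = NULL) {
    stopifnot(is.matrix(values), ncol(values) == length(groups))
    if (any(values < 0)) stop("abundances must be non-negative")
    if (any(table(groups) < 2L))
        stop("at least 2 samples per group are required")
    cd <- S4Vectors::DataFrame(group = as.character(groups),
                               row.names = colnames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = values), colData = cd)
    if (!is.null(rowData))
        SummarizedExperiment::rowData(se) <- rowData
    se
}

#' Normalise abundances to total ion intensity
#'
#' Each sample (column) is rescaled so that its total equals the mean of
#' the column totals, removing per-run loading/intensity differences. The
#' operation is idempotent and invariant to rescaling any single sample.
#'
#' @param se a `SummarizedExperiment` from [makeAbundanceTable()] (or a
#'   bare matrix).
#' @return Object of the same type with the normalised assay.
#' @examples
#' m <- matrix(c(1, 1, 3, 3), 2, 2, dimnames = list(c("P1", "P2"), NULL))
#' normalizeAbundance(m)
#' @export
normalizeAbundance <- function(se) {
    mat <- if (is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, "abundance") else se
    totals <- colSums(mat)
    if (any(totals <= 0)) stop("all-zero sample column")
    out <- sweep(mat, 2L, mean(totals) / totals, "*")
    if (is(se, "SummarizedExperiment")) {
        SummarizedExperiment::assay(se, "abundance") <- out
        se
    } else out
}

#' Differential protein abundance between groups
#'
#' Per protein: one-way ANOVA p-value across the sample groups and fold
#' change as the ratio of arithmetic group means (first group over second,
#' zero means floored at one tenth of the smallest positive abundance).
#' With two groups the ANOVA F statistic equals the squared pooled-variance
#' t statistic. Proteins constant across all samples get p = 1 with a
#' warning.
#'
#' @param se a `SummarizedExperiment` with assay `"abundance"` and a
#'   `group` column in `colData`, or a matrix plus `groups`.
#' @param groups group labels, required when `se` is a matrix.
#' @param alpha significance level; default 0.05.
#' @return data.frame with `protein`, `mean_<group>` per group,
#'   `fold_change`, `log2_fold`, `p_value`, `significant`.
#' @examples
#' sp <- abundanceSpec(nProteins = 50, nMatrisome = 10,
#'                     plantedEffects = data.frame(protein = "P1", fold = 8,
#'                                                 direction = "Y201"),
#'                     seed = 2)
#' tab <- generateAbundanceTable(sp)
#' head(differentialAbundance(tab$se))
#' @export
differentialAbundance <- function(se, groups = NULL, alpha = 0.05) {
    if (is(se, "SummarizedExperiment")) {
        mat <- SummarizedExperiment::assay(se, "abundance")
        groups <- SummarizedExperiment::colData(se)$group
    } else mat <- se
    if (is.null(groups)) stop("group labels are required")
    groups <- factor(groups, levels = unique(groups))
    if (nlevels(groups) < 2L) stop("at least 2 groups are required")
    if (any(table(groups) < 2L)) stop("at least 2 replicates per group")
    g1 <- levels(groups)[1L]; g2 <- levels(groups)[2L]
    m1 <- rowMeans(mat[, groups == g1, drop = FALSE])
    m2 <- rowMeans(mat[, groups == g2, drop = FALSE])
    pos <- mat[mat > 0]
    epsFloor <- if (length(pos)) min(pos) / 10 else .Machine$double.eps
    fold <- pmax(m1, epsFloor) / pmax(m2, epsFloor)
    pv <- apply(mat, 1L, function(v) {
        if (stats::var(v) == 0) return(NA_real_)
        stats::oneway.test(v ~ groups, var.equal = TRUE)$p.value
    })
    if (anyNA(pv)) {
        warning(sum(is.na(pv)),
                " protein(s) constant across samples; p set to 1")
        pv[is.na(pv)] <- 1
    }
    out <- data.frame(protein = rownames(mat), m1 = m1, m2 = m2,
                      fold_change = fold, log2_fold = log2(fold),
                      p_value = pv, significant = pv < alpha,
                      row.names = NULL)
    names(out)[2:3] <- paste0("mean_", c(g1, g2))
    out
}

#' Annotate proteins against a matrisome list
#'
#' Tags each protein with its matrisome division ("core matrisome",
#' "matrisome-associated") and category; proteins absent from the
#' annotation are "non-matrisome". Conflicting duplicate annotation entries
#' raise an error. The summary reports counts and the annotated percentage.
#'
#' @param proteins character vector of protein/gene ids.
#' @param annotation data.frame with columns `protein`, `division`,
#'   `category` (`division` within the closed set above).
#' @return list with `table` (protein, division, category) and `summary`
#'   (data.frame of division counts plus the overall annotated percentage
#'   as attribute `"percent_annotated"` and in the printed summary row).
#' @examples
#' ann <- data.frame(protein = c("FN1", "POSTN"),
#'                   division = "core matrisome",
#'                   category = c("ECM Glycoproteins", "ECM Glycoproteins"))
#' annotateMatrisome(c("FN1", "POSTN", "ALB"), ann)$summary
#' @export
annotateMatrisome <- function(proteins, annotation) {
    stopifnot(all(c("protein", "division") %in% names(annotation)))
    okDiv <- c("core matrisome", "matrisome-associated")
    if (!all(annotation$division %in% okDiv))
        stop("annotation divisions must be one of: ",
             paste(okDiv, collapse = ", "))
    if (!("category" %in% names(annotation)))
        annotation$category <- NA_character_
    dup <- annotation$protein[duplicated(annotation$protein)]
    if (length(dup)) {
        conf <- vapply(unique(dup), function(p) {
            sub <- annotation[annotation$protein == p, ]
            length(unique(sub$division)) > 1L
        }, logical(1L))
        if (any(conf))
            stop("conflicting divisions for: ",
                 paste(unique(dup)[conf], collapse = ", "))
        annotation <- annotation[!duplicated(annotation$protein), ]
    }
    i <- match(proteins, annotation$protein)
    tab <- data.frame(protein = proteins,
                      division = ifelse(is.na(i), "non-matrisome",
                                        annotation$division[i]),
                      category = ifelse(is.na(i), NA_character_,
                                        annotation$category[i]))
    counts <- c("core matrisome" = sum(tab$division == "core matrisome"),
                "matrisome-associated" =
                    sum(tab$division == "matrisome-associated"),
                "non-matrisome" = sum(tab$division == "non-matrisome"))
    nAnn <- sum(counts[1:2])
    summ <- data.frame(division = names(counts),
                       count = as.integer(counts),
                       percent = round(100 * counts / length(proteins), 1),
                       row.names = NULL)
    attr(summ, "percent_annotated") <-
        round(100 * nAnn / length(proteins), 1)
    list(table = tab, summary = summ)
}

#' Chi-square test for matrisome enrichment among significant proteins
#'
#' Two-category Pearson goodness-of-fit test (df = 1, no continuity
#' correction): observed matrisome count among the significant proteins
#' against the expectation under the background matrisome fraction,
#' `expected = n_significant * K_background / N_background`.
#'
#' @param observedK matrisome proteins observed among the significant set.
#' @param nSignificant number of significant proteins.
#' @param KBackground matrisome proteins in the background.
#' @param NBackground background (all detected) proteins.
#' @return data.frame with `observed`, `expected`, `chi2`, `df`, `p_value`.
#'   A warning is issued when the expected count falls below 1 (test
#'   validity).
#' @examples
#' chisqMatrisomeEnrichment(28, 44, 175, 861)
#' @export
chisqMatrisomeEnrichment <- function(observedK, nSignificant, KBackground,
                                     NBackground) {
    stopifnot(observedK <= nSignificant, KBackground <= NBackground)
    pK <- KBackground / NBackground
    expected <- nSignificant * pK
    if (expected < 1)
        warning("expected count below 1; chi-square approximation is weak")
    ## chisq.test's own small-count warning is superseded by the explicit
    ## expected-count check above
    ht <- suppressWarnings(
        stats::chisq.test(c(observedK, nSignificant - observedK),
                          p = c(pK, 1 - pK)))
    data.frame(observed = observedK, expected = expected,
               chi2 = unname(ht$statistic),
               df = as.integer(unname(ht$parameter)),
               p_value = ht$p.value)
}

#' Gene-set over-representation with size and FDR filters
#'
#' Hypergeometric upper-tail test of the overlap between a query list and
#' each gene set (restricted to the universe of detected proteins). Sets
#' with more than `KMax` members are excluded before testing (confounding,
#' relatively uninformative terms); Benjamini-Hochberg q-values are
#' computed over the tested sets and sets with q above `qMax` are filtered
#' from the ranked output. Ranking is by p ascending with ties broken by
#' the k/K ratio, descending.
#'
#' @param query character vector of significant protein ids (subset of
#'   `universe`; must be non-empty).
#' @param universe character vector of all detected protein ids.
#' @param collection named list of character vectors (see [readGMT()]).
#' @param qMax FDR threshold; default 0.05.
#' @param KMax maximum set size; default 500.
#' @return data.frame with one row per set: `set_name`, `k`, `K`,
#'   `k_over_K`, `p_value`, `q_value`, `passed_filters`. Rows passing both
#'   filters come first in rank order; excluded sets follow with
#'   `passed_filters = FALSE` (over-size sets carry `NA` p/q).
#' @examples
#' overrepresentation(c("a", "b"), letters[1:20],
#'                    list(s1 = c("a", "b", "c"), s2 = letters[10:14]))
#' @export
overrepresentation <- function(query, universe, collection, qMax = 0.05,
                               KMax = 500) {
    if (!length(query)) stop("empty query")
    if (!all(query %in% universe))
        stop("query must be a subset of the universe")
    universe <- unique(universe)
    query <- unique(query)
    N <- length(universe); n <- length(query)
    K <- vapply(collection, function(s)
        length(intersect(unique(s), universe)), integer(1L))
    k <- vapply(collection, function(s)
        length(intersect(unique(s), query)), integer(1L))
    testable <- K <= KMax & K > 0L
    p <- rep(NA_real_, length(collection))
    p[testable] <- stats::phyper(k[testable] - 1L, K[testable],
                                 N - K[testable], n, lower.tail = FALSE)
    q <- rep(NA_real_, length(collection))
    q[testable] <- stats::p.adjust(p[testable], method = "BH")
    res <- data.frame(set_name = names(collection), k = k, K = K,
                      k_over_K = ifelse(K > 0L, k / K, NA_real_),
                      p_value = p, q_value = q,
                      passed_filters = testable & !is.na(q) & q <= qMax,
                      row.names = NULL)
    ord <- order(!res$passed_filters, res$p_value, -res$k_over_K,
                 res$set_name)
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
    res
}
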