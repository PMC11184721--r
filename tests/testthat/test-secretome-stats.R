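test_that("normalisation equalises column totals and is idempotent", {
    m <- matrix(c(40, 60, 120, 180), 2L, 2L,
                dimnames = list(c("P1", "P2"), c("s1", "s2")))
    n1 <- normalizeAbundance(m)
    expect_equal(unname(colSums(n1)), c(200, 200))
    expect_equal(normalizeAbundance(n1), n1, tolerance = 1e-12)
    ## rescaling one sample's raw values leaves its normalised profile
    ## (column proportions) unchanged, and fold changes downstream with it
    m2 <- m; m2[, 2L] <- 2 * m2[, 2L]
    n2 <- normalizeAbundance(m2)
    expect_equal(sweep(n2, 2L, colSums(n2), "/"),
                 sweep(n1, 2L, colSums(n1), "/"), tolerance = 1e-12)
    ## equal totals: unchanged within numerical precision
    eq <- matrix(c(1, 3, 2, 2), 2L, 2L)
    expect_equal(normalizeAbundance(eq), eq, tolerance = 1e-12)
    expect_error(normalizeAbundance(cbind(m, s3 = c(0, 0))), "all-zero")
})

test_that("differential abundance reduces to the pooled t-test", {
    set.seed(11)
    m <- matrix(rlnorm(50 * 6, log(1e5), 1), 50L,
                dimnames = list(sprintf("P%02d", 1:50), NULL))
    g <- rep(c("A", "B"), each = 3L)
    da <- differentialAbundance(m, groups = g)
    ## with two groups the ANOVA F equals the squared pooled-variance t,
    ## so the p-values must agree to numerical precision
    pT <- apply(m, 1L, function(v) {
        tt <- t.test(v[g == "A"], v[g == "B"], var.equal = TRUE)
        pf(unname(tt$statistic)^2, 1, 4, lower.tail = FALSE)
    })
    expect_equal(da$p_value, unname(pT), tolerance = 1e-9)
    expect_equal(da$fold_change,
                 unname(rowMeans(m[, g == "A"]) / rowMeans(m[, g == "B"])),
                 tolerance = 1e-12)
})

test_that("identical groups give unit fold and constants warn", {
    half <- matrix(rlnorm(20 * 3, 10, 0.5), 20L)
    m <- cbind(half, half)
    rownames(m) <- sprintf("P%02d", 1:20)
    g <- rep(c("A", "B"), each = 3L)
    da <- differentialAbundance(m, groups = g)
    expect_true(all(abs(da$fold_change - 1) < 1e-12))
    expect_false(any(da$significant))
    flat <- matrix(5, 3L, 6L, dimnames = list(c("C1", "C2", "C3"), NULL))
    expect_warning(daf <- differentialAbundance(flat, groups = g),
                   "constant")
    expect_true(all(daf$p_value == 1))
})

test_that("planted folds are recovered under realistic noise", {
    pe <- data.frame(protein = c("P0001", "P0002"), fold = c(71, 104),
                     direction = c("Y201", "Y201"))
    tab <- generateAbundanceTable(abundanceSpec(nProteins = 200L,
                                                nMatrisome = 40L, cv = 0.1,
                                                plantedEffects = pe,
                                                seed = 6L))
    da <- differentialAbundance(tab$se)
    i <- match(c("P0001", "P0002"), da$protein)
    expect_lt(abs(da$fold_change[i[1L]] / 71 - 1), 0.10)
    expect_lt(abs(da$fold_change[i[2L]] / 104 - 1), 0.10)
    expect_true(all(da$significant[i]))
})

test_that("significance calls are calibrated on null proteins", {
    planted <- data.frame(protein = sprintf("P%04d", 1:8),
                          fold = c(4, 5, 8, 16, 32, 71, 104, 9.7),
                          direction = rep(c("Y201", "Y202"), 4L))
    tab <- generateAbundanceTable(abundanceSpec(nProteins = 2008L,
                                                nMatrisome = 100L,
                                                cv = 0.1,
                                                plantedEffects = planted,
                                                seed = 8L))
    da <- differentialAbundance(tab$se)
    i <- match(planted$protein, da$protein)
    ## every planted fold >= 4 is called
    expect_true(all(da$significant[i]))
    ## false-positive rate among the 2000 nulls is near alpha
    fpr <- mean(da$significant[-i])
    ci <- 2.58 * sqrt(0.05 * 0.95 / 2000)
    expect_lt(abs(fpr - 0.05), ci + 0.01)
})

test_that("matrisome annotation counts and percentages are exact", {
    ann <- data.frame(protein = c("FN1", "POSTN", "ACAN", "MMP2"),
                      division = c("core matrisome", "core matrisome",
                                   "core matrisome",
                                   "matrisome-associated"),
                      category = c("ECM Glycoproteins", "ECM Glycoproteins",
                                   "Proteoglycans", "ECM Regulators"))
    uni10 <- c(ann$protein, sprintf("X%d", 1:6))
    res <- annotateMatrisome(uni10, ann)
    expect_identical(res$table$division[res$table$protein == "X1"],
                     "non-matrisome")
    expect_equal(attr(res$summary, "percent_annotated"), 40.0)
    ## secretome-scale worked example: 85 core + 90 associated of 861
    big <- data.frame(protein = sprintf("M%03d", 1:175),
                      division = rep(c("core matrisome",
                                       "matrisome-associated"),
                                     c(85L, 90L)),
                      category = "x")
    uni <- c(big$protein, sprintf("N%03d", 1:686))
    res2 <- annotateMatrisome(uni, big)
    expect_identical(res2$summary$count[1:2], c(85L, 90L))
    expect_equal(attr(res2$summary, "percent_annotated"), 20.3)
    ## conflicting duplicate annotations are an error
    conf <- rbind(ann, data.frame(protein = "FN1",
                                  division = "matrisome-associated",
                                  category = "y"))
    expect_error(annotateMatrisome(uni10, conf), "conflicting")
})

test_that("chi-square enrichment matches its closed form", {
    res <- chisqMatrisomeEnrichment(28L, 44L, 175L, 861L)
    expect_equal(res$expected, 44 * 175 / 861, tolerance = 1e-12)
    expect_equal(res$chi2, oracleChi2(28, 44, 175, 861), tolerance = 1e-9)
    expect_identical(res$df, 1L)
    expect_lt(res$p_value, 1e-4)
    ## observed = expected -> statistic 0
    expect_equal(chisqMatrisomeEnrichment(10L, 20L, 50L, 100L)$chi2, 0)
    ## with a Yates correction the same counts would give ~48.3 (the
    ## correction is deliberately off, as the uncorrected form reproduces
    ## the reference statistic)
    e <- 44 * 175 / 861
    yates <- (abs(28 - e) - 0.5)^2 * (1 / e + 1 / (44 - e))
    expect_equal(yates, 48.34, tolerance = 0.01)
    expect_gt(res$chi2 - yates, 2)
    expect_warning(chisqMatrisomeEnrichment(0L, 4L, 10L, 100L), "below 1")
})

test_that("chi-square equals the closed form on random tuples", {
    set.seed(99)
    for (r in seq_len(1000L)) {
        N <- sample(50:2000, 1L)
        K <- sample.int(N - 1L, 1L)
        n <- sample.int(N - 1L, 1L)
        k <- sample.int(min(n, K), 1L)
        if (n * K / N < 1e-6 || n * (1 - K / N) < 1e-6) next
        expect_equal(
            suppressWarnings(
                chisqMatrisomeEnrichment(k, n, K, N))$chi2,
            oracleChi2(k, n, K, N), tolerance = 1e-9)
    }
})

test_that("over-representation matches exact combinatorics and filters", {
    uni <- letters[1:20]
    q <- letters[1:5]
    col <- list(hit = letters[1:5], miss = letters[10:14])
    res <- overrepresentation(q, uni, col, qMax = 1)
    i <- match("hit", res$set_name)
    expect_equal(res$p_value[i], 1 / choose(20, 5), tolerance = 1e-12)
    expect_equal(res$p_value[i], oracleHyperUpper(5, 5, 20, 5),
                 tolerance = 1e-12)
    ## forced overlap: query = universe = the only set
    forced <- overrepresentation(letters[1:5], letters[1:5],
                                 list(s = letters[1:5]), qMax = 1)
    expect_identical(forced$k, 5L)
    expect_identical(forced$K, 5L)
    expect_equal(forced$p_value, 1)
    expect_error(overrepresentation(character(), uni, col), "empty")
    expect_error(overrepresentation(c("zz"), uni, col), "subset")
})

test_that("hypergeometric p equals enumeration on small universes", {
    set.seed(7)
    for (r in seq_len(200L)) {
        N <- sample(5:25, 1L)
        uni <- sprintf("g%02d", seq_len(N))
        K <- sample.int(N, 1L)
        n <- sample.int(N, 1L)
        set <- sample(uni, K)
        q <- sample(uni, N)[seq_len(n)]
        res <- overrepresentation(q, uni, list(s = set), qMax = 1,
                                  KMax = 500)
        k <- length(intersect(set, q))
        expect_equal(res$p_value, oracleHyperUpper(k, K, N, n),
                     tolerance = 1e-12)
    }
})

test_that("ranking and the size / FDR filters follow the conventions", {
    uni <- sprintf("u%03d", 1:600)
    q <- uni[1:20]
    col <- list(
        tight = uni[1:10],          # k/K = 1
        loose = c(uni[1:8], uni[100:111]),  # same overlap-ish, lower k/K
        oversized = uni[1:501],
        unrelated = uni[301:320])
    res <- overrepresentation(q, uni, col, qMax = 0.05, KMax = 500)
    expect_false(res$passed_filters[res$set_name == "oversized"])
    expect_true(is.na(res$p_value[res$set_name == "oversized"]))
    ranked <- res$set_name[res$passed_filters]
    expect_false("oversized" %in% ranked)
    ## BH q-values dominate p and are monotone in p-rank
    ok <- !is.na(res$q_value)
    expect_true(all(res$q_value[ok] >= res$p_value[ok] - 1e-12))
    ord <- order(res$p_value[ok])
    expect_true(all(diff(res$q_value[ok][ord]) >= -1e-12))
    ## equal p (both overlaps forced to the minimum, p = 1), tie broken by
    ## k/K descending
    tie <- overrepresentation(
        letters[1:8], letters[1:10],
        list(lowRatio = c("c", "d", "i", "j"),
             highRatio = c("a", "b", "c", "i", "j")),
        qMax = 1)
    expect_equal(tie$p_value, c(1, 1))
    expect_identical(tie$set_name, c("highRatio", "lowRatio"))
    expect_equal(tie$k_over_K, c(3 / 5, 2 / 4))
})
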