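pygm <- list(c(1, 0, 0), c(12, 12, 8), c(10, 14, 14))
s10a9 <- list(c(0, 2, 0), c(7, 6, 12), c(10, 12, 11))

test_that("fold change is the ratio of group means with defined edges", {
    expect_equal(round(foldChange(c(15, 13, 7), c(41, 25, 37)), 2), 2.94)
    expect_equal(round(foldChange(c(1, 0, 0), c(12, 12, 8)), 2), 32.00)
    expect_equal(foldChange(c(3, 4, 5), c(3, 4, 5)), 1)
    expect_identical(foldChange(c(0, 0, 0), c(1, 2, 3)), Inf)
    expect_true(is.nan(foldChange(c(0, 0, 0), c(0, 0, 0))))
    expect_error(foldChange(c(-1, 0, 0), c(1, 1, 1)))
})

test_that("one-way ANOVA reproduces table F values and handles degeneracy", {
    expect_equal(round(anovaOneway(pygm)$statistic, 3), 35.848)
    expect_equal(round(anovaOneway(s10a9)$statistic, 3), 20.447)
    expect_identical(anovaOneway(pygm)$df, c(2L, 6L))
    # no variance anywhere -> F defined as 0
    flat <- anovaOneway(rep(list(c(1, 2, 3)), 3))
    expect_equal(flat$statistic, 0)
    expect_equal(flat$p.value, 1)
    # separation with zero within-group variance
    sep <- anovaOneway(list(c(1, 1, 1), c(5, 5, 5)))
    expect_identical(sep$statistic, Inf)
    expect_equal(sep$p.value, 0)
})

test_that("ANOVA agrees with stats::oneway.test on random inputs", {
    set.seed(11)
    for (i in 1:50) {
        g <- randomTriples()
        got <- anovaOneway(g)
        y <- unlist(g)
        f <- factor(rep(1:3, each = 3))
        ref <- stats::oneway.test(y ~ f, var.equal = TRUE)
        expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
        expect_equal(got$p.value, unname(ref$p.value), tolerance = 1e-9)
    }
})

test_that("F and fold change are invariant under count rescaling", {
    set.seed(12)
    for (i in 1:20) {
        g <- randomTriples()
        c0 <- runif(1, 0.1, 50)
        gs <- lapply(g, `*`, c0)
        expect_equal(anovaOneway(gs)$statistic, anovaOneway(g)$statistic,
                     tolerance = 1e-9)
        expect_equal(foldChange(gs[[1]], gs[[2]]),
                     foldChange(g[[1]], g[[2]]), tolerance = 1e-9)
    }
})

test_that("two-group F equals the squared pooled t statistic", {
    set.seed(13)
    for (i in 1:30) {
        x <- runif(3, 0, 30); y <- runif(3, 0, 30)
        f <- anovaOneway(list(x, y))$statistic
        t <- stats::t.test(x, y, var.equal = TRUE)$statistic
        expect_equal(f, unname(t)^2, tolerance = 1e-9)
    }
})

test_that("LSD p-values match the printed table values and emmeans", {
    expect_equal(round(lsdPairwiseP(pygm, c(2, 1)), 3), 0.001)
    expect_equal(round(lsdPairwiseP(s10a9, c(2, 1)), 3), 0.004)
    expect_equal(lsdPairwiseP(list(c(1, 2, 3), c(1, 2, 3))), 1)
    # independent oracle: unadjusted pairwise contrasts from emmeans
    set.seed(14)
    for (i in 1:10) {
        g <- randomTriples()
        d <- data.frame(y = unlist(g), f = factor(rep(1:3, each = 3)))
        em <- emmeans::emmeans(stats::lm(y ~ f, d), "f")
        ref <- as.data.frame(emmeans::contrast(em, "pairwise",
                                               adjust = "none"))
        expect_equal(lsdPairwiseP(g, c(2, 1)),
                     ref$p.value[ref$contrast == "f1 - f2"],
                     tolerance = 1e-9)
        expect_equal(lsdPairwiseP(g, c(3, 1)),
                     ref$p.value[ref$contrast == "f1 - f3"],
                     tolerance = 1e-9)
    }
})

test_that("degenerate LSD inputs give the boundary p-values", {
    same <- list(c(2, 2, 2), c(2, 2, 2))
    expect_equal(lsdPairwiseP(same), 1)
    apart <- list(c(2, 2, 2), c(5, 5, 5))
    expect_equal(lsdPairwiseP(apart), 0)
})

test_that("Dunnett T3 never undercuts Welch and handles extremes", {
    expect_equal(dunnettT3PairwiseP(list(c(1, 2, 3), c(1, 2, 3))), 1)
    expect_lt(dunnettT3PairwiseP(list(c(0, 0, 0), c(100, 101, 99))), 0.001)
    set.seed(15)
    for (i in 1:30) {
        g <- randomTriples()
        welch <- stats::t.test(g[[1]], g[[2]])$p.value
        expect_gte(dunnettT3PairwiseP(g, c(2, 1)), welch - 1e-12)
    }
})

test_that("Levene homogeneity test has near-nominal size and some power", {
    expect_equal(varianceHomogeneity(rep(list(c(1, 2, 3)), 3))$p.value, 1)
    set.seed(16)
    nullRej <- mean(replicate(600, {
        g <- list(rnorm(3, 0), rnorm(3, 5), rnorm(3, 10))
        varianceHomogeneity(g)$p.value < 0.05
    }))
    hetRej <- mean(replicate(600, {
        g <- list(rnorm(3, 0, 1), rnorm(3, 0, 1), rnorm(3, 0, 100))
        varianceHomogeneity(g)$p.value < 0.05
    }))
    expect_lt(nullRej, 0.12)   # size near the nominal 0.05 at n = 3
    expect_gt(hetRej, nullRej) # a 100x spread is detected more often
})

test_that("the cascade retains the printed 1-week survivors", {
    sce <- fixtureCountExperiment("T2")
    res <- applyFilterCascade(sce, comparison = "uuo1w", posthoc = "lsd")
    expect_identical(sum(res$trendFoldOK & res$minCountOK), 7L)
    expect_identical(sum(res$significant), 7L)
    # survivors containing a per-animal count of exactly 5 prove the >= read
    expect_true(res[res$accession == "IF172_RAT", "minCountOK"])
})

test_that("individual criteria reject the textbook counterexamples", {
    m <- rbind(lowCount = c(10, 10, 10, 5, 5, 4),
               badTrend = c(10, 10, 10, 40, 40, 1))
    colnames(m) <- c(paste0("s", 1:3), paste0("u", 1:3))
    sce <- SpectralCountExperiment(m, group = rep(c("sham", "uuo1w"),
                                                  each = 3))
    res <- applyFilterCascade(sce, comparison = "uuo1w")
    expect_false(res[res$accession == "lowCount", "minCountOK"])
    expect_false(res[res$accession == "badTrend", "trendFoldOK"])
    # unique-peptide information engages criterion 1
    res1 <- applyFilterCascade(sce, comparison = "uuo1w",
                               uniquePeptides = c(lowCount = 1L,
                                                  badTrend = 5L))
    expect_false(res1[res1$accession == "lowCount", "uniquePeptidesOK"])
    expect_true(res1[res1$accession == "badTrend", "uniquePeptidesOK"])
    expect_error(applyFilterCascade(sce, comparison = "uuo3w"), "uuo3w")
})

test_that("tightening thresholds never grows the survivor set", {
    set.seed(17)
    m <- matrix(rpois(50 * 6, 8), 50,
                dimnames = list(sprintf("P%02d_RAT", 1:50), NULL))
    colnames(m) <- c(paste0("s", 1:3), paste0("u", 1:3))
    sce <- SpectralCountExperiment(m, group = rep(c("sham", "uuo1w"),
                                                  each = 3))
    surv <- function(fold, minCount) {
        r <- applyFilterCascade(sce, comparison = "uuo1w",
                                criteria = FilterCriteria(
                                    foldThreshold = fold,
                                    minUuoCount = minCount))
        r$accession[r$trendFoldOK & r$minCountOK]
    }
    base <- surv(1.2, 2)
    expect_true(all(surv(2, 2) %in% base))
    expect_true(all(surv(1.2, 6) %in% base))
    expect_true(all(surv(3, 8) %in% surv(1.2, 2)))
})
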