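#' Group fold change of spectral-count abundances
#'
#' Ratio of arithmetic group means, UUO over sham. When the sham mean is 0
#' and the UUO mean positive the fold change is `Inf` (detected only after
#' obstruction); when both means are 0 the protein is not quantifiable and
#' `NaN` is returned so the cascade can exclude it.
#'
#' @param shamCounts,uuoCounts non-negative per-animal abundances.
#' @return Positive numeric, `Inf`, or `NaN` (both means zero).
#' @examples
#' foldChange(c(15, 13, 7), c(41, 25, 37))  # 2.94 at 2 dp
#' foldChange(c(1, 0, 0), c(12, 12, 8))     # 32
#' @export
foldChange <- function(shamCounts, uuoCounts) {
    stopifnot(all(shamCounts >= 0), all(uuoCounts >= 0))
    ms <- mean(shamCounts)
    mu <- mean(uuoCounts)
    if (ms == 0 && mu == 0) return(NaN)
    if (ms == 0) return(Inf)
    mu / ms
}

#' One-way fixed-effects ANOVA on per-animal abundances
#'
#' Classical one-way ANOVA across the experimental groups:
#' `F = (SS_between / df_between) / (SS_within / df_within)`, computed from
#' sums of squares so that degenerate inputs have a defined value: with no
#' variation at all (between or within) F is 0 and p is 1; with
#' between-group separation but zero within-group variance F is `Inf` and
#' p is 0. For the 3 x 3 design the degrees of freedom are (2, 6).
#'
#' @param groups list of numeric vectors, one per group, each of length
#'   >= 2; at least two groups.
#' @return List with `statistic` (F), `p.value`, and `df` (length 2).
#' @examples
#' anovaOneway(list(c(1, 0, 0), c(12, 12, 8), c(10, 14, 14)))$statistic
#' @export
anovaOneway <- function(groups) {
    stopifnot(is.list(groups), length(groups) >= 2L,
              all(lengths(groups) >= 2L))
    n <- lengths(groups)
    k <- length(groups)
    N <- sum(n)
    m <- vapply(groups, mean, numeric(1))
    grand <- sum(unlist(groups)) / N
    ssb <- sum(n * (m - grand)^2)
    ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
    df <- c(k - 1L, N - k)
    if (ssw == 0 && ssb == 0)
        return(list(statistic = 0, p.value = 1, df = df))
    if (ssw == 0)
        return(list(statistic = Inf, p.value = 0, df = df))
    f <- (ssb / df[1L]) / (ssw / df[2L])
    list(statistic = f, p.value = stats::pf(f, df[1L], df[2L],
                                            lower.tail = FALSE), df = df)
}

#' Fisher's LSD pairwise post-hoc p-value
#'
#' Unadjusted two-sided pairwise t-test using the pooled within-group mean
#' square of all groups in the ANOVA:
#' `t = |mean_i - mean_j| / sqrt(MSE * (1/n_i + 1/n_j))` with the pooled
#' within-group degrees of freedom (6 for the 3 x 3 design).
#'
#' @param groups list of per-group numeric vectors (all groups, not just
#'   the tested pair: they all contribute to MSE).
#' @param pair integer pair `c(i, j)` indexing the compared groups.
#' @return Two-sided p-value. `MSE = 0`: 1 if the two means are equal,
#'   otherwise 0.
#' @examples
#' g <- list(c(1, 0, 0), c(12, 12, 8), c(10, 14, 14))
#' lsdPairwiseP(g, c(2, 1))  # rounds to 0.001
#' @export
lsdPairwiseP <- function(groups, pair = c(2L, 1L)) {
    stopifnot(is.list(groups), length(groups) >= 2L, length(pair) == 2L,
              all(pair %in% seq_along(groups)), all(lengths(groups) >= 2L))
    n <- lengths(groups)
    m <- vapply(groups, mean, numeric(1))
    ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
    dfw <- sum(n) - length(groups)
    mse <- ssw / dfw
    diff <- abs(m[pair[1L]] - m[pair[2L]])
    if (mse == 0) return(if (diff == 0) 1 else 0)
    t <- diff / sqrt(mse * (1 / n[pair[1L]] + 1 / n[pair[2L]]))
    2 * stats::pt(t, dfw, lower.tail = FALSE)
}

#' Dunnett's T3 pairwise post-hoc p-value
#'
#' Unequal-variance post-hoc comparison: a Welch t statistic with
#' Welch-Satterthwaite degrees of freedom, adjusted for the family of all
#' pairwise comparisons. The exact T3 adjustment uses the studentized
#' maximum modulus distribution; here the conservative Sidak-style bound
#' `1 - (1 - p)^k` over the `k = choose(#groups, 2)` comparisons is used,
#' which never understates the adjusted p-value.
#'
#' @inheritParams lsdPairwiseP
#' @return Adjusted two-sided p-value, never below the unadjusted Welch p.
#' @export
dunnettT3PairwiseP <- function(groups, pair = c(2L, 1L)) {
    stopifnot(is.list(groups), length(groups) >= 2L, length(pair) == 2L,
              all(pair %in% seq_along(groups)), all(lengths(groups) >= 2L))
    x <- groups[[pair[1L]]]
    y <- groups[[pair[2L]]]
    vx <- stats::var(x) / length(x)
    vy <- stats::var(y) / length(y)
    diff <- abs(mean(x) - mean(y))
    k <- choose(length(groups), 2L)
    if (vx + vy == 0) return(if (diff == 0) 1 else 0)
    t <- diff / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1L) + vy^2 / (length(y) - 1L))
    p <- 2 * stats::pt(t, df, lower.tail = FALSE)
    min(1, 1 - (1 - p)^k)
}

#' Levene's test for homogeneity of group variances
#'
#' Levene's test on absolute deviations from the group means (via
#' [car::leveneTest] with `center = mean`). Used by the `"auto"` post-hoc
#' policy: LSD assumes equal variances, Dunnett's T3 does not.
#'
#' @param groups list of per-group numeric vectors.
#' @return List with `statistic` and `p.value`. Degenerate input in which
#'   every group is constant gives statistic 0, p 1.
#' @export
varianceHomogeneity <- function(groups) {
    stopifnot(is.list(groups), length(groups) >= 2L,
              all(lengths(groups) >= 2L))
    dev <- unlist(lapply(groups, function(x) abs(x - mean(x))))
    if (all(dev == 0) || stats::var(dev) == 0)
        return(list(statistic = 0, p.value = 1))
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    lt <- car::leveneTest(y, g, center = mean)
    list(statistic = lt[["F value"]][1L], p.value = lt[["Pr(>F)"]][1L])
}

#' Apply the three-criterion differential filter cascade
#'
#' Screens every protein of a [SpectralCountExperiment-class] for increased
#' abundance in one UUO group relative to sham:
#' \enumerate{
#'   \item identified by at least `minUniquePeptides` unique peptides
#'     (assumed satisfied when `uniquePeptides` is `NULL`, e.g. for count
#'     tables that were already identification-filtered);
#'   \item consistent upward trend — every UUO animal above the sham group
#'     mean — with a per-animal fold change (UUO animal count / sham group
#'     mean) above `foldThreshold` in at least one animal;
#'   \item every UUO animal count at least `minUuoCount`.
#' }
#' A protein is called `significant` when all three criteria hold, the
#' group-level fold change exceeds `foldThreshold`, and the post-hoc
#' p-value for UUO-vs-sham is below `alpha`. The ANOVA and the pooled MSE
#' use every group present in `x`, not just the compared pair. Under the
#' `"auto"` policy the post-hoc test is LSD unless Levene's test rejects
#' variance homogeneity (p < 0.05), in which case Dunnett's T3 is used.
#'
#' A Benjamini-Hochberg adjusted p-value column (`padjBH`, across the
#' proteins tested in the comparison) is emitted as supplementary output;
#' it is not part of the cascade, which applies no multiple-testing
#' correction.
#'
#' @param x a [SpectralCountExperiment-class] containing the sham group and
#'   the comparison group (other groups, when present, contribute to the
#'   ANOVA pooling).
#' @param comparison group label of the UUO group to compare against sham.
#' @param control label of the reference group, default `"sham"`.
#' @param criteria a [FilterCriteria-class].
#' @param uniquePeptides optional named integer vector, accession ->
#'   unique-peptide count, for criterion 1.
#' @param posthoc `"auto"`, `"lsd"` or `"t3"`.
#' @param alpha post-hoc significance level, default 0.05.
#' @return A [S4Vectors::DataFrame] sorted by accession with per-protein
#'   means, fold change, F statistic, ANOVA and post-hoc p, the three
#'   criterion flags, `significant`, and `padjBH`; the criteria and
#'   comparison are recorded in `metadata()`.
#' @export
applyFilterCascade <- function(x, comparison, control = "sham",
                               criteria = FilterCriteria(),
                               uniquePeptides = NULL,
                               posthoc = c("auto", "lsd", "t3"),
                               alpha = 0.05) {
    stopifnot(is(x, "SpectralCountExperiment"), is(criteria, "FilterCriteria"))
    posthoc <- match.arg(posthoc)
    grp <- groupLabels(x)
    for (g in c(control, comparison))
        if (!g %in% grp)
            stop(sprintf("group '%s' absent from the count matrix", g))
    cts <- spectralCounts(x)
    acc <- sort(rownames(cts))
    cts <- cts[acc, , drop = FALSE]
    lv <- c(control, setdiff(unique(grp), control))
    pairIdx <- c(match(comparison, lv), 1L)

    one <- function(a) {
        v <- cts[a, ]
        gl <- lapply(lv, function(l) unname(v[grp == l]))
        sham <- gl[[1L]]
        uuo <- gl[[pairIdx[1L]]]
        shamMean <- mean(sham)
        uuoMean <- mean(uuo)
        fc <- foldChange(sham, uuo)

        crit1 <- if (is.null(uniquePeptides)) TRUE
                 else !is.na(uniquePeptides[a]) &&
                      uniquePeptides[a] >= criteria@minUniquePeptides
        perFold <- if (shamMean > 0) uuo / shamMean
                   else ifelse(uuo > 0, Inf, NaN)
        trend <- if (criteria@requireConsistentTrend) all(uuo > shamMean)
                 else TRUE
        crit2 <- trend && any(perFold > criteria@foldThreshold, na.rm = TRUE)
        crit3 <- all(uuo >= criteria@minUuoCount)

        an <- anovaOneway(gl)
        method <- posthoc
        if (method == "auto")
            method <- if (varianceHomogeneity(gl)$p.value < 0.05) "t3"
                      else "lsd"
        pp <- if (method == "lsd") lsdPairwiseP(gl, pairIdx)
              else dunnettT3PairwiseP(gl, pairIdx)
        sig <- crit1 && crit2 && crit3 && !is.nan(fc) &&
               fc > criteria@foldThreshold && pp < alpha
        data.frame(accession = a, shamMean = shamMean, uuoMean = uuoMean,
                   foldChange = fc, fStatistic = an$statistic,
                   anovaP = an$p.value, posthocP = pp,
                   posthocMethod = method, uniquePeptidesOK = crit1,
                   trendFoldOK = crit2, minCountOK = crit3,
                   significant = sig)
    }
    res <- do.call(rbind, lapply(acc, one))
    if (is.null(res))
        res <- data.frame(accession = character(), shamMean = numeric(),
                          uuoMean = numeric(), foldChange = numeric(),
                          fStatistic = numeric(), anovaP = numeric(),
                          posthocP = numeric(), posthocMethod = character(),
                          uniquePeptidesOK = logical(),
                          trendFoldOK = logical(), minCountOK = logical(),
                          significant = logical())
    res$padjBH <- stats::p.adjust(res$posthocP, method = "BH")
    out <- S4Vectors::DataFrame(res)
    S4Vectors::metadata(out) <- list(criteria = criteria,
                                     comparison = comparison,
                                     control = control, alpha = alpha,
                                     posthocPolicy = posthoc)
    out
}

#' Round a differential table to reporting precision
#'
#' Reporting mirrors the field's tables: fold change at 2 decimals, F at
#' 3, p-values at 3; full precision stays in the unrounded object.
#'
#' @param res result of [applyFilterCascade()].
#' @return A base `data.frame` with rounded numeric columns.
#' @export
formatDifferentialTable <- function(res) {
    d <- as.data.frame(res)
    d$foldChange <- round(d$foldChange, 2)
    d$fStatistic <- round(d$fStatistic, 3)
    d$anovaP <- round(d$anovaP, 3)
    d$posthocP <- round(d$posthocP, 3)
    d$padjBH <- round(d$padjBH, 3)
    d$shamMean <- round(d$shamMean, 3)
    d$uuoMean <- round(d$uuoMean, 3)
    d
}
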