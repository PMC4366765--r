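test_that("the generator is deterministic and leaves the caller's RNG alone", {
    truth <- syntheticTruth(10, nDifferential = 3, seed = 5)
    set.seed(999)
    before <- runif(1)
    d1 <- generateDataset(truth, seed = 21)
    d2 <- generateDataset(truth, seed = 21)
    expect_identical(d1, d2)
    d3 <- generateDataset(truth, seed = 22)
    expect_false(identical(d1$runs$count, d3$runs$count))
    set.seed(999)
    expect_identical(runif(1), before)  # RNG state restored by withSeed
})

test_that("generated counts are non-negative integers with the right keys", {
    truth <- syntheticTruth(30, nDifferential = 5, dropoutRate = 0.2,
                            seed = 6)
    ds <- generateDataset(truth, seed = 6)
    expect_true(all(ds$runs$count >= 0))
    expect_true(all(ds$runs$count == floor(ds$runs$count)))
    expect_setequal(unique(ds$runs$accession), truth$accession)
    expect_identical(nrow(ds$runs), 30L * 3L * 3L * 3L)
    expect_error(generateDataset(transform(truth, base_mean = -1), seed = 1),
                 "invalid distribution")
})

test_that("replicate counts are centred on the animal mean", {
    # Monte-Carlo expectation check: no animal effect, small dispersion
    truth <- data.frame(accession = "SYN0001_RAT", base_mean = 12,
                        planted_fold = 1, dropout_rate = 0,
                        dispersion = 0.05)
    ds <- generateDataset(truth, nGroups = 2, nAnimals = 1,
                          nReplicates = 5000, animalSd = 0, seed = 8)
    expect_equal(mean(ds$runs$count), 12,
                 tolerance = 0.03)  # ~3 MC sds at this n
})

test_that("null folds sit near 1; planted folds land in the MC envelope", {
    truth <- syntheticTruth(300, nDifferential = 0, seed = 9)
    ds <- generateDataset(truth, seed = 9)
    agg <- lapply(split(ds$runs, ds$runs$animal),
                  aggregateTechnicalReplicates)
    design <- unique(ds$runs[c("animal", "group")])
    sce <- buildCountMatrix(agg, design)
    cts <- spectralCounts(sce)
    sham <- rowMeans(cts[, groupLabels(sce) == "sham"])
    uuo <- rowMeans(cts[, groupLabels(sce) == "uuo1w"])
    ratio <- uuo[sham > 0] / sham[sham > 0]
    expect_equal(median(ratio), 1, tolerance = 0.12)

    # planted fold 6, base mean 3, small dispersion; [2.59, 15.42] is the
    # 99% envelope of the aggregated fold estimate from 10,000 generator
    # draws at n = 3 animals (the estimate is wide at this sample size)
    tr6 <- data.frame(accession = "SYN0001_RAT", base_mean = 3,
                      planted_fold = 6, dropout_rate = 0, dispersion = 0.05)
    d6 <- generateDataset(tr6, nGroups = 2, seed = 1)
    a6 <- sapply(split(d6$runs, d6$runs$animal),
                 function(x) mean(x$count))
    g6 <- sapply(split(d6$runs, d6$runs$animal), function(x) x$group[1])
    est <- mean(a6[g6 == "uuo1w"]) / mean(a6[g6 == "sham"])
    expect_gt(est, 2.59)
    expect_lt(est, 15.42)
})

test_that("dropout zeroes replicates at about the configured rate", {
    truth <- syntheticTruth(100, dropoutRate = 0.3,
                            baseMeanRange = c(30, 60), seed = 10)
    ds <- generateDataset(truth, seed = 10)
    # at base mean >= 30 spontaneous zeros are negligible
    expect_equal(mean(ds$runs$count == 0), 0.3, tolerance = 0.05)
})

test_that("PSM export expansion matches counts, peptides and decoy settings", {
    counts <- c(P1_RAT = 3, P2_RAT = 0, P3_RAT = 2)
    psms <- generatePsmExport(counts, runId = "sham_1_1",
                              peptidesPerProtein = 2, seed = 11)
    p1 <- psms[psms$accessions == "P1_RAT", ]
    expect_identical(nrow(p1), 3L)
    expect_identical(length(unique(p1$peptide_sequence)), 2L)
    expect_false("P2_RAT" %in% psms$accessions)  # zero count, no rows
    expect_identical(sum(psms$decoy), 0L)        # decoyFraction 0

    withDec <- generatePsmExport(counts, runId = "r", decoyFraction = 0.4,
                                 seed = 12)
    expect_identical(sum(withDec$decoy), 2L)  # round(0.4 * 5)
    # round trip: at probability threshold 0 everything is retained
    expect_identical(nrow(filterPeptides(psms, minProbability = 0,
                                         maxFdr = 1)),
                     nrow(psms))
})

test_that("dataset TSVs round-trip byte-identically for the same seed", {
    truth <- syntheticTruth(8, nDifferential = 2, seed = 13)
    ds <- generateDataset(truth, seed = 13)
    f1 <- withr::local_tempfile(fileext = ".tsv")
    t1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    t2 <- withr::local_tempfile(fileext = ".tsv")
    writeSyntheticDataset(ds, f1, t1)
    writeSyntheticDataset(generateDataset(truth, seed = 13), f2, t2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(readLines(t1), readLines(t2))
})

test_that("packaged fixture tables load with their printed shapes", {
    t1 <- loadFixtureTable("T1")
    expect_identical(nrow(t1), 27L)
    expect_identical(t1$identified_proteins[t1$animal == "sham_1" &
                                            t1$replicate == 1], 305L)
    expect_identical(nrow(loadFixtureTable("T2")), 7L)
    # the published 3-week table has 19 rows; the transcription source
    # preserves 18 of them (documented in the vignette)
    expect_identical(nrow(loadFixtureTable("T3")), 18L)
    expect_error(loadFixtureTable("T9"))
    sce <- fixtureCountExperiment("T3")
    expect_identical(dim(sce), c(18L, 6L))
    expect_setequal(groupLabels(sce), c("sham", "uuo3w"))
})
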