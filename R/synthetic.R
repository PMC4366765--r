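#' Construct a synthetic ground-truth table
#'
#' One row per simulated protein: its baseline mean spectral count, the
#' fold change planted in the obstructed groups (1 for null proteins), the
#' technical-replicate dropout probability and the negative-binomial
#' dispersion. The first `nDifferential` proteins carry the planted fold.
#'
#' @param nProteins total number of proteins.
#' @param nDifferential number of up-regulated proteins (planted fold > 1).
#' @param plantedFold fold change planted in UUO groups, >= 1.
#' @param baseMeanRange range from which baseline means are drawn
#'   log-uniformly; chosen to span the printed count tables (singles to a
#'   few hundred spectra).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param dropoutRate probability that a replicate count is zeroed,
#'   in \[0, 1).
#' @param seed integer seed.
#' @return `data.frame` with columns `accession`, `base_mean`,
#'   `planted_fold`, `dropout_rate`, `dispersion`.
#' @export
syntheticTruth <- function(nProteins, nDifferential = 0L, plantedFold = 6,
                           baseMeanRange = c(2, 40), dispersion = 0.1,
                           dropoutRate = 0, seed) {
    stopifnot(nProteins >= 1L, nDifferential >= 0L,
              nDifferential <= nProteins, plantedFold >= 1,
              all(baseMeanRange > 0), dispersion >= 0,
              dropoutRate >= 0, dropoutRate < 1)
    withSeed(seed, {
        bm <- exp(stats::runif(nProteins, log(baseMeanRange[1L]),
                               log(baseMeanRange[2L])))
        data.frame(
            accession = sprintf("SYN%04d_RAT", seq_len(nProteins)),
            base_mean = bm,
            planted_fold = c(rep(plantedFold, nDifferential),
                             rep(1, nProteins - nDifferential)),
            dropout_rate = dropoutRate,
            dispersion = dispersion)
    })
}

#' Simulate a three-group spectral-count dataset
#'
#' Emulates the design of the urinary UUO study: `nGroups` groups (sham
#' first; the planted fold applies to every non-sham group) x `nAnimals`
#' animals x `nReplicates` technical replicates. For each protein and
#' animal, an animal-level mean is drawn as
#' `base_mean * fold * Lognormal(-animalSd^2/2, animalSd)` (mean-preserving
#' multiplicative biological variability), replicate counts are drawn
#' negative-binomial around that mean with the protein's dispersion
#' (Poisson when dispersion is 0), and each replicate count is
#' independently zeroed with probability `dropout_rate`. Fully reproducible
#' given `seed`.
#'
#' @param truth a [syntheticTruth()] table.
#' @param nGroups,nAnimals,nReplicates design dimensions (defaults 3,3,3).
#' @param animalSd lognormal sdlog of the animal effect; the default 0.3
#'   (CV about 31%) combined with the count noise reproduces the spread
#'   seen across real sham triples, from near-constant to wide.
#' @param seed integer seed.
#' @return List with `runs` (long `data.frame`: `group`, `animal`,
#'   `replicate`, `accession`, `count`) and `truth` (the input table).
#' @examples
#' tr <- syntheticTruth(5, nDifferential = 2, plantedFold = 6, seed = 1)
#' d <- generateDataset(tr, seed = 1)
#' head(d$runs)
#' @export
generateDataset <- function(truth, nGroups = 3L, nAnimals = 3L,
                            nReplicates = 3L, animalSd = 0.3, seed) {
    stopifnot(nGroups >= 2L, nAnimals >= 1L, nReplicates >= 1L,
              animalSd >= 0,
              all(c("accession", "base_mean", "planted_fold",
                    "dropout_rate", "dispersion") %in% colnames(truth)))
    if (any(truth$base_mean <= 0) || any(truth$planted_fold < 1) ||
        any(truth$dispersion < 0) || any(truth$dropout_rate < 0) ||
        any(truth$dropout_rate >= 1))
        stop("invalid distribution parameters in 'truth'")
    groups <- c("sham", "uuo1w", "uuo3w", paste0("grp", seq_len(nGroups)))
    groups <- groups[seq_len(nGroups)]
    withSeed(seed, {
        out <- vector("list", nGroups * nAnimals)
        idx <- 0L
        for (g in seq_len(nGroups)) {
            fold <- if (g == 1L) rep(1, nrow(truth)) else truth$planted_fold
            for (a in seq_len(nAnimals)) {
                animalMean <- truth$base_mean * fold *
                    stats::rlnorm(nrow(truth), -animalSd^2 / 2, animalSd)
                cnt <- matrix(0L, nrow(truth), nReplicates)
                for (r in seq_len(nReplicates)) {
                    mu <- animalMean
                    x <- ifelse(truth$dispersion > 0,
                                stats::rnbinom(nrow(truth),
                                               mu = mu,
                                               size = 1 / pmax(truth$dispersion,
                                                               1e-12)),
                                stats::rpois(nrow(truth), mu))
                    drop <- stats::runif(nrow(truth)) < truth$dropout_rate
                    cnt[, r] <- ifelse(drop, 0L, x)
                }
                idx <- idx + 1L
                out[[idx]] <- data.frame(
                    group = groups[g],
                    animal = sprintf("%s_a%d", groups[g], a),
                    replicate = rep(seq_len(nReplicates),
                                    each = nrow(truth)),
                    accession = rep(truth$accession, nReplicates),
                    count = as.integer(cnt))
            }
        }
        list(runs = do.call(rbind, out), truth = truth)
    })
}

#' Expand run counts into a synthetic PSM export
#'
#' Expands each protein's spectral count in one run into that many PSM
#' rows. Peptide sequences are synthesised so each protein has
#' `peptidesPerProtein` distinct peptides, assigned round-robin (so a count
#' of 3 with 2 configured peptides yields 3 rows over 2 sequences). Target
#' peptide probabilities are drawn from `Beta(targetShape)` (high), decoy
#' probabilities from `Beta(decoyShape)` (low); decoy rows are added in
#' proportion `decoyFraction` of the target PSMs.
#'
#' @param counts named numeric vector, accession -> spectral count, for
#'   one run.
#' @param runId run identifier written to every row.
#' @param decoyFraction fraction of decoy PSMs to add, in \[0, 0.5\].
#' @param peptidesPerProtein distinct peptides per protein, >= 1.
#' @param targetShape,decoyShape Beta shape pairs for target and decoy
#'   peptide probabilities (defaults give targets centred near 0.97 and
#'   decoys near 0.2).
#' @param seed integer seed.
#' @param path optional path; when given the export TSV is written there.
#' @return The PSM `data.frame` (invisibly when `path` is given).
#' @export
generatePsmExport <- function(counts, runId, decoyFraction = 0,
                              peptidesPerProtein = 3L,
                              targetShape = c(60, 2), decoyShape = c(2, 8),
                              seed, path = NULL) {
    stopifnot(decoyFraction >= 0, decoyFraction <= 0.5,
              peptidesPerProtein >= 1L, all(counts >= 0))
    counts <- counts[counts > 0]
    withSeed(seed, {
        aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
        pep <- function(n) vapply(seq_len(n), function(i)
            paste0(paste(sample(aa, 9, replace = TRUE), collapse = ""), "K"),
            character(1))
        rows <- lapply(names(counts), function(acc) {
            n <- as.integer(counts[[acc]])
            peps <- pep(peptidesPerProtein)
            data.frame(
                spectrum_id = sprintf("%s_%s_%04d", runId, acc, seq_len(n)),
                run_id = runId,
                peptide_sequence = peps[((seq_len(n) - 1L) %%
                                         peptidesPerProtein) + 1L],
                accessions = acc,
                peptide_probability = stats::rbeta(n, targetShape[1L],
                                                   targetShape[2L]),
                protein_probability = stats::rbeta(1, 90, 2),
                decoy = FALSE)
        })
        psms <- do.call(rbind, rows)
        if (is.null(psms)) psms <- data.frame(
            spectrum_id = character(), run_id = character(),
            peptide_sequence = character(), accessions = character(),
            peptide_probability = numeric(), protein_probability = numeric(),
            decoy = logical())
        nDecoy <- round(decoyFraction * nrow(psms))
        if (nDecoy > 0) {
            dec <- data.frame(
                spectrum_id = sprintf("%s_DECOY_%04d", runId,
                                      seq_len(nDecoy)),
                run_id = runId,
                peptide_sequence = pep(nDecoy),
                accessions = sprintf("DECOY%04d", seq_len(nDecoy)),
                peptide_probability = stats::rbeta(nDecoy, decoyShape[1L],
                                                   decoyShape[2L]),
                protein_probability = stats::rbeta(nDecoy, 2, 8),
                decoy = TRUE)
            psms <- rbind(psms, dec)
        }
        rownames(psms) <- NULL
        if (!is.null(path)) {
            writePsmExport(psms, path)
            return(invisible(psms))
        }
        psms
    })
}

#' Write the dataset in the TSV dialects consumed by the pipeline
#'
#' Raw run counts as a matrix TSV (first column `accession`, one column
#' per run named `<group>_<animal>_<replicate>`), and the ground-truth
#' table alongside.
#'
#' @param dataset result of [generateDataset()].
#' @param countsPath,truthPath output paths.
#' @return `countsPath`, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, countsPath, truthPath) {
    runs <- dataset$runs
    col <- sprintf("%s_%d", runs$animal, runs$replicate)
    acc <- sort(unique(runs$accession))
    cols <- unique(col)
    m <- matrix(0L, length(acc), length(cols),
                dimnames = list(acc, cols))
    m[cbind(match(runs$accession, acc), match(col, cols))] <- runs$count
    utils::write.table(data.frame(accession = acc, m, check.names = FALSE),
                       countsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(dataset$truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(countsPath)
}
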