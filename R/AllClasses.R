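#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' SpectralCountExperiment: proteins x animals spectral-count container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' per-animal spectral-count abundances (technical replicates already
#' aggregated, or raw per-run counts) with the experimental design in
#' `colData`: a `group` label per column (e.g. `"sham"`, `"uuo1w"`,
#' `"uuo3w"`) and an `animal` identifier.
#'
#' Validity requires a numeric, non-negative, NA-free `"counts"` assay and
#' the two design columns.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("SpectralCountExperiment", contains = "SummarizedExperiment")

setValidity("SpectralCountExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (!is.numeric(cts))
            msg <- c(msg, "'counts' must be numeric")
        else if (anyNA(cts))
            msg <- c(msg, "'counts' must not contain NA")
        else if (any(cts < 0))
            msg <- c(msg, "'counts' must be non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    for (col in c("group", "animal"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if ("animal" %in% colnames(cd) && anyDuplicated(cd$animal))
        msg <- c(msg, "duplicate animal identifiers in colData")
    if (length(msg)) msg else TRUE
})

#' Construct a SpectralCountExperiment
#'
#' @param counts numeric matrix, proteins in rows (rownames are accessions),
#'   animals in columns, non-negative.
#' @param group character vector of group labels, one per column.
#' @param animal character vector of animal identifiers, one per column;
#'   defaults to `colnames(counts)`.
#' @return A [SpectralCountExperiment-class] object.
#' @examples
#' m <- matrix(c(10, 2, 30, 4), nrow = 2,
#'             dimnames = list(c("P1_RAT", "P2_RAT"), c("s1", "u1")))
#' SpectralCountExperiment(m, group = c("sham", "uuo1w"))
#' @export
SpectralCountExperiment <- function(counts, group,
                                    animal = colnames(counts)) {
    counts <- as.matrix(counts)
    if (nrow(counts) > 0L && is.null(rownames(counts)))
        stop("'counts' must have rownames (protein accessions)")
    if (length(group) != ncol(counts))
        stop("'group' must have one label per column of 'counts'")
    if (is.null(animal))
        animal <- paste0(as.character(group), "_", seq_len(ncol(counts)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(group = as.character(group),
                                       animal = as.character(animal),
                                       row.names = colnames(counts)))
    new("SpectralCountExperiment", se)
}

#' @describeIn SpectralCountExperiment the counts assay.
#' @param x a `SpectralCountExperiment`.
#' @export
spectralCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn SpectralCountExperiment group label per animal column.
#' @export
groupLabels <- function(x) SummarizedExperiment::colData(x)$group

#' @describeIn SpectralCountExperiment animal identifier per column.
#' @export
animalIds <- function(x) SummarizedExperiment::colData(x)$animal

setMethod("show", "SpectralCountExperiment", function(object) {
    callNextMethod()
    tab <- table(groupLabels(object))
    cat("groups:", paste0(names(tab), "(", tab, ")", collapse = " "), "\n")
})

#' FilterCriteria: the three-criterion differential filter cascade
#'
#' Parameters of the conservative candidate filter applied to per-animal
#' spectral counts when comparing an obstructed (UUO) group against sham:
#' criterion 1 keeps proteins identified by at least `minUniquePeptides`
#' unique peptides; criterion 2 requires a consistent upward trend (every
#' UUO animal above the sham group mean) with a per-animal fold change
#' above `foldThreshold` in at least one animal; criterion 3 requires every
#' UUO animal's count to reach `minUuoCount` (compared as `>=`; the printed
#' survivor tables contain counts of exactly 5).
#'
#' @slot minUniquePeptides integer, default 2.
#' @slot foldThreshold numeric > 1, default 2.
#' @slot minUuoCount numeric >= 0, default 5.
#' @slot requireConsistentTrend logical, default TRUE.
#' @slot direction character, fixed to `"up"`: the cascade looks for
#'   proteins higher in the UUO group.
#' @export
setClass("FilterCriteria", representation(
    minUniquePeptides = "integer",
    foldThreshold = "numeric",
    minUuoCount = "numeric",
    requireConsistentTrend = "logical",
    direction = "character"))

setValidity("FilterCriteria", function(object) {
    msg <- character()
    if (length(object@minUniquePeptides) != 1L ||
        is.na(object@minUniquePeptides) || object@minUniquePeptides < 1L)
        msg <- c(msg, "minUniquePeptides must be a single integer >= 1")
    if (length(object@foldThreshold) != 1L || is.na(object@foldThreshold) ||
        object@foldThreshold <= 1)
        msg <- c(msg, "foldThreshold must be a single number > 1")
    if (length(object@minUuoCount) != 1L || is.na(object@minUuoCount) ||
        object@minUuoCount < 0)
        msg <- c(msg, "minUuoCount must be a single number >= 0")
    if (length(object@requireConsistentTrend) != 1L ||
        is.na(object@requireConsistentTrend))
        msg <- c(msg, "requireConsistentTrend must be TRUE or FALSE")
    if (!identical(object@direction, "up"))
        msg <- c(msg, "direction must be 'up' (up-in-UUO)")
    if (length(msg)) msg else TRUE
})

#' Construct filter-cascade criteria
#'
#' @param minUniquePeptides minimum unique peptides per protein (criterion 1).
#' @param foldThreshold fold-change threshold (criterion 2 and the final
#'   group-level gate).
#' @param minUuoCount minimum per-animal UUO spectral count (criterion 3,
#'   compared as `>=`).
#' @param requireConsistentTrend require all UUO animals above the sham mean.
#' @return A validated [FilterCriteria-class] object.
#' @examples
#' FilterCriteria()
#' FilterCriteria(foldThreshold = 3)
#' @export
FilterCriteria <- function(minUniquePeptides = 2L, foldThreshold = 2,
                           minUuoCount = 5, requireConsistentTrend = TRUE) {
    new("FilterCriteria",
        minUniquePeptides = as.integer(minUniquePeptides),
        foldThreshold = as.numeric(foldThreshold),
        minUuoCount = as.numeric(minUuoCount),
        requireConsistentTrend = as.logical(requireConsistentTrend),
        direction = "up")
}

#' @describeIn FilterCriteria fold-change threshold.
#' @param object a `FilterCriteria`.
#' @export
foldThreshold <- function(object) object@foldThreshold

#' @describeIn FilterCriteria per-animal UUO count threshold.
#' @export
minUuoCount <- function(object) object@minUuoCount

#' @describeIn FilterCriteria unique-peptide threshold.
#' @export
minUniquePeptides <- function(object) object@minUniquePeptides

setMethod("show", "FilterCriteria", function(object) {
    cat("FilterCriteria (up-in-UUO cascade)\n",
        "  1) unique peptides >= ", object@minUniquePeptides, "\n",
        "  2) consistent trend: ", object@requireConsistentTrend,
        ", per-animal fold > ", object@foldThreshold, " in >= 1 animal\n",
        "  3) every UUO animal count >= ", object@minUuoCount, "\n",
        sep = "")
})

#' PipelineConfig: end-to-end pipeline thresholds and policies
#'
#' Bundles every tunable of the identification -> quantification ->
#' differential pipeline. Defaults mirror the acceptance rules the analysis
#' was designed around: peptides at >= 90% probability with decoy FDR
#' < 0.1%, proteins at >= 95% probability with >= 2 peptides, a 2-fold
#' change threshold, a per-animal UUO count floor of 5 and alpha 0.05.
#'
#' @slot peptideProb,proteinProb,maxFdr,alpha fractions in (0, 1].
#' @slot criteria a [FilterCriteria-class].
#' @slot posthoc `"lsd"`, `"t3"` or `"auto"` (Levene-based switch).
#' @slot seed integer seed for any stochastic step (NA = none needed).
#' @export
setClass("PipelineConfig", representation(
    peptideProb = "numeric", proteinProb = "numeric", maxFdr = "numeric",
    criteria = "FilterCriteria", alpha = "numeric", posthoc = "character",
    seed = "integer"))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    chkFrac <- function(v, nm, lo = 0, hi = 1) {
        if (length(v) != 1L || is.na(v) || v < lo || v > hi)
            sprintf("%s must be a single value in [%g, %g]", nm, lo, hi)
        else character()
    }
    msg <- c(msg, chkFrac(object@peptideProb, "peptideProb"),
             chkFrac(object@proteinProb, "proteinProb"),
             chkFrac(object@alpha, "alpha"))
    if (length(object@maxFdr) != 1L || is.na(object@maxFdr) ||
        object@maxFdr <= 0 || object@maxFdr > 1)
        msg <- c(msg, "maxFdr must be in (0, 1]")
    if (!object@posthoc %in% c("lsd", "t3", "auto"))
        msg <- c(msg, "posthoc must be 'lsd', 't3' or 'auto'")
    if (length(msg)) msg else TRUE
})

#' Construct a pipeline configuration
#'
#' Unknown arguments are rejected (a misspelt threshold fails loudly rather
#' than being silently ignored).
#'
#' @param peptideProb minimum peptide identification probability.
#' @param proteinProb minimum protein identification probability.
#' @param maxFdr maximum decoy-estimated peptide FDR.
#' @param minUniquePeptides,foldThreshold,minUuoCount see [FilterCriteria()].
#' @param alpha post-hoc significance level.
#' @param posthoc post-hoc policy: `"lsd"`, `"t3"` or `"auto"`.
#' @param seed integer seed, or `NA` when no stochastic step is involved.
#' @return A validated [PipelineConfig-class].
#' @examples
#' pipelineConfig(foldThreshold = 3, posthoc = "lsd")
#' @export
pipelineConfig <- function(peptideProb = 0.90, proteinProb = 0.95,
                           maxFdr = 0.001, minUniquePeptides = 2L,
                           foldThreshold = 2, minUuoCount = 5,
                           alpha = 0.05, posthoc = "auto", seed = NA) {
    new("PipelineConfig",
        peptideProb = peptideProb, proteinProb = proteinProb, maxFdr = maxFdr,
        criteria = FilterCriteria(minUniquePeptides, foldThreshold,
                                  minUuoCount),
        alpha = alpha, posthoc = match.arg(posthoc, c("auto", "lsd", "t3")),
        seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n",
        sprintf("  peptide prob >= %.2f, decoy FDR < %.4f\n",
                object@peptideProb, object@maxFdr),
        sprintf("  protein prob >= %.2f\n", object@proteinProb),
        sprintf("  posthoc: %s, alpha: %.3f, seed: %s\n",
                object@posthoc, object@alpha, object@seed), sep = "")
    show(object@criteria)
})
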