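#' Read a tab-delimited PSM export
#'
#' Reads the simplified peptide-spectrum-match export dialect: one row per
#' PSM, header line, columns `spectrum_id`, `run_id`, `peptide_sequence`,
#' `accessions` (semicolon-joined when a peptide maps to several proteins),
#' `peptide_probability`, `protein_probability`, `decoy` (0/1). UTF-8,
#' `"."` decimal separator.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with the columns above, `decoy` as logical,
#'   validated (probabilities in \[0, 1\], spectrum ids unique within a run).
#' @export
readPsmExport <- function(path) {
    psms <- utils::read.delim(path, sep = "\t", header = TRUE,
                              colClasses = c(spectrum_id = "character",
                                             run_id = "character",
                                             peptide_sequence = "character",
                                             accessions = "character"),
                              fileEncoding = "UTF-8")
    needed <- c("spectrum_id", "run_id", "peptide_sequence", "accessions",
                "peptide_probability", "protein_probability", "decoy")
    missing <- setdiff(needed, colnames(psms))
    if (length(missing))
        stop("PSM export is missing column(s): ",
             paste(missing, collapse = ", "))
    psms <- psms[needed]
    psms$decoy <- as.logical(psms$decoy)
    validatePsms(psms)
    psms
}

#' Write a PSM table in the export dialect
#'
#' @param psms a PSM `data.frame` as returned by [readPsmExport()] or
#'   [generatePsmExport()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePsmExport <- function(psms, path) {
    out <- psms
    out$decoy <- as.integer(out$decoy)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

validatePsms <- function(psms) {
    for (col in c("peptide_probability", "protein_probability")) {
        p <- psms[[col]]
        bad <- which(is.na(p) | p < 0 | p > 1)
        if (length(bad))
            stop(sprintf("%s outside [0,1] for spectrum '%s' (row %d)",
                         col, psms$spectrum_id[bad[1]], bad[1]))
    }
    if (any(!nzchar(psms$accessions)))
        stop("every PSM needs at least one protein accession")
    dup <- duplicated(psms[c("run_id", "spectrum_id")])
    if (any(dup))
        stop(sprintf("duplicate spectrum '%s' within run '%s'",
                     psms$spectrum_id[which(dup)[1]],
                     psms$run_id[which(dup)[1]]))
    invisible(psms)
}

#' Peptide-level acceptance filter with decoy FDR control
#'
#' Retains PSMs whose identification probability reaches `minProbability`.
#' If the decoy-estimated false discovery rate of the retained set
#' (decoys / targets) still exceeds `maxFdr`, the probability cutoff is
#' raised to the smallest observed probability at which the estimated FDR
#' drops to `maxFdr` or below. Output preserves input order.
#'
#' The estimate is a global decoy FDR; a local-FDR model would need the
#' score distributions, which the simplified export does not carry.
#'
#' @param psms PSM `data.frame` (see [readPsmExport()]); the `decoy` flag
#'   must be set on every record.
#' @param minProbability minimum peptide probability, default 0.90.
#' @param maxFdr maximum decoy-estimated FDR, default 0.001 (0.1%).
#' @return The retained subset of `psms`, in input order.
#' @examples
#' psms <- data.frame(spectrum_id = c("s1", "s2"), run_id = "r1",
#'                    peptide_sequence = c("PEPTIDEK", "TIDEPEPR"),
#'                    accessions = "P1_RAT",
#'                    peptide_probability = c(0.95, 0.89),
#'                    protein_probability = 0.99, decoy = FALSE)
#' filterPeptides(psms)  # keeps s1 only
#' @export
filterPeptides <- function(psms, minProbability = 0.90, maxFdr = 0.001) {
    stopifnot(length(minProbability) == 1L, minProbability >= 0,
              minProbability <= 1, length(maxFdr) == 1L, maxFdr > 0,
              maxFdr <= 1)
    if (nrow(psms) == 0L) return(psms)
    validatePsms(psms)
    if (anyNA(psms$decoy))
        stop("'decoy' must be set (TRUE/FALSE) on every PSM")

    fdrAt <- function(cutoff) {
        keep <- psms$peptide_probability >= cutoff
        nT <- sum(keep & !psms$decoy)
        nD <- sum(keep & psms$decoy)
        if (nT == 0L) if (nD > 0L) Inf else 0
        else nD / nT
    }
    cutoff <- minProbability
    if (fdrAt(cutoff) > maxFdr) {
        candidates <- sort(unique(
            psms$peptide_probability[psms$peptide_probability >= cutoff]))
        ok <- candidates[vapply(candidates, fdrAt, numeric(1)) <= maxFdr]
        if (length(ok) == 0L) return(psms[0L, , drop = FALSE])
        cutoff <- ok[1L]
    }
    psms[psms$peptide_probability >= cutoff, , drop = FALSE]
}

#' Protein inference under the two-peptide rule
#'
#' Groups peptide-filtered PSMs by protein accession within each run.
#' A PSM whose peptide maps to several accessions contributes to the
#' spectral count of every mapped accession (shared-count policy), but
#' unique peptides are counted from peptides exclusive to one accession,
#' so shared peptides cannot satisfy the two-peptide rule by themselves.
#' Decoy PSMs never enter protein inference. Proteins failing the
#' probability or unique-peptide threshold are dropped.
#'
#' @param psms peptide-filtered PSM `data.frame`.
#' @param minProteinProbability minimum protein probability, default 0.95.
#' @param minUniquePeptides minimum exclusive peptides, default 2.
#' @return A `data.frame` with one row per accepted (run, accession):
#'   `run_id`, `accession`, `protein_probability` (max over the protein's
#'   PSMs), `unique_peptides`, `spectral_count`; sorted by run then
#'   accession.
#' @export
inferProteins <- function(psms, minProteinProbability = 0.95,
                          minUniquePeptides = 2L) {
    if (minUniquePeptides < 1L)
        stop("'minUniquePeptides' must be at least 1")
    stopifnot(minProteinProbability >= 0, minProteinProbability <= 1)
    empty <- data.frame(run_id = character(), accession = character(),
                        protein_probability = numeric(),
                        unique_peptides = integer(),
                        spectral_count = integer())
    if (nrow(psms) == 0L) return(empty)
    validatePsms(psms)
    psms <- psms[!psms$decoy, , drop = FALSE]
    if (nrow(psms) == 0L) return(empty)

    accList <- strsplit(psms$accessions, ";", fixed = TRUE)
    # peptides exclusive to a single accession, per run
    exclusive <- lengths(accList) == 1L
    long <- data.frame(
        run_id = rep(psms$run_id, lengths(accList)),
        accession = unlist(accList),
        peptide = rep(psms$peptide_sequence, lengths(accList)),
        protein_probability = rep(psms$protein_probability, lengths(accList)),
        exclusive = rep(exclusive, lengths(accList)))

    key <- interaction(long$run_id, long$accession, drop = TRUE)
    res <- do.call(rbind, lapply(split(long, key), function(d) {
        uniq <- unique(d$peptide[d$exclusive])
        data.frame(run_id = d$run_id[1L], accession = d$accession[1L],
                   protein_probability = max(d$protein_probability),
                   unique_peptides = length(uniq),
                   spectral_count = nrow(d))
    }))
    res <- res[res$protein_probability >= minProteinProbability &
               res$unique_peptides >= minUniquePeptides, , drop = FALSE]
    res <- res[order(res$run_id, res$accession), , drop = FALSE]
    rownames(res) <- NULL
    res
}
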