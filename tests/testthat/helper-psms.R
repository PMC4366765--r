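# Build a PSM data.frame with defaults; fields can be vectors.
makePsms <- function(n, probability = 0.95, decoy = FALSE,
                     accession = "P00001_RAT", peptide = NULL,
                     run = "sham_1_1", proteinProbability = 0.99) {
    if (is.null(peptide))
        peptide <- sprintf("PEPTIDE%03dK", seq_len(n))
    data.frame(
        spectrum_id = sprintf("sp%05d", seq_len(n)),
        run_id = rep_len(run, n),
        peptide_sequence = rep_len(peptide, n),
        accessions = rep_len(accession, n),
        peptide_probability = rep_len(probability, n),
        protein_probability = rep_len(proteinProbability, n),
        decoy = rep_len(decoy, n))
}

# Independent brute-force oracle for the FDR-controlled peptide filter:
# scan every candidate cutoff, pick the smallest achieving the FDR bound.
oracleFilter <- function(psms, minProbability, maxFdr) {
    cuts <- sort(unique(c(minProbability,
                          psms$peptide_probability[
                              psms$peptide_probability >= minProbability])))
    for (ct in cuts) {
        keep <- psms$peptide_probability >= ct
        nT <- sum(keep & !psms$decoy)
        nD <- sum(keep & psms$decoy)
        fdr <- if (nT == 0) (if (nD > 0) Inf else 0) else nD / nT
        if (fdr <= maxFdr) return(psms[keep, , drop = FALSE])
    }
    psms[0L, , drop = FALSE]
}

# Random three-group triples of non-negative "counts" for property tests.
randomTriples <- function(scale = 20) {
    lapply(1:3, function(i) round(stats::runif(3, 0, scale), 2))
}
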