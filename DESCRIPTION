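Package: uroSpectra
Title: Spectral-Count Differential Proteomics for Urinary Biomarker Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free spectral-counting analysis of urinary proteomes in the
    rat unilateral ureteral obstruction (UUO) model of renal tubular injury and
    interstitial fibrosis. Implements peptide- and protein-level identification
    acceptance filters (probability thresholds, decoy false-discovery-rate
    control, the two-peptide rule), technical-replicate aggregation under the
    all-replicates presence rule, group statistics (fold change, one-way ANOVA,
    Fisher LSD and Dunnett T3 post-hoc tests), and the three-criterion
    differential filter cascade, together with a negative-binomial synthetic
    count generator and packaged fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    emmeans
biocViews: Proteomics, MassSpectrometry, DifferentialExpression, Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
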