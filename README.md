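# uroSpectra

Label-free spectral-counting differential proteomics for urinary
biomarker discovery, built around the rat unilateral ureteral
obstruction (UUO) design: three groups (sham, UUO 1-week, UUO 3-week) ×
three animals × three technical LC-MS/MS injections per animal. The
1-week comparison targets biomarkers of renal tubular injury, the 3-week
comparison biomarkers of interstitial fibrosis.

**For whom:** proteomics analysts who have spectral-count exports (or a
protein × sample count matrix) from a small-n group comparison and want
the identification filters, replicate-aggregation rule and conservative
differential filter cascade of this study design as tested, reusable
code — plus a synthetic-count generator to benchmark it.

## The method

*Identification.* Peptides are accepted at probability ≥ 0.90 with a
decoy-estimated FDR < 0.1% (the probability cutoff is raised if needed);
proteins at probability ≥ 0.95 with ≥ 2 unique peptides (shared peptides
add to spectral counts but never to the unique-peptide tally).

*Quantification.* A protein's abundance for an animal is the mean
spectral count over the three technical replicates **only if observed
(count > 0) in all three**, otherwise 0. No between-sample
normalisation; the fold-change requirement below is the guard against
group differences in total spectral load.

*Differential screen.* For each protein, with per-animal abundances
x̄_sham and x̄_uuo:

- fold change FC = mean(x_uuo) / mean(x_sham), UUO over sham;
- one-way fixed-effects ANOVA across groups,
  F = (SSB/df_B)/(SSW/df_W), df (2, 6) for the 3 × 3 design;
- post-hoc pairwise p: Fisher's LSD,
  t = |x̄_i − x̄_j| / √(MSE·(1/n_i + 1/n_j)) on the pooled within-group
  MSE, or Dunnett's T3 (Welch t, Welch–Satterthwaite df, conservative
  Šidák-style family bound) when variances are unequal
  (Levene's test, policy `"auto"`);
- the three-criterion cascade: (1) ≥ 2 unique peptides; (2) every UUO
  animal above the sham group mean and per-animal fold > 2 in at least
  one animal; (3) every UUO animal count ≥ 5. A protein is *significant*
  if all criteria hold, FC > 2 and post-hoc p < 0.05.

## Worked example

The packaged fixtures transcribe the study's printed per-animal spectral
counts. Rebuilding the 1-week comparison and running the cascade:

```r
library(uroSpectra)
sce <- fixtureCountExperiment("T2")        # 7 proteins x 6 animals
res <- applyFilterCascade(sce, comparison = "uuo1w", posthoc = "lsd")
formatDifferentialTable(res)[, c("accession", "shamMean", "uuoMean",
                                 "foldChange", "fStatistic", "posthocP",
                                 "significant")]
```

```
 accession shamMean uuoMean foldChange fStatistic posthocP significant
  AMPN_RAT   11.667  34.333       2.94     17.785    0.014        TRUE
  CATD_RAT   19.000  94.667       4.98      9.328    0.038        TRUE
 IF172_RAT    0.333   9.667      29.00     12.645    0.024        TRUE
 LG3BP_RAT    6.667  34.667       5.20     12.600    0.024        TRUE
  PYGM_RAT    0.333  10.667      32.00     56.529    0.002        TRUE
 S10A9_RAT    0.667   8.333      12.50     15.114    0.018        TRUE
 S12A7_RAT    0.333   8.000      24.00     24.045    0.008        TRUE
```

All 7 proteins pass the cascade and are significant: aminopeptidase N is
2.94-fold higher in obstructed animals (41, 25, 37 spectra vs 15, 13, 7),
glycogen phosphorylase appears almost exclusively after obstruction
(fold 32), and so on. Fold changes match the published values at 2
decimals; the F and p columns here pool two groups (the fixture carries
no 1-week counts for 3-week-only proteins), which is why F differs from
the published three-group values except where all nine counts are
printed.

A seeded synthetic benchmark with planted effects:

```r
b <- simulateBenchmark(nNull = 200, nPlanted = 5, plantedFold = 10,
                       seed = 42)
b$recovery
#> $sensitivity
#> [1] 1
#> $fdp
#> [1] 0.2857143
```

All 5 planted fold-10 proteins are recovered; 2 of the 7 significant
calls are nulls (the cascade applies no multiple-testing correction, by
design — a supplementary BH column is emitted for readers who want one).

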