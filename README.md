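# stressig

Enhancer-driven gene-signature discovery and survival stratification for
pancreatic cancer, with a fully seeded synthetic-data generator that plants
ground truth for every stage of the pipeline.

## The science

Inflammatory cytokines (oncostatin-M) and hypoxia both activate STAT3 in
pancreatic ductal adenocarcinoma. Activated STAT3 binds DNA broadly, but its
transcriptional consequences depend on chromatin: some tumor cell lines hold
the relevant enhancers open ("inducible" lines, capable of upregulating
integrin β3 and an associated invasion program), others keep them closed.
`stressig` implements the computational pipeline built on that model:

1. **Shared differential binding** — intersect differential STAT3 ChIP-seq
   peaks (adjusted p ≤ 0.05, top 200 by score per condition) across the two
   stress stimuli.
2. **STAT-open regions** — keep shared regions that ATAC-seq shows
   accessible only in inducible lines.
3. **Candidate catalog** — map the surviving regions to target genes through
   an enhancer–gene catalog plus nearest-TSS annotation.
4. **Signature selection** — compute all pairwise Pearson correlations among
   catalog genes across a tumor cohort (Holm-adjusted), rank genes by how
   many significant pairs they join, and keep the top half of the distinct
   ranks: the STRESS signature.
5. **Hazard directions and stratification** — give each signature gene a
   direction from its best-cutoff log-rank split (hazardous vs protective),
   score patients by mean signature expression with protective genes
   inverted, and stratify at the best log-rank cutoff (binary Cox hazard
   ratio, Breslow ties).
6. **Cell-line inducibility signature** — Welch-t differential expression
   (|log2FC| > 1, FDR < 0.05) with a within-group SD robustness filter,
   scored on new lines by a monotone-invariant rank score.
7. **Single-cell corroboration** — QC gates, extreme-decile stratification
   of the pooled malignant population on integrin-β3 expression, treated/
   naive enrichment folds, and a windowed relative-expression CNV score.

All functions take and return tibbles or plain matrices; model objects
implement `print()`, `tidy()`, `glance()`, and `autoplot()` where they
apply. See the methods vignette
(`vignettes/stress-signature-methods.Rmd`) for the statistical details,
parameter defaults, and generator design.

## Running the tests

```r
testthat::test_dir("tests/testthat", package = "stressig",
                   load_package = "installed")
```

The suite contains per-module oracle tests (textbook re-implementations of
Holm/BH, brute-force interval intersection, Mann–Whitney enumeration,
size-factor definitions) plus `test-acceptance.R`, which checks end-to-end
planted-truth recovery across 20 seeds, Cox/KM parameter recovery, log-rank
type-I error, scoring invariances, QC determinism, and enrichment recovery.

## Worked example

A complete synthetic study at seed 1 — simulate, derive the signature, and
stratify the cohort:

```r
library(stressig)
run <- run_full_synthetic(sim_config(seed = 1), include_scrna = FALSE)
run$report
#> # A tibble: 12 × 2
#>    metric                              value
#>    <chr>                               <dbl>
#>  1 n_shared_regions                 1.4 e+ 1
#>  2 n_stat_open_regions              1.4 e+ 1
#>  3 stat_open_regions_exact          1   e+ 0
#>  4 n_candidate_genes                5.4 e+ 1
#>  5 catalog_matches_truth            1   e+ 0
#>  6 n_selected_genes                 1.8 e+ 1
#>  7 n_module_genes_correct_direction 1.8 e+ 1
#>  8 n_intruders                      0
#>  9 hr_high_vs_low                   5.22e+ 0
#> 10 logrank_p                        3.12e-16
#> 11 n_inducible_signature_genes      9.3 e+ 1
#> 12 panel_classification_accuracy    1   e+ 0
```

The pipeline recovers all 14 planted STAT-open regions, the full 54-gene
candidate catalog, and the 18-gene module with every hazard direction
correct (10 hazardous, 8 protective, no intruders):

```r
run$signature
#> Gene signature: STRESS
#>   up  ( 10 ): G0001, G0002, G0003, G0004, G0005, G0006, G0007, G0008 ...
#>   down( 8 ): G0011, G0012, G0013, G0014, G0015, G0016, G0017, G0018
#>   provenance: n_regions=14, n_candidates=54, n_ranked=54, n_selected=18,
#>     rank_threshold=1, n_up=10, n_down=8, alpha=0.05, use_adjusted=TRUE
#>   provenance tables: regions, catalog, ranking, directions

run$stratification
#> Best-cutoff stratification
#>   cutoff = 0.7272 (scanned 88), n_high = 88, n_low = 89
#>   log-rank chi2 = 66.726, p = 3.12e-16
#>   HR (high vs low) = 5.220, p = 7.68e-14
```

The measured hazard ratio of 5.22 (generating value 6, n = 177, 40%
censoring) and the 93-gene inducibility signature with 10/10 correct
cell-line calls complete the truth-recovery picture. `autoplot()` on
`run$stratification` or on any `km_curve` draws the survival curves;
`glance(run$stratification$cox)` gives the one-row Cox summary.

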