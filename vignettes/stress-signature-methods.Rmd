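---
title: "Methods: enhancer-driven signature discovery and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer-driven signature discovery and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressig)
```

## Scientific background

Inflammatory and hypoxic stress in pancreatic ductal adenocarcinoma (PDAC)
converge on STAT3: cytokines such as oncostatin-M and low oxygen both produce
STAT3 phosphorylated at tyrosine 705, which binds DNA. Whether that binding
has transcriptional consequences at a given locus depends on chromatin:
some tumor cell lines hold the relevant enhancers open ("inducible" lines,
able to upregulate integrin β3 and, with it, an adhesion/invasion program),
others keep them closed ("non-inducible"). This package implements the
computational arm of that model:

1. find genomic regions bound by activated STAT3 under *both* stress
   stimuli (shared differential ChIP-seq peaks),
2. keep those that are chromatin-accessible *only* in inducible lines
   ("STAT-open" regions; ATAC-seq cross-reference),
3. map the surviving regions to candidate target genes through an
   enhancer–gene catalog,
4. reduce the candidates to a compact prognostic signature by
   co-expression-frequency ranking in a tumor cohort,
5. assign each signature gene a hazard direction from survival data and
   score patients, stratifying them at the best log-rank cutoff, and
6. corroborate the program in single-cell data: stratify malignant cells by
   the extreme deciles of integrin-β3 expression and quantify how strongly
   the high state is enriched in chemotherapy-exposed tumors.

Every stage operates on plain tabular types (tibbles and matrices), and a
seeded generator plants ground truth for all of them, so the complete chain
is testable end to end without any external download.

## Stage parameters and their defaults

### Shared differential peaks and STAT-open regions

`shared_differential_peaks()` gates each condition's differential peak table
at adjusted p ≤ 0.05 (`alpha`), keeps the `top_n = 200` peaks by score,
intersects the two sets, and merges overlapping shared intervals.
`stat_open_regions()` then keeps regions overlapping ≥ 1 accessibility peak
from inducible lines and none from non-inducible lines. Coordinates follow
the BED convention (0-based, half-open); overlap queries run through
`IRanges` with the +1 shift applied internally.

### Candidate catalog and signature derivation

`annotate_peaks()` reports, per region, every overlapping enhancer record
(with its linked genes) plus the nearest transcription start site by region
midpoint, with distances signed by gene strand. The union of linked genes is
the candidate catalog. `derive_stress_signature()` then:

* computes all pairwise Pearson correlations among catalog genes across the
  tumor cohort (`pearson_pairs()`), Holm-adjusted across all pairs;
* ranks genes by the number of significant pairs they participate in
  (adjusted p ≤ 0.05), using competition ranking;
* keeps the top half of the *distinct* ranks (`select_top_half()`:
  `ceiling(n_distinct_ranks / 2)`), excluding genes with zero significant
  pairs;
* assigns each selected gene a hazard direction by splitting the cohort at
  the gene's best log-rank cutoff and reading the sign of the binary Cox
  coefficient (`survival_direction()`); directions whose fits are
  unconvincing (p > 0.5) are flagged.

### Inducibility signature

`derive_inducible_signature()` contrasts inducible against non-inducible
lines with Welch t tests on log2 size-factor-normalized counts, keeps genes
with |log2 fold change| > 1 and BH FDR < 0.05, and then drops genes whose
within-group SD of `log2(normalized + 1)` exceeds 2 — a robustness filter
against genes that pass the mean-difference gate only through a few extreme
samples. Scoring new samples uses `rank_score()` (see below) and
`classify_inducibility()`, which calls lines inducible / non-inducible
outside a ± 0.5 z band.

### Rank scoring

`rank_score()` ranks all G genes within each sample (midrank ties), takes
the mean rank of the signature's up set, and min–max normalizes it with the
closed-form extremes for a k-gene set, (k+1)/2 and (2G−k+1)/2; a down set is
scored the same way and subtracted. The score is therefore invariant under
any strictly monotone per-sample transform of expression — normalization
choices upstream cannot change it.

### Survival stratification

`best_cutoff()` emulates the web-tool procedure used for survival claims:
score each patient (mean signature expression with down genes inverted),
consider every observed score whose split leaves both groups within the
[`lower_q`, `upper_q`] = [0.25, 0.75] quantile band, pick the cutoff
minimizing the log-rank p, and report the binary Cox hazard ratio
(Breslow ties) of high vs low. Ties among cutoffs resolve toward the
median. Setting `lower_q = upper_q = 0.5` reproduces a median split.
`censor_at()` administratively censors follow-up at a horizon before
stratification when desired.

### Single-cell stage

`qc_filter()` applies four gates in a fixed order — ≥ 200 detected genes
per cell, ≥ 10 cells per gene, mitochondrial and ribosomal count fractions
each ≤ 15% (separate gates), and detected genes ≤ the 98th percentile — and
returns a per-gate removal report. `normalize_cells()` scales each cell to
the median total count and applies log1p. `stratify_extremes()` labels
exactly ⌊qN⌋ cells High and ⌊qN⌋ Low (q = 0.10) on the pooled malignant
population, with deterministic tie-breaking (total counts descending, then
cell id). `enrichment_fold()` is the ratio of the proportion of High cells
among treated cells to that among naive cells, with a flagged Haldane
correction only when a zero cell occurs. `cnv_window_score()` replaces an
HMM-based copy-number caller with its windowing core: reference-relative
log expression clipped at ± 3 reference SDs, averaged over a 250-gene
moving window, with the mean squared profile as a per-cell burden.

## The synthetic generator

`sim_config()` fixes the study conditions; `run_full_synthetic()` executes
the whole chain against them and reports truth recovery. Design points:

* **Geometry.** One synthetic chromosome, genes on a 100-kb grid. Each
  enhancer lives in a window private to its home gene, so planted
  enhancer–gene links are unambiguous. 14 shared-responsive enhancers
  target exactly the 54 candidate genes (1–5 targets each); the first
  candidate gene plays the integrin-β3 role, with one enhancer centered
  13.6 kb upstream of its TSS and a second 51.6 kb downstream. Background
  peaks occupy windows beyond the gene grid and are condition-disjoint.
* **Counts.** Negative-binomial with dispersion 0.03
  (`nb_dispersion`). This value is chosen so that the pipeline's own
  design-power assumptions hold: with 5 vs 5 cell lines, the Welch-t/BH
  stage can recover a 93-gene planted program, and the end-to-end run
  recovers ≥ 16 of 18 module genes in ≥ 18 of 20 seeds. At dispersion
  0.15 the same stage recovers barely half the program — the generator
  would then be testing a study the pipeline was never claimed to power.
* **Bulk cohort.** 177 tumors; a latent activation state (Bernoulli ½)
  shifts the 10 hazardous module genes up and the 8 protective genes down
  by 2 log2 units, planting the co-expression structure the correlation
  stage detects. Event times are exponential with hazard ratio 6 for
  activated tumors; censoring times are uniform on (0, τ) with τ
  calibrated by root-finding so the expected censored fraction is 40%.
* **Single cell.** 22,700 cells by default over a compact 300-gene
  universe (candidates + dedicated MT/ribosomal genes + background,
  including a contiguous 100-gene block amplified in malignant cells for
  the CNV stage). The high-program state has pooled prevalence 11% —
  deliberately just above the 10% stratification decile, so the
  extreme-decile estimator samples from inside the planted state and the
  enrichment measurement is unbiased. Per-treatment state probabilities
  are set so their ratio equals `treated_enrichment` (62 by default).
  Fixed fractions of cells are forced across the mitochondrial gate and
  under the detected-gene floor so QC has planted positives. Because the
  gene universe is small, the synthetic pipeline runs QC with a
  100-detected-gene floor (`sc_min_genes`); the `qc_filter()` default for
  real-scale data remains 200.
* **Seeding.** All randomness flows through one global seed fanned out to
  fixed per-stage child seeds, so any stage can be re-simulated
  independently and two runs with the same configuration are identical.

```{r, eval = FALSE}
run <- run_full_synthetic(sim_config(seed = 1), include_scrna = FALSE)
run$report
```

## Numerical and statistical choices

* Holm and BH adjustments delegate to `stats::p.adjust`; the Mann–Whitney
  test is implemented directly because exact p values under ties (full
  enumeration of group assignments, doubled smaller tail) are needed for
  small strata, with a tie- and continuity-corrected normal approximation
  when n₁·n₂ > 64.
* Size factors are the median of per-gene ratios to the geometric-mean
  reference sample, computed on the ratio scale (not the log scale, whose
  even-count median interpolates geometrically) and excluding genes with
  any zero.
* Cox fits use Breslow tie handling; under complete separation the log
  hazard ratio is capped at ± 10 and flagged rather than diverging.
* Zero-variance genes never produce NaN: differential expression assigns
  p = 1 (equal means) or p = 0 (unequal means) with a flag, and
  correlation pairs involving a constant gene are flagged with r = NA,
  p = 1.
* KM median survival is the smallest time at which the curve reaches 0.5,
  NA when never reached.

## Ambiguities resolved

Several procedural details admit more than one reading; the package fixes
them as follows, each configurable where reasonable:

* Correlation-frequency ranking counts **significant pairs after Holm
  adjustment** (α = 0.05), not raw-p pairs.
* "Top half" of the ranked catalog means the top `ceiling(k/2)` of the
  **distinct** competition ranks, and genes with zero significant pairs are
  never selected.
* Mitochondrial and ribosomal QC limits are **separate** 15% gates, not a
  combined one.
* Single-cell extreme deciles are taken over the **pooled** malignant
  population, not within treatment arms.
* Treated-vs-naive enrichment is a **proportion ratio**; an odds-ratio
  variant can be computed from the returned 2×2 table.

## Limitations

The generator validates the pipeline's logic, not biology: it does not
emulate read-level data, fragment-length effects, batch structure, doublets,
ambient RNA, or real LD between enhancers and genes. Cell types and patient
labels are taken as given metadata (no clustering or annotation is
performed), and the CNV score is a windowed relative-expression summary, not
a segmentation model. Hazard directions learned on the synthetic cohort
inherit its simple two-state mixture; real cohorts will show weaker, graded
activation.
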