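# sepsispanel

Immune dysregulation in sepsis pulls in two directions at once: excessive
innate activation (neutrophil degranulation, interferon signaling) and
immunosuppression (loss of MHC class II expression, lymphopenia).
`sepsispanel` implements a composite marker-gene-panel analysis of bulk
RNA-seq from peripheral blood that measures five of these components
side by side and turns two of them into a simple prognostic rule for
ICU patients. It is aimed at computational biologists and intensive-care
researchers who want to score their own cohorts, evaluate threshold
rules against outcomes, or stress-test the approach on simulated data.

## The model

Five marker gene sets are scored per sample as the arithmetic mean of the
log2-normalized expression of their member genes:

| panel | component | genes | direction in sepsis |
|-------|-----------|-------|---------------------|
| NDrG | neutrophil degranulation | S100A12, CD177, HP, ANXA3, ARG1 | up |
| ISGa | type I interferon | IFI27, RSAD2, IFI44L, ISG15, IFITM3 | both |
| GBPs | type II interferon | GBP1–GBP5 | both |
| HLAd | MHC class II | HLA-DRA, HLA-DRB1, HLA-DMA, HLA-DMB, HLA-DPA1 | down |
| LYMd | lymphocytes / dendritic cells | CD4, CD8A, CD79A, CD27, KLRF1, FCER1A | down |

Raw counts are normalized as `log2(CPM + 1)`; pre-normalized log2
matrices are used as-is. The **composite score** is `NDrG − HLAd`:
simultaneous neutrophil activation and MHC-II suppression pushes it up,
so low values mean a near-normal immune state. The survivor-identification
rule predicts survival when `composite < 1.50` **or** `SOFA < 8`
(strict inequalities; SOFA is the 0–24 Sequential Organ Failure
Assessment score), with an optional exploratory clause `GBPs > 8.5`.

Around this core the package provides the cohort statistics used with
such panels (Welch and paired t contrasts, Tukey HSD multi-group
comparison with a permutation cross-check, Pearson correlation with
SOFA, panel-level PCA), per-subject serial monitoring with
reversal-of-dysregulation flags, confusion-matrix rule evaluation with a
zero-false-positive threshold search, and a negative-binomial cohort
simulator whose presets mirror the published study designs — so the
entire pipeline runs and is testable without any data download.

## Worked example

```r
library(sepsispanel)

cohort <- simulate_cohort(preset("icu_outcome"), seed = 1)  # 60 survivors, 18 non-survivors, 44 controls
scores <- score_samples(normalize_log2(cohort$expression))
scores[1:4, 1:7]
#>   sample_id    NDrG  ISGa  GBPs  HLAd  LYMd composite
#> 1 healthy_001  4.47  6.91  6.66  7.07  7.50     -2.61
#> 2 healthy_002  4.99  3.09  6.72  7.98  6.75     -2.99
#> 3 healthy_003  4.25  7.79  8.62  9.97  6.71     -5.72
#> 4 healthy_004  6.57  5.54  6.29  8.13  8.87     -1.55
```

Each row is one sample; panel columns are mean log2(CPM+1) expression of
the panel genes, `composite` is `NDrG − HLAd`. Contrast survivors against
non-survivors and correlate NDrG with SOFA:

```r
two_group_contrast(scores, cohort$metadata, "non-survivor", "survivor", "NDrG")
#>   panel      group_a  group_b n_a n_b mean_diff statistic    df   p_value  method
#>    NDrG non-survivor survivor  18  60    -1.285     4.589 25.89 0.0001002 welch_t

score_sofa_correlation(scores, cohort$metadata, "NDrG")
#>   panel     r  n  p_value
#>    NDrG 0.571 78 4.65e-08
```

In this single simulated cohort survivors sit 1.29 log2 units below
non-survivors on NDrG (the generative mean offset is −1.71; single-cohort
estimates scatter around it), and NDrG tracks organ failure (r = 0.57).
Evaluate the combined decision rule and find the largest
zero-false-positive composite cutoff:

```r
evaluate_rule(apply_rule(scores, cohort$metadata, rule_spec()), cohort$metadata)
#> <rule_eval> 78 evaluated (44 unknown outcome, 0 unevaluable)
#>   TP 51  FP 7  FN 9  TN 11
#>   sensitivity 0.850 | FP/(TP+FP) 0.121 | FP/(FP+TN) 0.389

zero_fp_threshold(scores, cohort$metadata)
#>   threshold sensitivity n_survivors n_nonsurvivors
#>        1.06       0.717          60             18
```

The rule identifies 51 of 60 survivors here; at threshold 1.06 the
composite alone identifies 71.7% of survivors with no false positives in
this cohort. `plot_composite_sofa()`, `plot_scores()`,
`plot_trajectories()` and `autoplot()` on a `pca_panels()` result give
the corresponding figures, and `run_pipeline()` /
`write_cohort()` drive the whole analysis to files.

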