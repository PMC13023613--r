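---
title: "Methods: composite marker-gene-panel analysis of sepsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite marker-gene-panel analysis of sepsis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsispanel)
```

## The scoring model

Each of the five marker gene sets summarizes one compartment of the
host response to severe infection. A panel score for sample $s$ and
panel $P$ is the unweighted arithmetic mean of the log2-normalized
expression of the member genes:

$$\mathrm{score}_P(s) = \frac{1}{|P|} \sum_{g \in P} \log_2\!\left(\mathrm{CPM}_{gs} + 1\right),$$

with $\mathrm{CPM}_{gs} = 10^6 \, c_{gs} / \sum_g c_{gs}$ for raw counts
$c$. The composite score is $\mathrm{NDrG} - \mathrm{HLAd}$. Working
with a difference of two mean-log scores makes the composite invariant
to any per-sample additive shift on the log scale — equivalently, to any
per-sample rescaling of the library — which is why no reference genes or
further normalization are needed. Matrices that arrive already
log2-normalized are scored as-is; the package never re-normalizes
declared log2 data.

Assumptions worth stating explicitly:

* *Equal gene weights.* Every member gene contributes equally; no
  fitting is done. This trades some efficiency for portability across
  platforms and avoids overfitting to any single cohort.
* *Missing members.* A panel score over a matrix lacking some member
  genes is the mean of the available members, with the fraction found
  reported as a `coverage_*` column and a warning per absent symbol.
  Only complete absence (coverage 0) is an error. Matching is exact
  after uppercasing; alias tables drift between annotation releases and
  are deliberately not consulted.
* *Duplicate symbols* in an input matrix are collapsed on read by the
  per-sample maximum, keeping the dominant isoform row rather than
  averaging it away.

## The decision rule

Survival is predicted by an OR of strict-inequality clauses:
$\text{composite} < 1.50$, $\text{SOFA} < 8$, and optionally
$\text{GBPs} > 8.5$. Strictness follows the printed form of the rule;
boundary samples are not identified. A sample missing any input of an
enabled clause is *unevaluable* and excluded from confusion counts
(tallied separately), as is any sample with unknown outcome.

Published summaries of this rule quote a "false positive rate" whose
denominator is ambiguous at the reported precision, so
`evaluate_rule()` reports both candidates explicitly —
$\mathrm{FP}/(\mathrm{TP}+\mathrm{FP})$ as `false_discovery_fraction`
and $\mathrm{FP}/(\mathrm{FP}+\mathrm{TN})$ as
`fpr_among_nonsurvivors` — and never calls either one *the* FPR.

`zero_fp_threshold()` returns the minimum composite value among known
non-survivors: the largest threshold whose strict-inequality clause
admits zero false positives. A brute-force search over all candidate
cut points is kept in the test suite as its oracle.

## Statistical contrasts

Unpaired two-group comparisons use the Welch unequal-variance t test —
the study style reports group means with p-values but does not name the
unpaired test, and Welch is the robust default. Paired time-point
comparisons use the paired t test on per-subject deltas over complete
pairs (incomplete subjects dropped with a message). Multi-group
comparisons use Tukey's honest significant difference: the package
computes the Tukey–Kramer standard error from the pooled within-group
mean square and evaluates the studentized range distribution directly
(`ptukey`); base R's `TukeyHSD` is the independent cross-check in the
tests, and a seeded max-difference permutation test
(`permutation_contrasts()`, 10,000 permutations by default) provides an
assumption-light alternative. All p-values are two-sided and reported
per panel without cross-panel multiplicity correction, matching how
per-panel results are conventionally quoted.

PCA operates on the five panel scores (not the 26 genes), centered and
scaled to unit variance. Panel-level input is an interpretation choice:
the published account attributes components to gene sets, which is the
panel-level structure; gene-level PCA is out of scope. Loading signs
are fixed so each component's largest-magnitude loading is positive,
making orientations reproducible across platforms.

## The synthetic-cohort generator

No public cohort ships with the package; instead `preset()` +
`simulate_cohort()` / `simulate_longitudinal()` generate cohorts whose
*panel-level* statistical structure matches the seven published study
designs. The generative chain is the package's own construction, built
so that effects configured on the score scale survive the
counts → CPM → log2 → score round trip:

1. Per sample and panel, a latent score
   $L \sim \mathcal{N}(\mu_P(\text{group}), \sigma_P^2)$, plus an
   optional discrete mixture shift for the bidirectional interferon
   panels.
2. Per member gene, a log2(CPM+1) target $L + \beta_g + \varepsilon$,
   with fixed within-panel offsets $\beta$ summing to zero and
   $\varepsilon \sim \mathcal{N}(0, \tau^2)$.
3. Targets (and background-gene targets) are mapped to expected CPM
   $2^t - 1$; background genes are rescaled so each sample's CPMs total
   $10^6$, making the panel targets exactly recoverable in expectation.
4. Counts are drawn negative-binomially with dispersion $\varphi$ at a
   library size drawn uniformly from the configured range.
5. $\mathrm{SOFA} = \mathrm{clip}(\mathrm{round}(a + b\,L_{\mathrm{NDrG}}
   + \mathcal{N}(0, s^2)), 0, 24)$ for ICU groups; healthy controls get
   missing SOFA. For the ICU-outcome preset, $s$ is solved from the
   configured group mixture variance so the NDrG–SOFA correlation
   targets 0.508 (the linear-model solution; rounding and clipping
   attenuate it by under 0.01).

Defaults: $\sigma_P = 1.0$ and $\tau = 0.5$ log2 units,
$\varphi = 0.1$, 2,000 background genes with log2 means uniform on
$[1, 9]$, library sizes in $[5\times10^6, 2\times10^7]$. These are
plausible bulk RNA-seq magnitudes chosen once; the published study
reports no within-group spreads, so they are assumptions, not
estimates. Setting $\varphi = 0$ switches to fully deterministic counts
(the rounded expected count) rather than the Poisson limit — the
noiseless mode used by the round-trip tests, which recover configured
means to $10^{-3}$ log2 units.

Preset effect sizes for the unidirectional panels (NDrG, HLAd, LYMd)
equal the published mean differences; where a cohort's differences were
not printed (the hyper/hypo-inflammation and surgery-CRP designs) the
presets use the package's own plausible values and no quantitative
claim rests on them. Bidirectionality of ISGa/GBPs is modeled as a
mixture of shifted and unshifted samples (10/14 suppressed for GBPs in
the sepsis-vs-control preset; symmetric ±1.5 mixtures where both
directions were reported). Responder presets place the responder
baseline offset from the non-responder baseline so that both the
within-group paired deltas and the published cross-group
responder-at-follow-up versus non-responder-at-admission differences
are matched simultaneously.

What the generator does **not** emulate: gene–gene correlation outside
panels, batch effects, platform differences, sequencing-error models,
or per-gene realism beyond panel structure. Passing recovery tests
therefore show that the pipeline is a consistent estimator of
panel-level effects under this generative model — not that the
published per-sample values are reproduced, which would require the
original cohorts.

## Numerical choices and degenerate inputs

* "Normalized counts" is implemented as CPM with pseudocount 1 before
  log2. The pseudocount keeps zero counts at exactly 0 and is the
  simplest standard choice; median-of-ratios could be slotted in behind
  the same interface.
* Zero-total samples, negative raw counts, SOFA outside $[0, 24]$,
  duplicate sample ids, and zero-coverage panels are hard errors with
  the offending sample/gene named.
* Contrasts refuse $n < 2$ per group, zero variance in both groups, and
  zero-variance paired deltas (flagged as degenerate rather than
  returning $t = \pm\infty$).
* Correlation requires ≥ 3 complete cases and nonzero variance on both
  sides.
* All simulation randomness flows from one explicit integer seed via a
  scoped RNG (`withr::with_seed`); no global state is touched, and
  identical seeds reproduce cohorts bitwise.

## Problem sizes

The test suite and the acceptance script run everything at the preset
cohort sizes (29–189 samples, 2,026 genes) with 50 replicate seeds for
stochastic recovery checks, 1,000 replicates for null calibration of
the tests at $n = 10$ per group, and 100 random fixtures for the
threshold-rule property checks. These sizes give Monte-Carlo standard
errors comfortably below the ±0.15 log2-unit recovery tolerance while
keeping a full run in well under a minute per target.

## Known limitations

* The composite threshold 1.50 is platform-dependent; on a different
  expression assay the cutoff must be re-derived
  (`threshold_sweep()` and `zero_fp_threshold()` exist for exactly
  this).
* Responder/non-responder labels are inputs, not derived from SOFA
  trajectories: the defining SOFA-improvement cutoff is not public.
* The package scores bulk RNA-seq; microarray probe-to-gene mapping and
  GEO series-matrix parsing are out of scope.
* Rule evaluation dichotomizes outcome; no survival-time modeling is
  attempted.
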