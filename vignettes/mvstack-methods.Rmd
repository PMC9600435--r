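---
title: "Multi-view stacked generalization for microbiome diagnostics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view stacked generalization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvstack)
```

This vignette is the package's account of its statistical machinery: the
stacking model and its assumptions, the knobs that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design decisions taken where more than one reasonable choice existed.

## The model

The unit of analysis is a two-class patient cohort observed through two
*views*: a wide, sparse, non-negative OTU abundance matrix ("microbial")
and a narrow mixed-type table ("clinical") that may contain missing
values. The stacked model is built in four stages, all fit strictly on the
training split:

1. **Microbial pre-filter.** Zero-variance OTUs are removed, every column
   is Yeo–Johnson power-transformed toward normality and standardized, and
   a per-feature one-way ANOVA F-test between the two label groups keeps
   features whose multiplicity-corrected p-value is at most `alpha`. The
   clinical view passes through untouched: its one consumer handles raw
   mixed-type input natively, and transforming a seven-column table buys
   nothing.
2. **Per-view base learners.** Seven families on the filtered microbial
   matrix (regularized logistic-loss linear model, linear large-margin
   scorer, k-nearest neighbours, single-hidden-layer perceptron,
   covariance-shrinkage quadratic discriminant, random forest, histogram
   gradient boosting) plus histogram gradient boosting on the clinical
   view. Base learners run at fixed ecosystem defaults — the meta-learner,
   not per-base tuning, is the mechanism that allocates trust among them.
3. **Out-of-fold meta-features.** Stratified k-fold over the training set;
   within each round the *entire* label-using preprocessing (the ANOVA
   filter and the class weights) and every base learner are refit on the
   fold complement, and only the held-out fold's positive-class
   probabilities are kept. This makes meta-feature row *i* mathematically
   independent of sample *i*'s own label — the property the test suite
   checks by label mutation, and the reason a meta-learner trained on
   these columns does not inherit the base learners' training-set
   optimism.
4. **Meta-learner.** Elastic-net logistic regression on the stacked
   probability columns, grid-searched over penalty strength and l1-ratio
   by stratified cross-validated average precision and refit on all meta
   rows. Meta columns share the probability scale, so no internal
   standardization is applied and the fitted weights are directly
   comparable across base learners. For test-time prediction every base
   learner is refit once on the full training set (standard stacked
   generalization practice); the saved single filter state likewise comes
   from the full training set and serves only this prediction path.

The key modelling assumptions are: binary labels with both classes
represented at every fitting site; probabilities (or scores mapped into
[0, 1]) as the common currency between levels; and sample exchangeability
within class for the stratified resampling to be meaningful.

## Handling class imbalance

Both motivating cohort shapes are imbalanced (17% and 41% positive).
Three consequences run through the package:

- **Average precision, not AUROC**, is the primary metric; an
  uninformative ranker scores the positive prevalence (`random_ap()`),
  which every report and figure carries as its reference line. AP is
  computed as the interpolation-free step sum over descending unique score
  thresholds, ties forming one threshold.
- **Data-space class weighting** `w_c = n / (2 n_c)` is passed to every
  base learner that supports per-class or per-case weights. Resampling is
  deliberately avoided: undersampling can discard carriers of rare taxa,
  oversampling inflates overfitting.
- **Matthews correlation** quantifies agreement between predictors (and
  with the labels) symmetrically under imbalance; a zero denominator — a
  predictor emitting a single class, which does happen for weak base
  learners — returns 0 by convention.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `k` | 5 | fold count for meta-features and the grid search; small enough that each fold complement retains most rare-class members at a few hundred samples |
| `alpha` | 0.05 | significance level on the corrected ANOVA p-value; lower it for a stricter, lower-variance microbial panel |
| `correction` | `"BH"` | Benjamini–Hochberg FDR; `"bonferroni"` for family-wise control, `"none"` to disable (then `alpha = 1` makes the filter the identity on non-constant features) |
| `meta_learner` | `"elasticnet"` | `"random-forest"` and `"softvote"` as alternatives; only the linear meta exposes interpretable weights |
| grid | λ ∈ 10^{-3..3} (7 points), ρ ∈ {0, .25, .5, .75, 1} | exhaustive elastic-net grid, scored by CV average precision; ties resolve to the strongest penalty, then the smallest l1-ratio |
| `test_fraction` | 0.2 | holdout size; stratified by default so the test prevalence matches the cohort |
| `n_repeats` | 10 | permutation-importance repeats; the median over repeats is reported |

One global seed fans out deterministically (via a fixed linear-congruential
step) to the split, the fold assignments, every stochastic learner and the
permutation draws; reports are bit-for-bit reproducible from the config.

## The synthetic generator

`generate_multiview()` draws labels first (exact count
`round(n * positive_fraction)`), then features conditional on the label,
so every planted effect is auditable:

- **Microbial view**: zero-inflated log-normal abundances — presence is
  Bernoulli(1 − sparsity), abundance is log-normal with unit log-scale
  variance; an informative subset receives a class-dependent log-scale
  mean shift (`microbial_effect`).
- **Clinical view**: standard-normal numeric features (informative ones
  shifted by `clinical_effect`), categorical features with class-dependent
  level probabilities, and completely-at-random missingness at
  `missing_rate_clinical`.

The cohort presets mirror the two study shapes (535 samples / 17% /
6737 OTUs / 7 clinical; 291 / 41% / 5982 / 9) plus `-small` variants
(120 samples, 300 OTUs) sized so a full stacked fit takes seconds.

Default effect sizes were fixed once, from a power analysis rather than
from test outcomes: the Yeo–Johnson likelihood drives the exponent
negative on heavily zero-inflated columns, and a negative exponent
saturates large abundances — so a planted log-scale shift survives the
transform only for moderately prevalent features. The default sparsity of
0.3 places the generated panel in the regime of the moderately prevalent
OTUs that dominate real differential-abundance signals, where a shift of
two log-scale standard deviations is detectable by the ANOVA/FDR filter at
desk-scale n. The property-test configurations follow the same logic: the
complementary-views study uses moderate effects chosen so each single view
lands in the mid-AP range (saturated signal would make every learner
perfect and ensemble dominance vacuous), and the null mode sets every
effect to zero.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: compositionality and sequencing-depth
effects, phylogenetic correlation among taxa, informative (non-MCAR)
clinical missingness, batch effects, and label noise. Results on synthetic
cohorts demonstrate the pipeline's mechanics (no leakage, correct
bookkeeping, recovery of planted structure), not clinical performance.

## Numerical choices and degenerate inputs

- **Yeo–Johnson over Box–Cox**: abundance tables are full of exact zeros,
  which Box–Cox cannot accept. The per-column exponent is the maximizer of
  the profile log-likelihood on [−3, 3] (golden-section search); fitted
  transforms store the exponent plus the training mean/SD for
  standardization, and are applied verbatim to new samples.
- **Empty filter result**: if no microbial feature passes at `alpha`, the
  single best-ranked feature is kept and the state flagged, so downstream
  learners always receive a non-empty view; the all-constant input case
  remains a hard error.
- **Constant meta-features**: if every base learner outputs a constant,
  the meta-learner degrades to an intercept-only model predicting the
  prevalence (the no-information answer) instead of failing.
- **Probability mapping for score-based families**: the large-margin
  linear scorer's decision values are oriented on the training set and
  mapped by `clip((d + 1)/2, 0, 1)`; nearest-neighbour scores are the
  neighbour vote fraction.
- **Shrinkage QDA**: per-class covariances are shrunk toward a scalar
  diagonal (10% by default) so the discriminant stays defined when the
  filtered feature count approaches the class size.
- **Unseen categorical levels** at prediction time map to the missing
  category of the histogram-gradient-boosting encoder.
- **Soft-vote ties** (mean probability exactly 0.5) go to the negative —
  reference — class. MCC matrices threshold probabilities at 0.5.
- Single-sample datasets are valid prediction inputs; fitting functions
  demand both classes.

## Open design points, resolved

- The fold count for meta-feature construction is not canonical; 5 is the
  default and it is configurable.
- Only the positive-class probability enters the meta-feature matrix: the
  binary task makes the complementary column redundant, and one column per
  learner keeps the meta weights readable.
- Whether per-fold "training AP" should be measured on the fold complement
  or the full training set is ambiguous in common usage; the
  cross-validation summary uses the fold-complement reading, while the
  headline train-split AP comes from the full-training refit (the same
  models that serve test prediction).
- The permutation-importance metric is average precision on the training
  set, with filtered-out features reported as exactly zero rather than
  omitted, so reports are comparable across `alpha` settings. Because all
  per-column transforms are elementwise, permuting a raw column and
  transforming equals transforming and permuting; the implementation uses
  this identity and recomputes only the learners on the affected view —
  numerically identical to rerunning the full pipeline, at a fraction of
  the cost.
- Cross-validated scores for the stacked model come from a full nested
  stacked fit inside each fold complement (inner fold count 3 by default)
  so the outer validation fold is never touched during any part of the
  nested fit.

## Problem sizes used by the test suite

The suite exercises every stage on generated cohorts of 10–535 samples.
The heavier statistical checks use: 20 replicates of the complementary-
views study at n = 160 (25% positive, 300 OTUs); 20 replicates of the
clinical-only-signal study at n = 120; three null-mode cross-validation
runs at n = 120 with k = 4, compared against a 2000-replicate Monte-Carlo
band for the median validation AP of an uninformative ranker; and a
planted-importance study at n = 200 with 10 permutation repeats. The
full-size presets are generated once to verify their stated dimensions.

## Limitations

- Two views are exercised; the design admits more, but the test surface
  does not cover them.
- No probability calibration of base learners; score-based families
  contribute ranked scores, not calibrated probabilities.
- Binary classification only.
- The ANOVA filter is univariate: it can discard features that are only
  jointly informative. Loosening `alpha` (or disabling correction)
  trades false discoveries for sensitivity; both knobs are exposed.
- Real-data ingestion is limited to the delimited-table loader; BIOM
  parsing, 16S processing and taxonomic annotation are out of scope.
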