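---
title: "Building and validating rank-based gene-pair prognostic signatures"
author: "pairsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating rank-based gene-pair prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsig)
```

## The model

Absolute expression values travel poorly between cohorts: microarray and
RNA-seq platforms, library preparation and normalization all shift them.
A within-sample *gene-pair indicator* does not. For genes $A$ and $B$ and
sample $s$,

$$ I_{A|B}(s) = \mathbf{1}\{x_{A,s} > x_{B,s}\}, $$

with ties scored 0. The indicator depends only on which of the two genes is
higher inside one sample, so it is invariant under any strictly increasing
per-sample transform of expression — log, quantile scaling, CPM — which is
what lets one fitted signature be re-derived on an independent cohort from
that cohort's raw values, without cross-cohort normalization.

A signature is a linear risk score over a small set of such indicators,

$$ \mathrm{risk}(s) = \sum_i \beta_i \, I_{A_i|B_i}(s), $$

with the $\beta_i$ estimated by Cox proportional-hazards regression.
Patients are dichotomized at a cut-off chosen on the training cohort, and
the high/low groups are compared by Kaplan–Meier/log-rank. The package ships
one fixed instance of this family — a three-pair colorectal-cancer signature
(`published_signature()`: C6orf15|PCSK1, CTSW|FABP4, SPRR1B|PCSK1 with
coefficients 0.39691, −0.74874, 0.67854 and cut-off 0.703) — and the full
machinery to fit new ones.

## The selection pipeline

`run_pipeline()` reproduces the construction procedure end to end:

1. **Candidate genes.** Three differential-expression contrasts are
   screened on log2 expression — tumor vs. normal (|logFC| ≥ 1.3, p <
   1e−4), metastatic vs. non-metastatic and high- vs. low-immune
   infiltration (both |logFC| ≥ 1.0, p < 0.05) — and intersected. logFC
   boundaries are inclusive, p boundaries strict. The statistic is a
   Wilcoxon rank-sum test (tie-corrected normal approximation) with
   mean-difference logFC: self-contained and rank-robust, but deliberately
   *not* a count-model DE analysis, so gene lists will not numerically match
   an edgeR run on the same data. Raw p-values are thresholded by default
   (a BH option exists), mirroring the published screening rules.
2. **Immune grouping.** Per-sample ssGSEA scores over immune cell-type gene
   sets, summarized into immune/stromal means, standardized, Ward-clustered
   (`ward.D2`, Euclidean) into three groups relabeled high/medium/low by
   mean immune score. The high-vs-low contrast feeds step 1; the medium
   group is excluded.
3. **Pairs.** All $\binom{m}{2}$ indicators over the intersected genes, in
   canonical orientation (lexicographically smaller gene first), then the
   *prevalence validity filter*: a pair whose minority indicator frequency
   is ≤ 20% is nearly constant and is dropped (strict inequality at the
   boundary; an indicator mean of exactly 0.2 or 0.8 is dropped).
4. **Selection.** Univariate Cox screen at p < 0.05; LASSO-penalized Cox on
   the survivors with λ chosen at the minimum 10-fold cross-validated
   partial-likelihood deviance (folds stratified by event status, fold
   assignment seeded); an unpenalized multivariable Cox refit of the
   selected pairs reports per-pair HR, 95% CI and Wald p.
5. **Evaluation.** Time-dependent ROC (cumulative/dynamic,
   Heagerty–Lumley–Pepe Kaplan–Meier estimator) at 1, 3 and 6 years; the
   cut-off is the Youden-J maximizer on the longest-horizon curve
   (ties → smaller threshold); Kaplan–Meier/log-rank on the resulting
   groups; chi-square (no continuity correction) and rank-sum association
   tests against clinical fields; per-set infiltration differences and
   Spearman correlations against the risk score.

### ssGSEA variant

`ssgsea_score()` is the Barbie-style running sum: per sample, genes are
ordered by expression (descending, ties broken by stable gene order); the
score is the sum over all positions of the difference between the cumulative
in-set mass (weights $\mathrm{rank}^\alpha$, $\alpha = 0.25$ by default,
normalized to 1) and the cumulative out-set mass (uniform steps). Summing
the running difference — rather than taking its maximum deviation — is what
distinguishes ssGSEA from the classical GSEA enrichment statistic. Scores
are not rescaled across samples. No proprietary immune/stromal signature
lists are bundled: the 29-cell-type collection the method conventionally
uses is supplied by the user (GMT), and the synthetic generator emits a
matched collection.

## The synthetic world

`generate_cohort()` exists so that every stage is exercisable, with ground
truth, in seconds. It is a *stated world*, not a tuning surface; its
defaults are fixed here once.

- **Expression**: log2-normal noise (sd 1, a typical bulk log-scale
  residual spread) around per-gene baselines drawn uniformly on [4, 12]
  log2 units, exponentiated to positive values; optional Poisson rounding
  to counts. The floor of 4 keeps the log2(x+1) pseudocount distortion well
  below the DE effect sizes.
- **Cohort layout**: 444 samples, 10% adjacent-normal (emulating the
  roughly 44-normal complement of a ~450-patient TCGA-style colorectal
  series), 16% of tumors metastatic.
- **Contrasts**: 100 tumor-DE genes at ±2 log2 units, 60 metastasis-DE
  genes at ±1.5, 29 immune cell-type sets of 10 genes plus 2 stromal sets,
  all set members shifted by `immune_effect` (default 1) times a latent
  standard-normal immune score — making ssGSEA scores monotone in the
  latent axis, testable by rank correlation.
- **Overlap block**: 12 genes differential in *all three* contrasts (tumor
  and metastasis shifts, immune-set membership); planted pairs draw their
  genes from it so they can survive the intersection. Both genes of a pair
  receive identical shifts and the same immune coupling, so the indicator
  depends only on baselines and noise.
- **Prevalence**: each planted pair's tumor-sample indicator prevalence is
  forced into (0.2, 0.8) by resampling the two baselines (at most 100
  retries), matching the validity filter.
- **Survival**: event times exponential with hazard
  $h_0 \exp(\sum_i \beta_i I_i)$, $h_0 = 0.12$/year, independent
  exponential censoring at 0.035/year plus a 12-year administrative cap —
  roughly 30% censoring and a median follow-up in the range of colorectal
  cohorts. Default planted effects are $\beta = (0.9, −0.8, 0.7)$.
- **Determinism**: one seed drives a single RNG stream; identical
  config + seed reproduces the cohort bit for bit. The generator restores
  the caller's RNG state.

What the generator does *not* emulate: negative-binomial count dispersion,
batch effects, correlated co-expression modules, competing risks,
non-proportional hazards. A green recovery test therefore establishes that
the pipeline's statistics do what they claim under the stated model — not
that the published gene lists or cohort-dependent numbers (DEG counts, AUC
0.711, the 0.703 cut-off as a fitted quantity) would be reproduced; those
require the original cohorts and are out of scope by design.

## Numerical choices and edge cases

- **Cox ties**: Efron correction throughout (the convention for tied event
  times); tie-free toys make Efron, Breslow and the exact partial
  likelihood coincide, which is how the grid-search oracle tests work.
- **CI identities**: every reported record satisfies `hr = exp(coef)` and
  `sqrt(ci_low * ci_high) = hr` (symmetric interval on the log scale,
  z = 1.959964); the published table is checked against these identities at
  construction.
- **λ rule**: `lambda.min`, not `lambda.1se` — the selection step is a
  screen feeding an unpenalized refit, so mild over-selection is preferable
  to dropping a true pair. An empty selection at `lambda.min` aborts the
  run loudly.
- **Cut-off boundary**: a score exactly at the cut-off is *low* risk; a
  deterministic convention where the source procedure is silent.
- **td-ROC**: the conditional-Kaplan–Meier (survivalROC-style "KM")
  estimator; in the no-censoring limit it reduces exactly to the empirical
  ROC and its AUC to the Mann–Whitney statistic. Under censoring this
  estimator is known to admit local non-monotonicities; the AUC integrates
  the threshold-ordered path, which is robust to them. The evaluation
  horizons default to 1/3/6 years and are configurable (the source
  procedure itself is inconsistent between 1/3/6 and 1/2/6).
- **Rank tests**: normal approximation with tie correction and no
  continuity correction; a completely tied comparison returns p = 1.
  "Wilcoxon signed-rank" comparisons between independent risk groups are
  read as rank-sum (Mann–Whitney) tests — signed-rank requires a pairing
  that does not exist between risk groups.
- **Degenerate inputs** fail loudly and early: zero library sizes name the
  sample, all-identical clustering inputs refuse to cluster, constant
  indicators are flagged non-estimable and excluded rather than crashing
  the screen, missing genes in validation cohorts are listed by name.

## What the tests establish

The suite pins every statistical primitive to an independent oracle
(1-D grid search of the Cox partial likelihood, position-enumeration
ssGSEA, hand O−E/V log-rank, Mann–Whitney AUC), checks the published
model's internal identities and scorer arithmetic, and runs two
property-style campaigns on the synthetic world: planted-pair recovery
(the full pipeline finds ≥ 2 of 3 planted pairs in ≥ 80% of 20 seeds at
400 tumor samples) and null calibration (≈ 5% univariate screen retention
and AUC ≈ 0.5 with no planted effects). Bias of the refit coefficients is
estimated by averaging over seeds at n = 2000, since a single draw's
sampling error would otherwise dominate the 0.1 bound.
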