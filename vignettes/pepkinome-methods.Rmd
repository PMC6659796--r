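---
title: "Kinome peptide array profiling: models and methods"
author: "pepkinome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinome peptide array profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepkinome)
```

## The measurement and the question

Kinome peptide microarrays (PepChip-type) expose a lysate of primary
leukemic cells to an array of 976 kinase substrate peptides, each spotted
in triplicate.  Kinases active in the lysate transfer radiolabelled
phosphate onto the peptides, and the background-subtracted spot intensity
summarizes net phosphorylation of each substrate — a functional snapshot
of the active kinome rather than of expression.  The analysis question
this package addresses: do such activation profiles stratify acute
myeloid leukemia (AML) samples into subgroups with different clinical
behaviour (relapse incidence, chemosensitivity), using CD34+ normal bone
marrow (NBM) samples as the non-leukemic reference?

`pepkinome` implements the full chain from spot-level scans to outcome
statistics, together with a synthetic cohort generator that carries its
own ground truth, so every stage can be validated end to end without
access to raw scans.

## Preprocessing model

Spot tables arrive as long-format TSV (`sample_id`, `group`,
`peptide_id`, `replicate`, `fg`, `bg`).  Preprocessing applies, in order:

1. **Background subtraction** — `max(fg - bg, 0)` per spot.  Negative
   differences are floored at zero because the readout (incorporated
   radioactivity) cannot be negative; floored spots are counted in the
   run log rather than dropped.
2. **Quantile normalization** at spot level across all samples: sort each
   sample column, average across samples at each rank, assign the rank
   means back by each column's original ranks.  Ties within a column
   receive the mean of the rank means they span.  After normalization all
   columns share one value multiset exactly when the input is tie-free;
   with ties, tie-group averaging can perturb individual multisets
   slightly (a property shared by the common implementations of the
   procedure).  Normalization precedes QC and collapse, matching the
   stated processing order of the assay.
3. **Triplicate concordance QC** — for each sample the spot column is
   split into its three replicate vectors (one value per peptide each)
   and the concordance is the mean of the three pairwise squared Pearson
   correlations.  Samples with r² strictly below 0.6 are excluded.  The
   mean-of-pairs aggregation is a design choice (the assay description
   names only "Pearson correlation over the triplicates"); minimum-of-
   pairs is available via `method = "min"`.  A pair involving a
   zero-variance replicate vector contributes 0.
4. **Median collapse** — the per-(sample, peptide) value is the median of
   the three replicate spots, giving the samples × peptides activation
   matrix used downstream.

We do not re-normalize after sample exclusion; whether the original
analysis did is unknowable from its description, and re-normalization
would couple the retained samples' values to the excluded ones' ranks.

## Clustering and the number of clusters

Stratification operates on the AML samples only:

* **Variance filter**: retain peptide *i* iff σᵢ/σ_max ≥ 0.15, with σ the
  per-peptide standard deviation across samples.  The ratio uses σ, not
  σ², as written in the filter's definition.
* **Scaling**: `log2(1 + x)` then per-peptide z-score.  Euclidean
  distance on z-scored log intensities is the default metric (the
  convention of the visualization software the assay's analysis used);
  correlation distance is available via `metric = "correlation"`.
* **Average linkage (UPGMA)** agglomerative clustering of samples via
  `stats::hclust`.  The test suite checks it against a brute-force O(n³)
  UPGMA oracle (identical merge heights and partitions on random
  instances).
* **Gap statistic**: for k = 1…6, `W_k = Σ_r D_r / (2 n_r)` (equivalently
  the within-cluster sum of squared distances to centroids) is computed
  from the dendrogram cut; B = 100 reference datasets are drawn uniformly
  over each feature's observed range and clustered with the *same*
  hierarchical procedure, so that model selection matches the clustering
  actually used.  `Gap(k) = mean_b log W*_kb − log W_k`,
  `s_k = sd_b(log W*_kb)·√(1 + 1/B)`, and k̂ is the smallest k with
  `Gap(k) ≥ Gap(k+1) − s_{k+1}`.  The uniform-over-range reference is the
  simplest published variant and is fully seeded.

Cluster labels are renumbered by order of first appearance in the sample
ordering so results are reproducible across platforms.  `run_all()`
anchors all downstream cluster-1 / cluster-2 contrasts on the k = 2 cut
of the dendrogram — the comparisons are defined for the two main
clusters — while reporting k̂ and the full gap curve alongside.  On
default-size cohorts (96 evaluable samples) the gap statistic selects
k̂ = 2; on much smaller cohorts it may legitimately subdivide further.

## Differential activation

Per-peptide one-way fixed-effects ANOVA across cluster-1, cluster-2 and
NBM, Bonferroni-corrected over the variance-filtered peptide set (not all
976; the filtered set is what the analysis carries forward).  Two scales
are involved, deliberately:

* **Test statistics** (omnibus F and the three pairwise pooled-variance
  t-tests) are computed on `log2(1 + x)`.  On the natural intensity
  scale, spot intensities are approximately lognormal and the F-test is
  markedly anti-conservative — with a 4-sample control group we measured
  family-wise error far above nominal under a global null, while on the
  log scale Bonferroni holds its level (this is verified by a calibration
  test).  `log_transform = FALSE` restores natural-scale testing.
* **Group means and folds** are reported on the natural intensity scale,
  which is how fold differences between clusters and NBM are
  conventionally presented.  Folds are ratios of arithmetic means by
  default (`geometric = TRUE` switches); a zero denominator yields an
  `Inf` sentinel with a flag.

Peptides with zero variance everywhere are degenerate (0/0 F-ratio) and
reported as F = 0, p = 1 with a flag, rather than NA, so downstream
tabulations stay total.

## Outcome statistics

* **Overall survival**: Kaplan–Meier product-limit per cluster with
  follow-up time and death as the event; log-rank χ² (df = 1) between
  clusters.
* **Cumulative incidence of relapse (CIR)**: reported both as the raw
  per-cluster relapse proportion — which is what the Pearson chi-square
  on the 2×2 relapse × cluster counts tests — and as 1 − KM of
  time-to-relapse for plotting.  When no relapses occur at all the 2×2
  margin degenerates; the CIR report then returns statistic 0, p = 1
  instead of failing.
* **Pearson chi-square** without continuity correction (the "Pearson
  Chi-Square" line of SPSS output); Yates' correction by flag.  The
  standalone 2×2 test refuses zero margins.
* **Mann–Whitney U**, two-sided: exact by full enumeration when
  n₁ + n₂ ≤ 12 without ties, otherwise normal approximation with tie and
  continuity corrections.
* **Characteristics table**: Mann–Whitney for age, blast %, WBC, RBC,
  PLT; chi-square for sex, relapse, death, complete response.  Unknown
  sex is a first-class category, excluded from the sex contingency test
  and never imputed.

All times are months; event indicators are 0/1.

## LC50 estimation

Viability curves (% of untreated control at ascending drug
concentrations) are summarized by the bracketing interpolation

LC50 = (V_above − 50)/(V_above − V_below) · (c_below − c_above) + c_above

evaluated at the first adjacent concentration pair where viability
crosses from above to below 50%, on the **linear** concentration scale —
exactly the printed formula, even though the concentration grids are
log-spaced.  Conventions: viability exactly 50 at a measured
concentration returns that concentration; curves never dipping below 50%
are censored above the maximum concentration; curves starting below 50%
are censored below the minimum; on noisy non-monotone curves the first
crossing wins (the conservative, lowest lethal estimate).  Censored
values enter the Mann–Whitney comparison at their boundary concentration
(as max-concentration ties) but are excluded from the median folds; both
policies are switchable because the original analysis does not state how
non-crossing curves were handled.

The between-cluster summary is the fold difference of per-drug medians,
`median(cluster-2)/median(cluster-1)`, with a two-sided Mann–Whitney
test.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws, per seed: 96 evaluable AML arrays plus 4
planted low-concordance arrays (100 total) and 4 NBM controls over 976
peptides in triplicate.  The spot model is `fg = bg + activity` with

* per-peptide baseline log-activity `N(log 500, 0.5)`,
* a **binary** two-cluster pattern: 192 informative peptides shifted by
  ±effect/2 (default effect 1.5 on the natural-log scale, i.e. ≈4.5-fold
  between clusters), half up in each cluster, cluster sizes 39/57 — the
  minimal structure the clustering must detect,
* biological (sample × peptide) noise sd 0.25 and replicate spot noise
  sd 0.07 on the log scale; corrupt samples multiply replicate noise by
  6, placing their expected concordance (≈0.4) well below the 0.6 QC cut
  while clean samples sit near 0.95,
* lognormal additive background (`log 50`, sd 0.3) with a small
  measurement error on the reported background column,
* NBM controls drawn from the unshifted baseline,
* relapse ~ Bernoulli(0.26 / 0.47 by cluster; marginal ≈ 36/96) with
  exponential event times (median 12 months) and uniform censoring;
  death and complete response at cluster-independent marginal rates, so
  no covariate other than relapse differs between clusters,
* true LC50s for 5 samples per cluster: cluster-1 medians 0.1 / 0.3 /
  0.03 (mitoxantrone μg/mL, etoposide μM, amsacrine μg/mL), cluster-2 =
  cluster-1 × {31, 31, 104}, lognormal spread 0.15.

`generate_dose_response()` evaluates a Hill curve
`100 / (1 + (c/LC50)^h)` (default h = 1) on the drugs' log-spaced
concentration grids with bounded uniform noise (±3 points).  The
generator is parametric on purpose while the estimator is model-free
interpolation, so the recovery tests do not check an implementation
against itself.

The effect size, noise magnitudes and LC50 spread are not stated by any
source; they were fixed once, at values a clean single-batch array
experiment would plausibly show, such that the default pipeline recovers
the planted structure, and they are all config-exposed.  Passing
recovery tests therefore demonstrate internal consistency of the
pipeline under the assumed noise model — not performance on real arrays,
which carry spatial artifacts, batch effects, heavy-tailed outliers and
continuous (not binary) cluster structure that the generator deliberately
omits.

## Validation problem sizes

The test suite exercises: property checks on ~100 random matrices for
normalization; 20 default cohorts for QC recovery; 50 default cohorts for
gap-statistic/ARI recovery; 50 seeds for LC50-fold recovery; 1000 random
monotone curves against a piecewise-linear root oracle; brute-force UPGMA
equivalence on random instances of up to 8 samples; full-enumeration
Mann–Whitney checks up to n = 12; 5000 multinomial draws for chi-square
calibration and 200 null families for Bonferroni family-wise error.
Empirical error rates are judged with binomial sampling slack (e.g. the
FWER check uses a one-sided binomial test at the 1% level against the
nominal 5%), since an empirical rate over a few hundred replicates cannot
be compared to its target exactly.

## Known limitations

* No spatial/print-tip normalization and no two-channel (log-ratio)
  handling; the pipeline starts from extracted spot intensities.
* CIR is compared by frequency chi-square, not by competing-risks
  estimators (Gray's test); no multivariable survival modelling.
* The LC50 interpolation is intentionally model-free; it inherits grid
  resolution as estimation error (within one concentration step).
* Pathway/network interpretation of differential peptides is out of
  scope.
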