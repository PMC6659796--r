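# pepkinome

Analysis pipeline for kinome peptide microarray (PepChip-type) profiling
of acute myeloid leukemia (AML) samples. Arrays of 976 kinase substrate
peptides, spotted in triplicate, read out the net phosphorylation
activity of the kinases in a cell lysate; the package takes such
spot-level scans through quality control and normalization, stratifies
the samples into activation clusters, and asks whether the clusters
differ in peptide activation (versus CD34+ normal bone marrow controls),
relapse incidence, survival, and *in vitro* chemosensitivity.

## What it computes

* **Preprocessing** — per-spot background subtraction (`max(fg − bg, 0)`),
  quantile normalization across samples, triplicate-concordance QC
  (samples with mean pairwise r² < 0.6 across the three replicate
  vectors are excluded), and collapse to per-peptide medians.
* **Clustering** — peptides are kept when σᵢ/σ_max ≥ 0.15, log2-scaled
  and z-scored; samples are clustered by average-linkage (UPGMA)
  hierarchical clustering on Euclidean distances, and the number of
  clusters is chosen by the gap statistic
  (Gap(k) = E*[log W_k] − log W_k with the one-standard-error rule,
  uniform reference over each feature's range, B = 100).
* **Differential activation** — per-peptide one-way ANOVA across
  cluster-1 / cluster-2 / NBM with Bonferroni correction over the
  filtered peptides (statistics on log2 intensities, folds in natural
  intensity space).
* **Outcomes** — Kaplan–Meier + log-rank overall survival, cumulative
  incidence of relapse compared by Pearson chi-square on the 2×2
  relapse × cluster counts, Mann–Whitney U / chi-square for patient
  characteristics.
* **Chemosensitivity** — LC50 per sample × drug by bracketing linear
  interpolation, LC50 = (V₊ − 50)/(V₊ − V₋)·(c₋ − c₊) + c₊ at the first
  concentration pair crossing 50% viability; per-drug median fold between
  clusters with a Mann–Whitney test.
* **Synthetic cohorts** — `generate_cohort()` / `generate_dose_response()`
  draw complete cohorts (100 AML arrays of which 4 are planted
  low-concordance, 4 NBM controls, a binary two-cluster pattern on 192 of
  976 peptides, cluster-dependent relapse probabilities 0.26/0.47 and
  LC50 fold shifts of 31/31/104) together with ground truth, so the whole
  pipeline is testable end to end.

See `vignettes/pepkinome-methods.Rmd` for the models, parameter choices
and limitations.

## Worked example

```r
library(pepkinome)

rep <- run_all(sim_config(seed = 1))
print(rep)
#> pipeline_report
#>   samples: 104 in, 4 excluded by QC
#>   peptides: 976 -> 382 after variance filter
#>   clusters: k_hat = 2 (sizes 57/39), ARI vs truth = 1
#>   relapse: 43.9% vs 25.6% (chi-square p = 0.069)

rep$lc50_comparison[, c("drug", "median_cluster1", "median_cluster2",
                        "fold", "p")]
#>           drug median_cluster1 median_cluster2        fold           p
#> 1    amsacrine        2.964646      0.02851704 0.009619038 0.007936508
#> 2    etoposide        9.842812      0.29802840 0.030278786 0.007936508
#> 3 mitoxantrone        3.102387      0.13193695 0.042527560 0.007936508
```

Reading this: of 104 arrays (100 AML + 4 NBM), the 4 planted
low-concordance samples are removed by QC; 382 peptides pass the variance
filter; the gap statistic selects two clusters whose labels agree
perfectly with the generator's truth (adjusted Rand index 1). One cluster
relapses at 43.9% versus 25.6% in the other, and its cells tolerate
23–104× higher drug concentrations (cluster numbering follows dendrogram
order, so here "cluster-1" is the resistant group and the folds are the
reciprocals of the planted 31/31/104 shifts; Mann–Whitney p ≈ 0.008 for
every drug).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/pepkinome.R simulate --seed 2 --out sim/
Rscript inst/cli/pepkinome.R preprocess --in sim/ --out prep/
Rscript inst/cli/pepkinome.R cluster --matrix prep/collapsed_matrix.tsv \
        --seed 2 --out clus/
Rscript inst/cli/pepkinome.R run-all --seed 2 --out full/
```

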