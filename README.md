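# metaboqc

Statistical post-processing and quality assessment for untargeted LC-MS
metabolomics feature tables, plus reference-range validation of
preclinical phenotyping variables.

## The problem

An untargeted LC-MS run produces a matrix of feature intensities
(features = detected m/z × retention-time ions) across an injection
sequence that mixes biological samples with solvent blanks, pooled QC
samples (a pool of all study samples injected at regular intervals) and a
pooled-QC dilution series. Before any biological analysis, this matrix
has to be cleaned of solvent background, non-quantitative features,
instrument signal drift, unreliable features and chemical redundancy —
and the cleaned dataset's quality has to be scored so that datasets and
platforms can be compared. `metaboqc` implements that post-processing
chain and its quality metrics as a reusable, tested pipeline for data in
the three-file tabular convention (`dataMatrix.tsv`, `sampleMetadata.tsv`,
`variableMetadata.tsv`). It is aimed at analysts running multi-platform
metabolomics studies and at methodologists who need a seeded synthetic
benchmark with planted ground truth.

## What it computes

**Post-processing chain** (`run_pipeline()`), applied in this order with
full feature-count bookkeeping:

1. **Blank filter** — discard features whose mean intensity in the
   biological samples is less than 3× the mean in the blanks.
2. **Dilution filter** — discard features whose Pearson correlation
   between intensity and 1/dilution factor over the diluted pooled QCs is
   below 0.7.
3. **Drift correction** — per feature, loess regression of intensity on
   injection order over the reference injections (pooled QCs, or the
   biological samples); correction is multiplicative with renormalization
   to the reference median: x'(o) = x(o) · m_ref / f̂(o).
4. **CV filter** — discard features with pooled-QC coefficient of
   variation above 30% or above the biological-sample CV.
5. **Redundancy filter** — link features when profile correlation > 0.9,
   |Δrt| < 6 s and |Δm/z| matches a reference list of isotope/adduct/
   fragment differences at 0.005 Da; collapse each connected component to
   its highest-median-intensity representative.
6. **log2 transform** — the explicit final step.

**Quality metrics** (`quality_report()`), each on a 0–100 scale with 100
the highest quality:

- *Drift Spearman* = (1 − p_correlated / p_total) × 100, the share of
  features not significantly rank-correlated with injection order
  (Benjamini–Hochberg, FDR 5%).
- *Drift PCA* = (1 − cos²α) × 100, where α is the angle between the
  injection-order direction and its projection onto the first 3
  principal-component score vectors.
- *QC spread* = (1 − max(d_QC) / max(d_sample)) × 100 with d the
  Mahalanobis distance to the centroid in the 3D PCA score space.
- *QC CV* = percentage of features with pooled-QC CV ≤ 30%.
- *QC ICC* = 100 × ICC(A,1) (two-way random effects, absolute agreement,
  single measurement) of the pooled-QC intensities in the most populated
  log2-intensity bin.

Spiked-standard screening (`flag_standard_outliers()`) reports
(sample, standard) pairs with |z| > 3.

**Reference ranges** (`rr95()`, `flag_project_controls()`): for each
quantitative phenotyping variable, the interval covering 95% of
historical control values — mean ± 2 sd after a Shapiro–Wilk-gated
normalizing transformation (identity, log, square root or inverse), or
the 2.5th/97.5th percentiles when none normalizes; per sex, with a
warning below the recommended 120 animals. Project control cohorts are
screened against these ranges and overlaid on the historical PCA cloud
(`control_pca_overlay()`).

A synthetic-data generator (`simulate_ms_dataset()`,
`simulate_preclinical()`) produces datasets with planted blank-only
features, smooth multiplicative drift, redundancy groups and skewed
variables, together with the ground truth needed to score every step.

## Worked example

```r
library(metaboqc)

sim <- simulate_ms_dataset(seed = 1)   # the default synthetic study
sim$dataset
#> <ms_dataset> 200 features x 56 samples (raw scale)
#>   samples: blank=3, pool=9, pool_dilution=4, sample=40

# quality metrics at the canonical state: drift-corrected, not yet
# CV-feature-filtered
state <- run_pipeline(sim$dataset, steps = c("blank", "dilution", "drift"))
quality_report(state$dataset)
#> <quality_report>
#>          metric     score
#>  drift_spearman 100.00000
#>       drift_pca  92.95209
#>       qc_spread  92.40561
#>           qc_cv 100.00000
#>          qc_icc  97.63887

# the full chain with its feature-count cascade
full <- run_pipeline(sim$dataset)
glance(full)
#> # A tibble: 5 × 5
#>   step              n_features_in n_features_out n_discarded skipped
#> 1 blank_filter                200            180          20 FALSE
#> 2 dilution_filter             180            180           0 FALSE
#> 3 drift_correct               180            180           0 FALSE
#> 4 cv_filter                   180            180           0 FALSE
#> 5 redundancy_filter           180            160          20 FALSE
```

All 20 planted blank-background features fall at the blank step and all
20 planted redundant isotope/adduct partners at the redundancy step,
leaving the 160 genuine features — the generator's recorded truth
(`sim$truth`) makes such checks exact.

A reference range on a simulated control cohort:

```r
set.seed(42)
rr95(rnorm(150, 22.5, 1.8))
#>   transform     method    lower    upper   n shapiro_p small_n_warning
#> 1  identity parametric 18.82847 26.06806 150 0.8659194           FALSE
```

`read_triplet()` / `write_triplet()` move datasets between this package
and the on-disk triplet convention; a thin command-line wrapper with
`validate` / `simulate` / `postprocess` / `qc` / `refrange` / `all`
subcommands is installed at `system.file("cli/metaboqc", package = "metaboqc")`.

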