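---
title: "Post-processing and quality assessment of untargeted LC-MS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-processing and quality assessment of untargeted LC-MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboqc)
```

This vignette explains the statistical model behind each step of the
package, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the procedure left room for judgement.

## The data model

A dataset is the in-memory form of the tabular triplet used to exchange
processed metabolomics data: a features × samples intensity matrix, a
sample table (role of each injection: `blank`, `pool`, `pool_dilution` or
`sample`, plus injection order, dilution factor, genotype, sex, batch)
and a feature table (m/z in Da, retention time in seconds, annotation,
filter flags). Intensities are kept on the raw scale throughout
filtering; the log2 transformation is an explicit, flagged, final step,
because the blank-ratio rule and the coefficient of variation are defined
on raw intensities and become meaningless after a log transform.

Missing values are written as `NA` and ignored (not zero-filled) in all
means and CVs. A blank mean that cannot be computed because every blank
value is missing counts as zero background, which keeps the feature. This
convention is a deliberate choice: zero-filling missing blank values
would silently strengthen the background estimate with data that was
never measured.

## The post-processing chain

The six steps run in a fixed order — blank filter, dilution filter, drift
correction, CV filter, redundancy collapsing, log2 — with any step
skippable but never reorderable. Drift correction must precede the CV
filter: the pooled-QC CV is only a meaningful reliability measure after
the systematic injection-order trend has been removed, otherwise the
filter mostly measures drift amplitude.

**Blank filter.** A feature is kept when its biological-sample mean is at
least 3 times its blank mean; equality passes, because the rule discards
only features *below* the threshold. Features with no observed
biological value at all are discarded.

**Dilution filter.** Over diluted pooled-QC injections, the intensity of
a quantitative feature is proportional to the amount of matrix injected,
so its Pearson correlation with 1/dilution factor should be high; the
threshold is r ≥ 0.7 over at least 3 distinct dilution points. An
undefined correlation (zero intensity variance across an 8-fold dilution)
fails the filter: a feature blind to dilution is not quantitative. When
no usable dilution series exists the filter is skipped with a warning —
this matches practice, where only some platforms include diluted pools.

**Drift correction.** For each feature, a loess curve f̂(o) of intensity
versus injection order o is fitted on the reference injections and every
intensity is corrected multiplicatively,

x'(o) = x(o) · m_ref / f̂(o),

with m_ref the median raw intensity of the reference samples. The
defaults are span 1 and degree 2: with typically 10–30 pooled QCs per
sequence, smaller spans chase injection noise rather than drift.
Renormalizing by the reference *median* keeps the corrected feature on
its original intensity scale, so the downstream 3×-blank and 30%-CV rules
keep their meaning; an additive correction could produce negative
intensities. The reference is either the pooled QCs (default) or the
biological samples — the latter is preferable when pooled-QC
normalization visibly under-corrects, which is why the choice is a
parameter rather than a constant. Numerical guards: f̂ is clipped below
at 10⁻⁶·m_ref before division; outside the reference injection range the
nearest fitted value is carried forward rather than trusting polynomial
extrapolation; features with fewer than 5 observed reference values are
left uncorrected and flagged rather than corrected from an unstable fit.

**CV filter.** A feature is discarded when its pooled-QC CV exceeds 0.30
or exceeds its biological-sample CV — identical aliquots should never
vary more than distinct animals. Features with fewer than 3 observed pool
values are discarded as unreliable rather than silently kept.

**Redundancy collapsing.** One metabolite typically yields several
features (isotopes, adducts, in-source fragments). Two features are
linked when *all three* criteria hold: biological-profile Pearson
correlation above 0.9, retention-time difference below 6 s, and absolute
m/z difference matching a reference list of mass differences within
0.005 Da. The shipped list covers the ¹³C isotope spacing (1.00336 Da)
and common adduct/neutral-loss exchanges (+Na/−H, +K/−H, +NH₄, −H₂O,
+HCOOH, +Cl, +CH₃COOH) and is replaceable by any table with `label` and
`delta_mz` columns. Linked features are grouped by connected components
(chains count as one group even without every pairwise edge, since all
members descend from one metabolite), and each group keeps exactly one
representative: the member with the highest median biological intensity,
ties broken by lowest m/z. Highest intensity is the natural survivor —
usually the monoisotopic base peak — and the tie-break makes the choice
deterministic.

## The five quality metrics

All metrics are computed on the drift-corrected dataset *before* the CV
feature filter, on the non-blank injections excluding the dilution series
(whose intensities vary by design and would register as spurious drift).
Scores live on a 0–100 scale, 100 best, clamped where the raw formula can
leave the interval.

**Drift Spearman.** Per feature, a Spearman rank-correlation test of
intensity against injection order; p-values corrected by
Benjamini–Hochberg at FDR 5%; the score is the percentage of features
not significantly correlated. Exact permutation p-values are used at 10
or fewer observations, the t approximation above. Being rank-based, the
metric is invariant under any strictly monotone per-feature
transformation.

**Drift PCA.** Features are centered and unit-variance scaled, a PCA is
fitted on the included injections, and the centered injection-order
vector is projected onto the span of the first 3 score vectors; with
cos²α the squared cosine between the order vector and its projection,
the score is (1 − cos²α)·100. Under exchangeability (no drift) the
expected cos²α is 3/(n−1) for n injections, so the *null* score is
100·(1 − 3/(n−1)) — about 93.8 at n = 49 and 97.9 at n = 145. Scores
should be read against that ceiling, which is why validation of
drift-correction efficacy uses sequences of 100+ injections. Missing
values are mean-imputed per feature for the decomposition only and never
written back; unit-variance scaling stops high-abundance features from
monopolizing the components (the unscaled variant is available and is the
one with a rotation-invariance property).

**QC spread.** Same PCA on pooled QCs and biological samples jointly;
every sample's 3D score vector gets a Mahalanobis distance to the score
centroid under the covariance of *all* included scores — a common metric
for both groups, so the ratio max(d_QC)/max(d_sample) compares like with
like. The score 100·(1 − ratio) is clamped below at 0 for the case of a
pooled QC lying beyond the farthest biological sample. Numerically dead
score components (zero variance) are dropped before inverting the
covariance.

**QC CV.** The percentage of features with pooled-QC CV at or below 0.30
(boundary inclusive, per the defining inequality CV ≤ 0.3), among
features with at least 3 observed pool values; the cumulative
percentage-versus-CV curve is returned alongside.

**QC ICC.** Features with complete pooled-QC values are binned into 10
equal-width bins of log2 median pool intensity, and the intraclass
correlation ICC(A,1) — two-way random effects, absolute agreement,
single measurement — is computed per bin from the two-way ANOVA mean
squares:

ICC(A,1) = (MS_R − MS_E) / (MS_R + (k−1)·MS_E + (k/n)·(MS_C − MS_E)),

with n features and k pool injections. The score is the ICC of the most
populated bin ("most probable abundance"), ×100, clamped to [0, 100]
(the ANOVA estimator can go slightly negative). Equal-width bins are the
choice that makes "most populated bin" meaningful; equal-count bins
would make every bin modal. Ten bins over the ~4 decades of a typical
dynamic range keeps ≥3 features per informative bin at realistic dataset
sizes.

**Spiked standards.** Per standard, intensities across the non-blank
samples are z-scored and pairs with |z| > 3 are reported for manual
review together with each standard's CV. With estimated mean and sd at
n = 50 samples, the flag rate under normality sits slightly below the
nominal 2·Φ(−3) ≈ 0.27%, which the tests verify by simulation.

## The synthetic-data generator

The generator emulates the design the pipeline assumes: an injection
sequence opening with solvent blanks and a pooled-QC dilution series
(factors 1, 2, 4, 8), then biological samples with a pooled QC every 5
injections — the layout used in practice. Its defaults are the study
conditions of the validation suite and were fixed once:

| parameter | default | rationale |
|---|---|---|
| `n_features` | 200 | enough for stable filter proportions at desk scale |
| `n_bio_samples` | 40 | a typical single-batch cohort |
| `qc_every` | 5 | pooled QC every 5 samples |
| `n_blanks` | 3 | blanks at the head of the sequence |
| `noise_cv` | 0.05 | injection-to-injection repeatability of a stable platform |
| `bio_cv` | 0.20 | median biological between-sample variation |
| `drift_amplitude` | 0.30 | a strong but realistic within-batch drift |
| `frac_blank_features` | 0.10 | share of background-dominated features |
| `n_redundant_groups` | 10 (×2 members) | planted isotope/adduct clusters |
| `n_standards` | 4 | a small spiked-standard panel |

Baseline abundances are lognormal with log10 means spread uniformly over
4 decades, making the ICC intensity binning meaningful. Drift is
g(o) = exp(a·s(o)) with s a random cubic rescaled so max|g−1| equals the
requested amplitude — smooth, feature-specific, and recorded in the
truth object. Pooled-QC levels equal the mean of the biological levels
(that is what pooling does); dilution intensities scale as 1/factor;
blanks carry no drift (solvent background does not track matrix response)
and their levels are set so planted blank features fail the 3× rule at
ratio 2 and all others pass at ratio 15 — margins that keep the filter
tests sharp rather than flaky. Redundant members copy their
representative's profile at a scale factor in 0.3–0.8 (so the
representative always has the highest median), share its drift, sit
within 3 s in retention time and at a listed m/z offset, and share most
of its injection noise so the planted correlation stays above 0.95 at any
noise level. The preclinical generator draws per-sex normal or lognormal
variables (the skewed fraction defaults to 1/3, since roughly two thirds
of phenotyping variables are normal after at most a mild transform) for a
historical cohort of 1112 animals (573 males, 539 females) and a
15-animal project cohort drawn from the same distributions.

What the generator does *not* emulate: missing values, batch-to-batch
discontinuities, correlated biological structure (genotype effects on the
metabolome), retention-time drift, heteroscedastic noise, or isotope
intensity ratios. Passing tests therefore demonstrate correctness of the
procedures under the stated statistical model, not performance on any
particular real dataset.

## Validation design and known limitations

The test suite validates the linear-algebra internals (Mahalanobis,
ICC(A,1), cos²α) against brute-force oracles at 10⁻¹⁰, calibrates the
drift metrics under the null, verifies exact recovery of planted blank
and redundancy structure at 5% noise, and checks rr95 coverage
(the parametric interval covers 95.45% of a normal population; empirical
coverage on 1000-animal cohorts lands in [0.94, 0.97]) and
transformation recovery (≥85% of variables at ~500 animals per sex).
Problem sizes were chosen to keep the whole suite under half a minute:
fuzzing uses 40-feature datasets, null calibration 500 × 60, and
drift-efficacy runs a 120-biological-sample sequence so that the Drift
PCA null ceiling (~97.9) leaves headroom above the 95-point pass mark.

Two limitations are worth knowing. First, the Drift PCA score at short
sequences is bounded by its null expectation 100·(1 − 3/(n−1)), so a
perfectly corrected 50-injection dataset cannot score much above 94; the
metric should be compared across datasets only at similar sequence
lengths. Second, pool-based drift correction carries the pooled QCs'
injection noise into the estimate: with 5% noise and ~25 pools the
residual per-feature trend is ~1.7%, and because those residuals are
smooth in injection order they can surface in the top principal
components when the feature count is large relative to the sample count,
costing a corrected dataset a few Drift PCA points in unfavorable noise
realizations. Using the biological samples as reference (more
observations) or longer sequences reduces this.

The rr95 procedure makes its own documented choices: transforms are
tried identity → log → square root → inverse and the first one whose
Shapiro–Wilk p ≥ 0.05 wins (ordering by interpretability; the gate level
is the conventional 0.05); percentile bounds use type-7 linear
interpolation so results are reproducible bit for bit; ranges are
computed per sex, matching the sex-specific reference rectangles of
phenotyping practice, with a pooled mode available; for the inverse
transform the back-transformed bounds swap order, and when the
transformed lower bound crosses zero the original-scale upper limit is
reported as infinite rather than inventing a finite one. Screening
discards a variable only when a project-control mean falls *strictly*
outside a bound for either sex — a mean exactly on the bound is inside
the 95% range by construction.
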