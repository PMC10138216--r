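---
title: "stimMII: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stimMII: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimMII)
```

## The prediction problem

Controlled ovarian stimulation aims to mature multiple follicles before
oocyte retrieval in an IVF cycle. The clinically useful outcome is the
number of metaphase-II (MII) oocytes retrieved: too few reduces the chance
of a transferable embryo, while an excessive response risks ovarian
hyperstimulation. Anti-Müllerian hormone (AMH) and the antral follicle
count (AFC, follicles ≤ 10 mm on the first stimulation day) are the
standard ovarian-reserve markers, with age, previous-cycle yields and PCOS
as secondary predictors. stimMII implements a pipeline that augments such a
clinical predictor with *engineered genetic features* — combinations of
sequence variants in reproduction-related genes (e.g. *LHCGR*, *FSHR*,
*FSHB*, *ESR1*, *ESR2*, *GDF9*, *PRLR*) — and quantifies how much they
improve a gradient-boosted prediction of the MII count.

The pipeline operates on a `StimCohort`: a `RangedSummarizedExperiment`
whose columns are IVF processes (a patient may contribute her first and
second cycle; all cross-validation is therefore grouped by patient), whose
rows are panel variants, and whose single assay holds allele dosages
in {0, 1, 2, NA}. Every feature computation uses the *alt-presence* view
(dosage > 0): heterozygous and homozygous-alternative genotypes are not
distinguished downstream, and missing genotypes are never imputed — they
propagate to missing feature values, which the boosted trees consume
natively.

## Pipeline stages

1. **Benchmark and clinical model.** The trivial predictor is the cohort
   mean (its RMSE is the population SD). Clinical candidates, ordered by
   absolute Pearson correlation with the outcome, enter a greedy forward
   selection: a candidate is kept iff the cross-validated RMSE strictly
   decreases, with the fold assignment held fixed across all iterations.
2. **Per-variant screening.** For each variant, MII counts of carriers vs
   non-carriers are compared with the two-sample Kolmogorov–Smirnov test
   and the Mann–Whitney U test at α = 0.05; a direction (higher/lower) is
   called only when both tests are significant. No multiple-testing
   correction is applied by default (a Benjamini–Hochberg option exists):
   the screening stage is deliberately liberal because downstream stages
   re-validate everything against cross-validated RMSE.
3. **Shadow-feature ranking.** Three runs of the Boruta scheme — random
   forest permutation importance on the variants, gradient-boosted trees
   with mean |SHAP| on the variants, and random forest on variants + AMH —
   are aggregated by mean rank, and the top 20 variants survive.
4. **Correspondence analysis (CA).** Variants × MII-group carrier counts
   (five outcome groups: ≤2, (2,4], (4,7], (7,11], >11 oocytes) are
   decomposed by SVD of the standardized residuals. The count feature
   `IV_CA` sums alt-presence over the k = 3 variants nearest the target
   group (>11) in the plane of the first two principal coordinates.
5. **Self-organizing map (SOM).** A 6×6 hexagonal-grid SOM with Gaussian
   neighborhood (σ = 1.5), learning rate 0.7, Manhattan distance and
   100,000 online iterations maps genotype vectors; nodes where an extreme
   outcome group is over-represented contribute their most characteristic
   variants (largest node-minus-population alt-frequency difference). All
   2^m − 1 subsets of those ≤ 10 candidates are evaluated by the
   cross-validated RMSE of a model containing the resulting standardized
   count feature; the winner becomes `IV_SOM`, standardized with
   population (1/n) moments frozen on the defining cohort.
6. **Haplotype features.** Pairwise LD is estimated by a two-locus EM over
   the double-heterozygote ambiguity (D′, r²); blocks come from the
   four-gamete rule (default), Gabriel-style D′ confidence intervals, or
   the solid spine of LD. Block haplotypes (multi-locus EM, exhaustive to
   12 variants, partition–ligation beyond) above a 5 % frequency floor are
   screened as binary carrier features by RMSE reduction. The best blocks
   are then *reduced*: block genotypes are embedded in 2-D, K-means
   clustered (k ∈ 2..10 by silhouette), and a classification tree grown to
   purity predicts the clusters; the root-to-leaf path for the leaf
   capturing the largest cluster defines a binary feature — 1 iff every
   path variant matches its baseline state.
7. **Combination search and explanation.** Every non-empty subset of the
   genetic features (2^n − 1 combinations; 127 for five features) is added
   to the fixed clinical set and refit on identical folds; the best subset
   defines the clinical-genetic model. Per-patient explanations use an
   exact path-dependent TreeSHAP written in double precision, so the base
   value plus contributions reproduces the prediction to ~1e-12; the sum
   of the genetic contributions is reported as the patient's cumulative
   genetic impact.

## The synthetic cohort generator

No patient-level data ship with the package; `generateCohort()` produces
cohorts with the statistical structure the analysis assumes, and is itself
first-class, tested code. It emulates:

* **Clinical marginals** of the genotyped study group: age ~ discretized
  truncated normal (34.55 ± 4.20, range 18–46), BMI, FSH, LH, E2 with the
  published means/SDs, AMH log-normal truncated at the 15 ng/mL exclusion
  bound (so the exclusion filter is exercised), AFC negative-binomial with
  its mean coupled to log AMH (the two markers correlate in practice).
* **Panel allele frequencies**: the 19 distinct published panel variants
  with their printed frequencies, plus 100 independent null variants so
  screening specificity is testable.
* **Block LD** via founder-haplotype pools: within a block each individual
  draws two founders from an aligned pool, giving complete (D′ = 1) LD and
  exact ground-truth haplotypes for block-detection tests; a `recomb`
  parameter can break LD partially.
* **Outcome**: MII ~ negative binomial with log-mean
  β₀ + β_AMH·log(1+AMH) + β_AFC·AFC + β_age·age + Σ β_g·g(genotype).
  The negative binomial was chosen because MII is an overdispersed count;
  no noise model is prescribed by the source method. Defaults
  (β₀ = 1.25, β_AMH = 0.48, β_AFC = 0.012, β_age = −0.012, dispersion 5)
  were fixed once to reproduce the published outcome marginals
  (mean ≈ 5.9, SD ≈ 4.8) and a strong positive AMH–MII correlation; the
  planted genetic coefficients are free parameters documented in
  `defaultEffects()` — the source reports no genetic effect sizes in
  outcome units.
* **Structural missingness**: first cycles lack previous-stimulation
  fields; second cycles carry the first cycle's observed yields; a
  configurable fraction of processes lacks AFC.

What the generator does *not* emulate: assay noise and batch effects in
hormone measurements, population stratification, genotyping error,
realistic recombination gradients within blocks, and clinic-level protocol
heterogeneity. Tests passing on synthetic cohorts therefore validate the
*algorithms* (recovery of planted structure, calibration under the null),
not the clinical transportability of any fitted model.

```{r example, eval = FALSE}
cohort <- generateCohort(generatorConfig(seed = 1))
report <- runPipeline(cohort, pipelineConfig(seed = 2))
report
```

## Numerical and design choices

* **MII bins.** The five outcome groups are implemented as [0,2], (2,4],
  (4,7], (7,11], (11,∞): closing the first bin at 2 is the only choice
  that makes the groups exhaustive over the nonnegative integers.
* **Mann–Whitney exactness.** The exact null is used when both carrier
  groups have ≤ 8 observations and no ties; otherwise the normal
  approximation with tie correction. The KS test always uses the
  asymptotic two-sample form (MII counts are heavily tied).
* **Boruta details.** 100 iterations by default; a two-sided binomial test
  on hits at α = 0.05 decides confirmed/rejected; undecided features are
  resolved by comparing median importance with the median best-shadow
  importance. Columns are processed in sorted-name order so results are
  invariant to input column order under a fixed seed. The random-forest
  engine imputes missing alt-presence to 0 (ranger takes no NAs); the
  GBM engine passes NAs through.
* **Combined ranking.** "Combined score" is implemented as the mean rank
  across the three runs, ties broken by mean score then variant id — the
  simplest reproducible re-sort.
* **CA map.** Rows and columns are both shown in principal coordinates
  (symmetric map). Cross-set distances on a symmetric map are not χ²
  distances in the strict sense; they are used only to *rank* variants by
  proximity to one group, and the selection is invariant to rotation or
  reflection of the solution. Ties break by variant id.
* **SOM schedules.** Only the initial σ = 1.5 and learning rate 0.7 are
  prescribed; both decay linearly to a small floor (0.05 and 1e-3) over
  the iteration budget. The hexagonal neighborhood distance uses odd-r
  offset → cube coordinates. Missing inputs are imputed to 0 for map
  training only. "Over-represented" is made concrete as: node share ≥ 2 ×
  population share with node occupancy ≥ 10 (both configurable).
* **Haplotype thresholds.** Four-gamete floor 0.01, Gabriel CI bounds
  0.70/0.98 with 95 % informative-pair fraction and recombination bound
  0.90, solid-spine D′ ≥ 0.80, MAF filter 0.05 — conventional defaults,
  each configurable. D′ confidence bounds come from a flat-prior
  likelihood scan over the admissible D′ range with allele frequencies
  fixed at their EM estimates.
* **Haplotype carrier semantics.** Features evaluate on unphased
  alt-presence vectors: a process carries a haplotype iff its alt-presence
  pattern over the block matches the haplotype's allele string. A missing
  genotype at any path variant yields a missing feature value (rather than
  0), keeping missingness visible to the learner.
* **2-D embedding for reduction.** The block embedding uses classical
  (Torgerson) metric MDS on Manhattan/Hamming distances: for binary
  vectors it is deterministic, needs no tuning, and serves the only role
  the embedding has here — giving K-means a low-dimensional, metric
  representation of block genotypes. K is chosen by maximal mean
  silhouette over k ∈ 2..10; "first leaf" is the leaf predicting the
  largest cluster (largest n among such leaves).
* **Boosting.** xgboost with `tree_method = "hist"`,
  `grow_policy = "lossguide"`, 100 trees, 5 leaves, depth 16, l2 loss;
  the learning rate (0.1) is a package default, surfaced in
  `modelConfig()`. Metrics are computed on pooled out-of-fold predictions
  (more stable than averaging per-fold metrics); MAPE excludes
  zero-outcome rows (the count is logged). Folds are grouped by patient to
  prevent leakage between a woman's first and second cycle.
* **Shapley values.** Screening uses xgboost's fast native contributions;
  the explanation API re-implements path-dependent TreeSHAP in double
  precision over the dumped trees (with feature values and thresholds
  round-tripped through float32 so traversal matches the library
  bit-for-bit). This keeps the additivity identity exact to ~1e-12 instead
  of the ~1e-6 float32 noise of the native path.

## Problem sizes used in validation

The shipped tests validate on: toy panels of ≤ 14 variants against
brute-force oracles; screening calibration on 200 outcome permutations of
a 300-process cohort; planted-signal recovery on cohorts of 400–2,000
processes across 10 seeded runs per claim; and one compact end-to-end
pipeline run (150 patients, reduced Boruta/SOM iteration counts). The
acceptance script runs the full pipeline at the study's own size (264
patients, 516 processes) with 50 shadow-feature iterations per ranking
run and the default 100,000 SOM iterations.

## Known limitations

* The subset and combination searches are exhaustive by design and
  therefore bounded (≤ 15 and ≤ 7 features respectively).
* Two-locus EM assumes random mating when resolving double heterozygotes;
  departures (inbreeding, strong stratification) bias D′ estimates.
* The CA proximity rule inherits the symmetric-map caveat above; with a
  near-independent table (tiny inertia) the "nearest" variants are noise.
* Haplotype reduction assumes the dominant K-means cluster is the
  scientifically meaningful one; with balanced clusters the choice of
  leaf, and hence the path, can be unstable between seeds.
* Forward selection is greedy; correlated clinical covariates (AMH and
  AFC) can mask one another, and on small cohorts the deep default trees
  can overfit so severely that no clinical candidate beats the benchmark —
  the pipeline then legitimately reports an empty clinical set and falls
  back to the mean predictor as reference.
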