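---
title: "Multi-omics subtype discovery with omicsubtype: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics subtype discovery with omicsubtype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsubtype)
```

# Overview

`omicsubtype` implements an end-to-end protocol for discovering prognostic
tumor subgroups from three matched molecular layers per patient — mRNA
expression, copy-number aberration (CNA) and DNA methylation (MET) — plus a
clinical table with overall survival (OS), age, gender and optional PAM50
labels. This vignette documents the model and its assumptions, the
parameters that matter, the synthetic world used for validation, and the
numerical conventions, in the spirit of the methods sections of mature
omics packages.

# The pipeline, stage by stage

## Preprocessing

Inputs arrive as cBioPortal-style tab-delimited matrices. The chain is:
keep female patients (male and unknown-gender breast-cancer records are
minor cases and removed); intersect the sample sets of the three matrices
and the clinical table; drop genes with *more than* 50% missing values (a
gene missing in exactly half the samples is retained — the boundary is
strict); impute the rest by gene-wise k-nearest neighbours; optionally
truncate follow-up at an administrative horizon, which censors rather than
drops patients (so event counts can only decrease; dropping long-lived
patients would bias survival upward).

Two conventions deserve a note:

* **Sample order.** After matching, samples are ordered lexicographically.
  Every downstream stochastic stage (k-means restarts, perturbation draws)
  consumes randomness in sample order, so a canonical order makes whole
  pipeline runs bit-reproducible regardless of input column order.
* **kNN imputation** treats genes as objects and samples as features
  (classical expression-array practice, k = 10). Distances are
  root-mean-square Euclidean over the samples two genes both observe —
  normalizing by the number of shared samples keeps genes with different
  missingness patterns comparable. Donors must themselves observe the
  target sample. The masked-entry test verifies this beats column-mean
  imputation in RMSE whenever rows are correlated.
* **Duplicate gene symbols** are dropped entirely by default (an ambiguous
  symbol cannot be attributed to either copy); `keep_first` is available
  when upstream ordering is meaningful.

## CNAcor and METcor genes

For each gene shared between a DNA layer and mRNA, the Pearson coefficient
is computed across matched samples, with the exact two-sided t test on
n − 2 df. Genes at p ≤ 0.05 — raw, not FDR-adjusted; multiplicity control
is deliberately deferred to the survival screen, where decisions are made
gene by gene — form the CNAcor/METcor sets. Their coefficients are mapped
through the Fisher transformation Z = ½·ln[(1+r)/(1−r)] and the skewness of
the Z distribution is tested with the D'Agostino statistic (moment-ratio
g1, Johnson SU normalization, two-sided normal p). On real cohorts the
CNA–mRNA Z distribution skews right (dosage drives expression) and the
MET–mRNA distribution skews left (methylation silences); the sign of the
skew, not its magnitude, is the biological readout.

Degenerate rows (zero variance, |r| = 1 exactly) are dropped with a
warning rather than clamped: Fisher Z is undefined there, and a synthetic
duplicated gene should not crash the skewness stage. The sign constraint
on selection defaults to `"any"`, matching significance-only selection;
`"positive"`/`"negative"` are available as an explicit stance.

## Survival screening

Two distinct screens exist because they answer different questions:

* `cox_feature_select()` — univariate Cox on the *continuous* value; used
  to thin the CNAcor/METcor sets to prognostic genes before clustering.
* `univariate_cox_median()` — dichotomize at the median ("up-regulation"
  strictly above; ties fall "down", since only values *greater than* the
  median are up), Cox on the indicator, HR with Wald 95% CI, and BH
  q-values computed within each gene set separately (CNAcor and METcor are
  corrected as separate families, mirroring their separate reporting).

The reported p is the score test, which for a single binary covariate *is*
the logrank test — this is why Cox output is conventionally labelled
"logrank p" in this literature. Ties in event times use the Efron
approximation, the default of the mainstream survival implementations this
field relies on. Whether the continuous or a dichotomized value enters the
pre-clustering Cox filter is not fully determined by the upstream
literature; the continuous form is used, matching the semantics of the
CancerSubtypes-style `FSbyCOX` filter.

## Perturbation clustering and k selection

The stability machinery follows the perturbation-clustering idea (PINS
family): a partition you should trust is one that survives noise.

1. Cluster the original samples×features matrix at k (k-means,
   Hartigan–Wong, 20 restarts, best inertia).
2. Draw `n_perturb` copies with added i.i.d. Gaussian noise, sd =
   `noise_scale` × median per-feature sd; cluster each; average their
   binary connectivity matrices.
3. Let D be the entrywise |original − averaged| over off-diagonal pairs.
   The stability score is the area under the empirical CDF of D on [0, 1]
   (equivalently 1 − mean(D)); AUC = 1 iff every perturbed partition
   reproduces the original.
4. k* = argmax AUC over k ∈ [2, 10]; ties break toward the smallest k
   (parsimony). If no k reaches AUC 0.9 the result is flagged "no strong
   structure" — a diagnostic, not an error; the argmax is still returned.

The noise calibration deserves emphasis: because the sd is the *median*
per-feature sd, a realistic data set — where informative features are a
minority — is perturbed at roughly the noise level of its uninformative
features. A toy data set whose every feature carries class signal gets
perturbed at the signal scale instead and will look less stable than it
is; test fixtures therefore embed class separation in a feature subset,
which is also the honest analogue of omics data.

Integration fuses layers at the connectivity level: per layer and per k,
the perturbation-averaged connectivity; across layers, the unweighted
entrywise mean (no weighting scheme is justified a priori, and the mean
keeps the fused matrix in [0,1] with unit diagonal). The fused
dissimilarity 1 − S_k is cut at k by *hierarchical* clustering
(average linkage) — hierarchical rather than k-means for the integrative
step, for comparability with how expression-based intrinsic subtypes were
originally derived — and scored by the same AUC with the fused S_k playing
the role of the averaged connectivity. Fusion helps exactly when layer
errors decorrelate: each layer misplaces different borderline samples, and
the fused co-clustering average acts as a vote across layers.

Degenerate perturbed partitions (an empty cluster) are resampled up to
three times; k-means with k ≤ 10 on ≥ 30 samples essentially never
exhausts the retries.

## Subgroup-specific genes

Each candidate gene is assigned to the subgroup with the largest mean
value and kept if one-way ANOVA across subgroups gives p ≤ 0.05 (raw — the
procedure is descriptive labelling, not inference over the genome). Exact
mean ties go to the lowest-indexed subgroup and are flagged. The candidate
list is an explicit argument: the three published-style lists are produced
by scanning the full mRNA matrix, the CNA matrix restricted to CNAcor
genes, and the MET matrix restricted to METcor genes. Zero within-group
variance with distinct means yields F = ∞, p = 0 by convention.

## Downstream characterization

Per-subgroup n, mean age, mean observed follow-up and PAM50 composition;
within-subgroup logrank between age ≤ 65 and age > 65 (65 is the
conventional geriatric threshold and the mode of the age distribution in
the motivating cohorts); CNA burden — defined here, since no standard
definition exists, as the fraction of genes with |log-ratio| > 0.3 per
sample, threshold configurable — compared between subgroups by the Welch
unequal-variance t test; and a deliberately descriptive OLS fit of the
binary subgroup indicator on per-sample CNA burden and mean methylation
(the output carries a note that a linear fit of a binary outcome is
descriptive; a logistic option exists). The regression mirrors a published
observation that the subgroup–omics relationship is *not* well captured
linearly — its purpose is diagnostic contrast with the nonlinear
clustering, not modeling.

# The synthetic world

`generate_cohort()` plants exactly the structure the analysis assumes, so
every pipeline claim is testable against ground truth:

* CNA and MET values i.i.d. N(0,1) per gene; mRNA N(0,1) except planted
  genes.
* CNAcor genes: mRNA = slope·CNA + ε; METcor genes: mRNA = −slope·MET + ε,
  with slope 1 and ε ~ N(0, 0.5) by default, giving per-gene |r| =
  1/√1.25 ≈ 0.894.
* Two subgroups (75/25 by default) expressed as a 1.5-sd mean shift in a
  random 10% of each layer's genes.
* Exponential survival with log hazard = Σ 0.2·(standardized prognostic
  gene values) + log(4.25)·(minority subgroup); the Cox model is thereby
  correctly specified, so estimator bias in tests isolates implementation
  errors from model misfit. The subgroup hazard ratio and the ~6-year age
  shift of the minority subgroup take the magnitudes reported for real
  breast-cancer subgroups of this kind.
* Independent exponential censoring whose rate is root-solved against the
  realized hazards so the expected censored fraction hits the target
  (default 60%; a naive rate-ratio calibration misses badly once the
  linear predictor has variance ~1).
* Ages N(58.6 + shift, 12²), 5% male samples, 5% missing cells, optional
  PAM50-style labels whose composition differs by subgroup
  (LumA-dominant majority, LumB-dominant minority).

Presets: `default` (above), `null` (every effect zeroed — used for type-I
tests), and `integration-gain` (subgroup shift thinned to 1.25 sd in 10%
of features, calibrated so each single layer clusters imperfectly, ARI
typically < 0.9, while the fused partition recovers the planted labels in
≥ 18/20 seeded replicates). What the generator does *not* emulate: real
marginal distributions (beta-value bimodality of methylation, CNA
segmentation structure, heavy-tailed expression), gene–gene correlation
beyond the planted couplings, or informative censoring. A green test
therefore establishes algorithmic correctness on the assumed structure,
not performance on any particular real cohort.

The per-gene prognostic effect (0.2 × 20 genes) was chosen so the
linear-predictor sd stays near 0.9 — a heterogeneous but plausible cohort;
single-gene power scenarios at log-HR 0.8 are exercised separately in the
tests with exactly that stated value.

# Numerical conventions and edge cases

* Fisher Z errors on |r| ≥ 1 (upstream code drops such records first).
* The D'Agostino skewness test requires n ≥ 9; smaller significant-gene
  sets skip the skew characterization with a warning.
* BH is the textbook step-up with capping at 1; it is order-invariant and
  agrees with `p.adjust(, "BH")` (used as an oracle in tests only).
* The AUC summary uses the exact identity ∫₀¹ F̂ = 1 − mean(D) for D in
  [0, 1], verified in tests against numerical ECDF integration.
* Chi-square overlap tests are Pearson, without continuity correction, so
  the 2×2 hand formula n(ad−bc)²/(r₁r₂c₁c₂) holds exactly.
* All randomness flows from explicit seeds: the generator seeds once and
  draws everything from that stream; the pipeline derives stage seeds from
  `config$seed` (+0, +1, +2 for CNAcor, METcor and integrated clustering).
  Identical seeds give bit-identical results and file hashes.

# Known limitations

* The perturbation scheme and fusion rule are one reconstruction of the
  perturbation-clustering family; published AUC values from other
  implementations are not expected to reproduce numerically.
* No penalized or multivariate Cox; the screens are univariate by design.
* The CNA burden definition is a documented convention, not a community
  standard.
* Probe-level methylation and raw copy-number segmentation are out of
  scope: inputs are gene-level matrices.
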