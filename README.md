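# omicsubtype

Multi-omics perturbation clustering for prognostic cancer subtype discovery.

## The problem

Breast tumors (and cancers generally) are routinely profiled on three
molecular axes per patient: mRNA expression, DNA copy-number aberration
(CNA, log-ratio scale) and DNA methylation (MET). Expression-only
classifications such as the PAM50 intrinsic subtypes ignore the genomic and
epigenomic layers, and their subgroups align imperfectly with patient
outcome. `omicsubtype` implements a reusable, tested pipeline that

1. selects genes whose expression is *driven* by the DNA layers — **CNAcor**
   genes (expression correlated with copy number) and **METcor** genes
   (expression anti-correlated with methylation);
2. keeps the prognostic ones (univariate Cox association with overall
   survival);
3. discovers patient subgroups by **perturbation-stability clustering** of
   each layer and by **connectivity fusion** of all three layers; and
4. characterizes the subgroups: Kaplan–Meier/logrank survival, hazard
   ratios, subgroup-specific genes, PAM50 composition, age interaction and
   CNA burden.

It is aimed at computational biologists who want the whole protocol as
composable R functions with a planted-truth synthetic cohort generator for
validation and power analysis.

## The statistics at the core

**Gene selection.** For each gene \(g\), the Pearson correlation \(r_g\)
between its CNA (or MET) row and its mRNA row is computed across matched
samples, with the exact two-sided t test on \(n-2\) df. Significant
coefficients (\(p \le 0.05\)) are variance-stabilized by the Fisher
transformation \(Z = \tfrac12 \ln\frac{1+r}{1-r}\), and the skewness of the
resulting \(Z\) distribution is tested with the D'Agostino statistic — a
right skew of the CNA–mRNA \(Z\) values indicates genome-wide positive
dosage coupling, a left skew of MET–mRNA indicates epigenetic silencing.

**Survival screening.** Each candidate gene is screened by a univariate Cox
proportional-hazards model (score test = logrank test for one covariate;
Efron ties). The median-split screen dichotomizes patients at the gene's
median expression and reports the hazard ratio (up vs down) with Wald 95%
CI, logrank p and Benjamini–Hochberg q.

**Perturbation clustering.** For a candidate cluster number \(k\), the data
are clustered (k-means, 20 restarts), then `n_perturb` Gaussian-noise
perturbed copies are clustered and their binary co-clustering (connectivity)
matrices averaged. The discrepancy \(D = |C_0 - \bar C|\) over sample pairs
is summarized by the area under its empirical CDF on \([0,1]\): AUC = 1
means every perturbed partition equals the original. \(k^\*\) maximizes the
AUC over \(k \in [2, 10]\). Integration fuses the per-layer perturbed
connectivity matrices by their unweighted mean into a similarity matrix
\(S_k\) and cuts \(1 - S_k\) by average-linkage hierarchical clustering.

**Subgroup-specific genes.** Each gene is assigned to the subgroup where its
mean value is largest and kept if the across-subgroup difference is
significant by one-way ANOVA (\(p \le 0.05\)).

## Worked example

```r
library(omicsubtype)

co  <- generate_cohort(preset_params("default"), seed = 42)
cfg <- pipeline_config(k_range = 2:4, n_perturb = 10, seed = 42)
res <- run_pipeline(co$mrna, co$cna, co$met, co$clinical, cfg)
res
#> PipelineResult: 285 samples, k* = 2 (AUC = 0.741), logrank p = 1.38e-33
length(res$genecor$cna$selected)   # 55 CNAcor genes (50 planted)
length(res$genecor$met$selected)   # 54 METcor genes (50 planted)
res$subgroup_survival$cox
#> HR 7.96 (95% CI 5.39-11.76)
res$downstream$summary[, 1:4]
#>   subgroup   n mean_age mean_survival_time
#> 1   IntCl1 213 60.03479           34.55208
#> 2   IntCl2  72 66.20057            9.24288
adjusted_rand_index(res$labels, co$truth$labels[res$cohort$clinical$sample_id])
#> 0.985
```

The generator planted two subgroups (75/25) expressed jointly in all three
layers, with the minority subgroup ~6 years older and carrying a strongly
elevated hazard; the pipeline recovers the planted partition (ARI 0.985),
selects `k* = 2`, and reports the worse survival (mean observed follow-up
9.2 vs 34.6 months) and older age of the minority subgroup. The 55 selected
CNAcor genes are the 50 planted ones plus false positives at the 5% level.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli","omicsubtype.R",package="omicsubtype"))') \
    simulate --preset default --out data/ --seed 1
... run-all --mrna data/mrna.tsv --cna data/cna.tsv --met data/met.tsv \
    --clinical data/clinical.tsv --out results/ --seed 1
```

Subcommands: `simulate`, `run-all`, `genecor`, `cluster`. Inputs are
cBioPortal-style tab-delimited matrices (`Hugo_Symbol` [+
`Entrez_Gene_Id`] + one column per sample) and a clinical TSV
(`SAMPLE_ID`, `OS_MONTHS`, `OS_STATUS`, `AGE`, `GENDER`[, `PAM50`]).

## Vignette

See `vignettes/multiomics-subtyping.Rmd` for the methods: model
assumptions, tunable parameters, what the synthetic generator does and does
not emulate, and numerical conventions.
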