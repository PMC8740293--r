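---
title: "Genomic prediction for germplasm collections: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction for germplasm collections: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(peagp)
```

## The problem

Large crop germplasm collections are cheap to genotype and expensive to
phenotype. Genomic prediction closes that gap: a training set of accessions
with both genotypes and multi-year phenotypes is used to learn a map from
markers to breeding values, which is then applied to the genotyped-only
remainder of the collection, with a per-accession reliability attached so a
breeder knows which predictions to trust. `peagp` implements that workflow
end-to-end for panels of inbred accessions genotyped by sequencing (GBS),
and pairs it with a synthetic-data generator with known truth so every
stage is testable without any external download.

## The phenotypic model

Multi-year records are reduced to one entry value per accession with the
random-effects model

y_ij = mu + G_i + E_j + (GE)_ij + e_ij,

where G_i is the accession (genotype) effect, E_j the year effect, (GE)_ij
their interaction, and e_ij the residual — all random. Fitting is by REML
(lme4 backend, the standard tool for exactly this model), and the accession
BLUPs become the response for every prediction model downstream.

Two heritability estimators are reported:

* entry-mean: H² = σ²G / (σ²G + σ²GE/j + σ²e/(j·r)), with j years and r the
  harmonic mean of per-accession replicate counts;
* Cullis: H² = 1 − mean(PEV)/σ²G, built from the prediction error variances
  of the BLUPs (the relationship matrix here is the identity, so its mean
  diagonal is 1).

**Identifiability note.** With one record per accession-year — the usual
situation for unreplicated collection trials, and what the generator
produces — σ²GE and σ²e cannot be separated; only their sum is identified.
The fitter detects this and drops the interaction term, attributing the sum
to the residual. Entry-mean H² is unaffected (with r = 1 only
σ²GE/j + σ²e/j enters). With replicated records the full four-component
model is fitted. The noiseless limit (zero residual) breaks REML iterations
and is handled by an exact closed-form path.

## Prediction models

All models share one contract: fit on a training genotype matrix and BLUP
vector, predict any new genotype rows. Genotypes are coded 1 = homozygous
major, −1 = homozygous minor, 0 = heterozygous; every fit centres marker
columns on *training* means, which makes results invariant to the
(0, 1, 2) vs (−1, 0, 1) coding choice up to the intercept.

* **RR-BLUP / GBLUP.** Ridge regression with all marker effects from one
  normal distribution, fitted by REML through the eigendecomposition of the
  marker kernel K = ZZ'/c with c the mean diagonal — a one-dimensional
  profile over the variance ratio. Marker effects come from the ridge
  identity u = Z'(ZZ' + λI)⁻¹(y − μ), so RR-BLUP and GBLUP give identical
  GEBVs (verified to 1e-6·sd in the tests). PEVs come from the
  mixed-model-equation coefficient inverse, with fixed effects accounted
  for.
* **PLSR.** NIPALS partial least squares; components maximize covariance
  between score and deflated response; the count is chosen by five-fold CV
  (smallest count within numerical reach of the minimum PRESS, so exact
  low-rank signals select the minimal model).
* **Random forest.** randomForest with mtry = p/3 and node size 5; the tree
  count is tuned by five-fold CV, scoring truncated ensembles from a single
  maximal forest per fold.
* **BayesC-pi.** Each marker is null with probability pi, else drawn from a
  common normal; pi has a uniform prior and is sampled per iteration from
  its beta full conditional. Both variances carry scaled-inverse-chi-square
  priors with nu0 = 5; scales are elicited from var(y) split by an assumed
  heritability of 0.5, with the genetic share spread over the *included*
  marker fraction (divided by max(1 − pi, 1/p)). That last division
  matters: with a static per-marker scale, null data leave pi unidentified
  (the inclusion Bayes factor is ~1 when the effect variance is
  negligible, so pi performs a random walk); spreading the budget over the
  included fraction makes exclusion self-reinforcing on null data and
  recovery sharp on sparse data. The Gibbs sampler runs in compiled code
  on R's RNG, so chains are reproducible from a seed. Defaults: 20000
  iterations, 5000 burn-in, thinning 5; scaled-down chains are used in
  cross-validation loops.
* **RKHS.** Gaussian kernels exp(−h·d²/s) on squared Euclidean genotype
  distances, with s the mean off-diagonal squared distance so the printed
  bandwidths h = 0.5·{1/5, 1, 5} act on a standardized scale. The
  multi-kernel fit estimates one variance component per kernel
  (Nelder-Mead on the restricted likelihood over log-variances) and
  averages the kernels by their variance shares; final GEBVs and PEVs come
  from GBLUP on the averaged kernel. On panels whose genotype distances
  concentrate (no structure), the three bandwidths are nearly
  indistinguishable — all kernels are close to compound-symmetric — so
  kernel-weight interpretation is only meaningful when the panel has real
  distance spread.

## Cross-validation designs

`run_cv` implements the 80/20 random split (20 replicates by default) and
k-fold schemes; splits are drawn on lexicographically sorted accession IDs,
so results do not depend on input row order. Every preprocessing statistic
— column means, PC loadings, hyperparameter tuning — is computed on
training folds only (a planted validation-outlier test enforces this).
Predictive ability is the Pearson correlation between predicted GEBVs and
the full-data BLUPs of the validation accessions; using full-data BLUPs as
the reference is the field's convention for germplasm studies, though not a
strictly out-of-sample target, and the replicate means carry 10,000-sample
percentile bootstrap confidence intervals.

Specialized designs: training-size curves (validation sets of 50, training
sets nested as they grow 50→175 by 25), marker-density curves (random
marker subsets, five-fold CV, folds shared across subset sizes so the curve
is paired), structure-adjusted CV (top-10 PCs computed within training
folds and projected onto validation, an external admixture Q-matrix, or
subpopulation-factor contrasts entering RR-BLUP as fixed effects), and
within- vs leave-one-subpopulation-out prediction.

One statistical subtlety: when checking that models are unbiased on
pure-noise phenotypes, the 20 replicates must each draw fresh noise. With a
single shared draw the replicate abilities are conditionally biased
together and the replicate standard error understates the variance of the
mean — a sparse model can sit three standard errors from zero purely
because of the draw.

## Reliability screening

Nonphenotyped accessions are carried as unknowns in the mixed-model
equations of the kernel form, so every accession has a GEBV and a PEV; the
reliability 1 − PEV/σ²G uses the marker-based REML σ²G from the same fit.
PEVs come from a direct inverse of the MME coefficient matrix — exact and
cheap at collection scale (n ≲ 1000). Reliabilities are clipped to [0, 1]
with a warning; values above σ²G arise legitimately for accessions whose
kernel diagonal exceeds the panel average. The calibration identity — mean
reliability of masked accessions ≈ squared GEBV-TBV correlation — is
verified by simulation to within ±0.1. Screening tables flag the top and
bottom 50 nonphenotyped accessions by GEBV, ties broken by accession ID.

## The synthetic-data generator

The generator emulates a GBS'd inbred collection:

* **Structure.** Balding-Nichols subpopulation allele frequencies
  (divergence parameter F) with Dirichlet admixture per accession — the
  minimal model under which >60%-ancestry assignment and PC covariates are
  meaningful.
* **LD.** Markers in blocks share a latent Gaussian haplotype signal with
  AR(1) decay (correlation ≈ exp(−3·d/block size)), which reproduces the
  plateauing marker-density curve.
* **Inbreds.** True genotypes are homozygous (±1); heterozygous calls are
  injected only as defects, which is why the het filter exists.
* **Defects.** Low-QUAL sites, site-wise heterozygosity injection (a
  fraction of sites receive ~25% het calls — defects cluster by locus),
  per-call missingness, optional high-missingness sites, and appended
  low-MAF / multiallelic decoy sites, all with exact bookkeeping so filter
  counts are checkable.
* **Phenotypes.** Marker effects normal (polygenic) or sparse (n_qtl
  mode); σ²G is *defined* as the realized variance of the true breeding
  values; the `h2` argument is the entry-mean heritability over the
  simulated years (j = n_years, r = 1), so the entry-mean estimator should
  recover it directly — the year-effect variance is fixed at 0.5·σ²G and
  does not enter heritability. MAF floors are enforced by rejection
  resampling.

What the generator does **not** emulate: read-level sequencing error,
augmented-design check plots and spatial field trends, linkage maps with
physical coordinates, selection or pedigree structure, and
non-additive genetic action (beyond what RKHS/RF can pick up from the
additive simulation). Passing tests therefore demonstrate correctness of
the machinery and its statistical calibration under a clean additive
model — not that any particular real collection will reach the same
predictive abilities.

## Numerical choices

* REML (single kernel): 1-D profile over log variance ratio on [−18, 18];
  multi-kernel: Nelder-Mead over log variances, 2000 iterations, reltol
  1e-10; variance ratios are capped at 1e8 before the weighted solve.
* k-NN imputation: distances are mean squared differences over markers
  observed in both accessions (vectorized via cross-products); vote ties
  resolve toward the more frequent genotype at the marker, then toward 1.
* Filter rule order is fixed: biallelic → MAF → QUAL → missingness →
  heterozygosity; boundaries: keep MAF ≥ 0.05, keep QUAL ≥ 20, keep
  missingness ≤ 0.80, keep het < 0.20 (strict); an all-missing site falls
  to the missingness rule rather than dividing by zero.
* Major-allele ties (exact 50/50) resolve toward the VCF reference allele.
* Ancestry exactly at the 60% threshold is admixed (strict >).
* PCA signs are fixed by making each component's largest-magnitude loading
  positive, so repeated runs are byte-identical.

## Problem sizes

The bundled analysis scripts use a 480 x 5000 panel with 7 subpopulations
and three traits (entry-mean h² 0.85 / 0.75 / 0.45, the observed range for
collection traits), 10 cross-validation replicates per cell, and
scaled-down MCMC chains (3000/1000/2); the test-suite simulations use
panels from 150 x 800 up to 480 x 3000 (and 200 x 30000 for the
marker-density plateau), sizes at which every check runs in minutes on one
CPU while leaving the statistical conclusions stable across seeds.

## Known limitations

* Reference abilities use full-data BLUPs (the field convention); a
  leak-free variant (refitting the phenotypic model within training folds)
  is available by passing the training-subset BLUPs explicitly.
* PEV-based reliability is defined only for the MME-based models (RR-BLUP,
  RKHS/GBLUP); PLSR, random forest, and BayesC-pi predictions carry no
  analytic PEV.
* The admixture Q-matrix is consumed, not estimated: ancestry estimation
  belongs to external software, and simulations provide the true Q.
* Multi-trait models, dominance/epistasis terms, spatial adjustment, and
  training-set optimization criteria (CDmean and relatives) are out of
  scope.
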