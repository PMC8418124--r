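---
title: "Methods: TME phenotype discovery and scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TME phenotype discovery and scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery behind `tmescore()`, the
choices made where the design was genuinely open, and what the synthetic
benchmark does and does not establish.

## Model overview and assumptions

The package treats a bulk tumor expression profile as an approximately
linear mixture of cell-type reference profiles plus gene-level noise, and a
patient's tumor-microenvironment (TME) state as a latent phenotype visible
through the mixture weights. The pipeline estimates the weights
(deconvolution), clusters them into phenotypes, finds genes that track the
phenotypes, keeps the prognostic ones, compresses them into a small
signature, and reads the signature out as one number per patient.

Assumptions worth keeping in mind:

* **Linearity on the natural scale.** Deconvolution operates on linear
  (TPM-like) values, where mixing is additive. All other stages use
  `log2(x + 1)`, where fold changes are additive and variances are closer
  to homoscedastic. The pipeline converts internally; inputs declare their
  scale.
* **Proportional hazards.** Cox screening, direction assignment and the
  log-rank machinery assume proportional hazards for the groups being
  compared.
* **Two dominant phenotypes.** Differential expression contrasts the k = 2
  consensus partition. The consensus scan still reports the selected k; if
  it is not 2 the fit warns and proceeds with the two-group contrast.

## The stages and their tunable parameters

### Deconvolution (`nusvr_deconvolve`)

Per sample, the mixture restricted to genes shared with the reference is
z-standardised together with the reference columns, and a linear
ν-support-vector regression (cost 1) is fitted for each ν in
{0.25, 0.5, 0.75}. Negative coefficients are clipped to zero and the
remainder renormalised to a fraction vector on the probability simplex. The
ν minimising the reconstruction RMSE wins, ties toward smaller ν.
Significance (when requested) is a permutation p-value: the mixture values
are permuted across genes and the best-fit Pearson r recomputed; the
p-value is the fraction of permutations reaching the observed r. The
permutation null permutes the mixture itself rather than resampling from a
parent expression distribution — a simpler, self-contained null than the
original web tool's, and documented as such. A standalone analysis defaults
to 100 permutations (the classical choice is 1000); inside `tmescore()`
permutations default to 0 because no downstream stage consumes the p-value.
Gene coverage below 80% of the reference warns; below 50% it is an error.

The reference matrix is an input, not a bundled asset: published leukocyte
matrices are licensed data, and the synthetic generator provides a
marker-structured stand-in for development and testing.

### ssGSEA and immune/stromal scores

The per-sample enrichment of a gene set is the integrated difference
between the rank-weighted (exponent α = 0.25) cumulative distribution of
set members and the uniform one of non-members, walking genes in decreasing
rank order; ties get average ranks, so scores are invariant under any
strictly increasing transform of one sample's values. Scores are reported
unnormalised by default (published variants disagree on rescaling; a
min–max variant is available by flag). `estimate_scores()` is the sum
convention: ImmuneScore + StromalScore = ESTIMATEScore.

### Consensus clustering (`consensus_cluster`)

For each candidate k, items are subsampled at `item_fraction = 0.8`
without replacement `n_resamples` times, clustered (PAM on Euclidean
distance for samples; hierarchical average-linkage on 1 − Pearson for
genes), and the consensus matrix accumulates co-cluster over co-sample
counts. Final labels come from the base clusterer applied to
1 − consensus. Defaults mirror the consensus-clustering literature:
resamples 1000, k scanned 2–6. The tests and the bundled benchmark use 50
resamples, which keeps a 400-sample run in tens of seconds and already
drives consensus entries to near 0/1 on separated data.

k is selected by the largest relative increment of the area under the
consensus CDF (delta-area), ties toward smaller k. The delta-area rule is a
package decision — the elbow criterion is the community default but no
single rule is canonical.

PAM itself is the classical BUILD + steepest-descent SWAP algorithm
(via the `cluster` package). SWAP converges to a local optimum of the
total-dissimilarity objective; on tiny instances the tests certify every
non-global solution as a genuine swap-local optimum.

### Moderated differential expression (`moderated_t_test`)

Per gene: mean log2 difference, pooled residual variance s² with d = n − 2
degrees of freedom. Hyperparameters (d0, s0²) are fitted by matching the
moments of log s² to a scaled-F model (trigamma inversion of the excess
variance of log s²); the posterior variance is
(d0·s0² + d·s²)/(d0 + d) and p-values use d0 + d degrees of freedom. When
the gene variances show no excess spread, d0 = ∞ and the common variance
(arithmetic mean of s²) is used for every gene, which reduces the statistic
to the ordinary pooled t. The implementation is checked against an
independent reference implementation of the same empirical-Bayes model to
1e-8. DEGs are selected at BH-adjusted p < 0.01 and ranked by |t|; the
ranking criterion is a package decision (the threshold is the standard
one, the ranking is not specified anywhere authoritative).

### Survival machinery

Kaplan–Meier, log-rank and Cox fits delegate to the `survival` package
(Efron tie handling by default; Breslow available). Features are z-scored
before univariate Cox screening so hazard ratios are per SD and comparable
across genes; the screening threshold defaults to p < 0.05. The maximally
selected cutpoint scans every split that leaves ≥ `minprop = 0.1` of
samples on each side, using a closed-form two-group log-rank statistic
(validated against `survdiff` to 1e-9). The naive chi-square p-value of the
maximal statistic is optimistic because the maximum runs over many
correlated statistics; a permutation-corrected p (default 1000 permutations
when requested) is provided rather than an asymptotic band, because it is
direct to verify.

### Signature selection (`svm_rfe_rank`, `select_signature`)

A linear soft-margin SVM (C = 1) is trained on the current gene set, genes
are scored by squared weight, and the lowest ⌈10% of remaining⌉ are dropped
per round (one at a time once fewer than 20 remain); rank 1 is the last
survivor. The signature size is then chosen by stratified cross-validated
accuracy over a grid of top-m sets (default 10–300 in steps of 10, clipped
to the pool), ties toward the smaller size. On the bundled benchmark the
accuracy plateau is reached by small signatures, so the tie rule selects
compact gene sets; on noisier real cohorts the grid search matters more.

### Scoring (`fit_pc1`, `assign_direction_sets`, `tme_score`)

Signature genes are consensus-clustered on 1 − Pearson correlation so each
cluster is a co-expression programme. Per cluster, genes are z-scored and
the first principal axis of the samples × genes matrix extracted; the sign
of PC1 is chosen so the sample score correlates positively with the
cluster's mean z-scored expression — PCA is sign-ambiguous and without a
convention the score's direction would be undefined. A univariate Cox fit
on the oriented PC1 score assigns the cluster to direction *i* (HR > 1) or
*j* (HR ≤ 1; the boundary HR = 1 goes to *j*), and

TME-score = Σ over *i*-clusters of PC1 − Σ over *j*-clusters of PC1.

Both sums are over *cluster-level* PC1 scores; the alternative reading (one
PCA per pooled direction set) is not used because per-cluster components
keep co-expression programmes intact. When the model is applied to a new
cohort, genes are re-standardised within that cohort before projection —
cross-platform cohorts have incomparable location/scale even after batch
correction — with a flag to reuse training parameters instead. Missing
signature genes are tolerated to 80% coverage; their loadings are dropped
and the affected loading vector renormalised to unit norm.

### Immunotherapy readouts

CYT is the geometric mean of the two cytolytic markers (GZMA, PRF1) on TPM
scale with a 0.01 pseudocount; GEP is the unweighted mean of log2
expression over a user-supplied 18-gene inflamed panel (the panel's
published weights are not reproduced; the gene list is an input).

## The synthetic benchmark

`generate_cohort()` draws, per patient, a latent phenotype (fair coin),
cell fractions from a phenotype-specific Dirichlet, expression as
reference × fractions with multiplicative log-normal noise (SD 0.5 on the
log2 scale), planted differentially expressed background genes (100 genes,
2 log2 units; half up in each phenotype so both hazard directions are
populated), an additive per-batch log2 shift (+1, two batches), and
exponential survival whose hazard doubles in phenotype 1, with uniform
censoring calibrated to 30%. Default scale: 400 samples × ~2000 genes ×
8 cell types — large enough for stable recovery, small enough that a full
discovery run completes in about a minute.

The phenotype tilt (Dirichlet concentration 4 on two "suppressive-like"
cell types for phenotype 1 versus two other types for phenotype 2, all
others 1) was chosen once as a realistic degree of overlap: the two
phenotypes share most of their compositional space, so perfect recovery is
not attainable by any method — the tests document recovery *near* the
mixture's intrinsic ceiling rather than a trivially separable toy.

A `biology_seed` separate from the sampling seed fixes the
cohort-invariant biology (reference profiles, identity and direction of
planted DEGs) so that independent cohorts can be drawn from one disease
process — the setting in which external validation of a trained signature
is meaningful.

What the generator does **not** emulate: realistic gene–gene covariance
beyond the cell-type mixture, platform-specific probe effects, non-linear
batch distortions, competing risks, or tumor-cell content varying with
phenotype. Passing the benchmark therefore shows the pipeline recovers the
structure it models; it does not certify performance on any particular
real cohort.

## Numerical and degenerate-input choices

* Quantile normalisation gives tied values the mean of their tied
  positions' reference values, so ties stay tied; the operation is
  idempotent.
* Batch correction refuses batches with fewer than two samples, passes a
  single batch through unchanged, and leaves genes that are constant
  within some batch unadjusted (with a warning) rather than dividing by a
  zero scale.
* Zero-variance genes are excluded from DE hyperparameter fitting, skipped
  (flagged) in Cox screening, and dropped (warned) from PC1 fits; a gene
  flat in both DE groups gets t = 0, p = 1.
* Duplicate gene identifiers collapse to the row with the highest mean
  expression; identifiers are opaque case-sensitive strings.
* RMSE ties across the ν grid, accuracy ties across signature sizes, and
  delta-area ties across k all break toward the smaller value, keeping
  every selection deterministic.
* Model JSON is written with 17 significant digits so a round trip
  reproduces scores bitwise.
* All stochastic stages take explicit integer seeds; a fit is a pure
  function of (data, parameters, seed).

## Problem sizes used by the test-suite

Unit tests run each stage at the smallest size that exercises its
behaviour (tens to hundreds of samples, hundreds of genes). The end-to-end
checks use the default 400-sample benchmark with 50 consensus resamples,
and the recovery experiments use 20-seed replicates (Cox bias, cutpoint
location) or 5–10 seed replicates (SVM-RFE, DEG recovery). These sizes are
the package's validation conditions; production analyses should raise
consensus resamples to the literature default of 1000.

## Known limitations

* Two-group differential expression only; no general design matrices,
  paired designs or continuous covariate adjustment.
* Deconvolution is relative (fractions of the modelled cell types), not
  absolute abundance, and inherits the reference matrix's biases.
* The maximally selected cutpoint's naive p-value is anti-conservative;
  use the permutation p for inference on the split itself.
* No proportional-hazards diagnostics, time-dependent covariates or
  competing risks.
* The selected number of phenotypes feeds a two-group contrast; k > 2
  structures are reported but not modelled further.
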