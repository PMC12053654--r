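---
title: "Discovering obesity-predisposition signatures with adiposig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering obesity-predisposition signatures with adiposig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiposig)
```

## Overview

`adiposig` implements a marker-discovery workflow for predisposition to
diet-induced obesity: stratify a phenotyped cohort into sensitivity
groups, select discriminant genes per expression dataset by PLS-DA/VIP,
refine the candidate set by intersection and differential-expression
q-values, and integrate multiple heterogeneous studies (mouse and human,
microarray and RNA-seq) into a single predictive model with MINT
(multi-group) PLS-DA. This vignette documents the models, the defaults
and why they were chosen, the numerical conventions, and what the
synthetic data generator does and does not emulate.

## Phenotype stratification

Animals are described by six end-of-challenge variables: body weight,
fat mass and adiposity (fat as % of body weight) at T18, plus the
percent change of each relative to its T0 value
(`delta_x_pct = 100 (x18 − x0)/x0`; the reference point is T0 — the
natural definition when asking how much an animal *changed* under the
challenge). Because the variables mix grams and percent, they are
z-scored before clustering; unstandardized Ward would be dominated by
whichever variable has the largest numeric range. Clustering uses
Euclidean distance with Ward.D2 linkage and the tree is cut at `k = 3`.
Clusters are labelled R/I/P by ascending mean percent body-weight gain;
ties break by mean percent fat gain, then cluster index, so the
labelling is deterministic and invariant to row order.

Group statistics are the classical one-way ANOVA F (equal-variance
`oneway.test`), Cohen's *d* with the pooled standard deviation
(`n1 + n2 − 2` denominator — the standard definition of Cohen's *s*; a
plain per-group SD is not symmetric, and pooling is what makes
`d(a, b) = −d(b, a)` hold), and the trapezoidal area under
glucose-tolerance curves in mg/dL·min.

## Expression preprocessing

Microarray data enter as log2 intensities and are used as-is. RNA-seq
counts are processed in the order *filter → normalize → transform*:

* genes with mean CPM below 10 across all samples are rejected as
  low-expressed (the boundary keeps a gene exactly at 10; the mean is
  taken across all samples rather than per group, the simpler reading
  when groups are unbalanced);
* TMM normalization factors are computed with `edgeR` (reference library
  by the upper-quartile rule, M-values trimmed at 30% and
  average-intensities at 5%, inverse-variance precision weights) and
  rescaled to geometric mean 1;
* the analysis matrix is
  `log2((count + prior)/(libsize·f + 2·prior) · 1e6)` with
  `prior = 0.5`, a small stabilizer that keeps zero counts finite while
  converging to plain log2-CPM for large counts.

Because of the precision weights, TMM factors are *exactly*
scale-invariant only for libraries that differ by a pure scale factor;
on noisy counts the invariance holds to a fraction of a percent, which
the tests check explicitly.

## Differential screening

Each gene is tested by the classical one-way ANOVA F on the log-scale
matrix (vectorized over genes, cross-checked in the tests against
`oneway.test` gene by gene). Constant genes are flagged and assigned
`p = 1` rather than an error, since all-flat probes are expected in
filtered panels. Benjamini–Hochberg q-values come from
`p.adjust(method = "BH")`, and selection uses the inclusive rule
`q ≤ 0.05` (configurable to strict). Moderated statistics (empirical
Bayes variance shrinkage, quasi-likelihood dispersion tests) are
deliberately out of scope: the declared model is the ordinary ANOVA F on
linearized data, which is also what the downstream q-value exclusion
rule consumes.

## PLS-DA, VIP and validation

`fit_plsda()` is NIPALS PLS2 on the dummy-coded class matrix: columns of
X and of the dummy response are centered and (by default) scaled to unit
variance — the common default for this model family, so that highly
expressed genes do not dominate the weights. Per component the unit-norm
weight vector `w_h` maximizes covariance with the response scores, and
both X and Y are deflated by the regression on the score `t_h = X w_h`.
The first weight vector solves the eigenproblem of `X'YY'X`, which the
tests verify by brute-force eigendecomposition; scores are pairwise
orthogonal to 1e-8.

VIP follows the standard definition
`VIP_j = sqrt(p · Σ_h SS_h w²_jh / Σ_h SS_h)` with `SS_h` the Y-variance
explained by component *h*, so `mean(VIP²) = 1` identically and, with a
single component, `VIP = sqrt(p)·|w|`. Selection keeps `VIP ≥ 1.5`
(inclusive; a strict `>` is available since both conventions appear in
practice). When several probes map to one symbol,
`collapse_probes_by_vip()` keeps the probe with the largest |VIP|.

Prediction supports `max` distance (argmax of predicted dummy scores;
ties break to the lowest class index, deterministically) and nearest
centroid in score space. Cross-validation is stratified k-fold with
round-robin assignment inside each class, processed in first-occurrence
order so fold draws are invariant to class relabelling.

The permutation test permutes class labels B times (default 500, the
conventional choice for this workflow) and recomputes the cross-validated
error with the fold scheme held fixed; the empirical p-value is
`(1 + #{null ≤ true})/(B + 1)`, bounded below by `1/(B+1)`. The error
estimator is stratified 5-fold CV, switching to leave-one-out below 15
samples where 5-fold folds become degenerate. Ties between null and true
errors count against significance, making the p-value conservative on
discrete error scales.

## Sparse and multi-study models

Sparsity constrains each component's weight vector to exactly `keepX`
nonzero entries by soft-thresholding at the magnitude of the
(keepX+1)-th largest weight inside the NIPALS loop — the standard lasso
surrogate of sparse PLS. Exact ties at the threshold retain a
sign-preserving epsilon so the cardinality contract holds exactly;
`keepX = p` reproduces the dense fit to machine precision.

MINT fits center and unit-scale *every study with its own statistics*,
estimate global weights on the concatenated standardized data, and
deflate per study with study-specific partial scores and loadings. Two
consequences are contractual: a single-study MINT fit equals an ordinary
PLS-DA fit exactly, and per-study additive offsets (batch shifts) leave
loadings, error rates and AUC unchanged. At prediction time a new study
is standardized with its **own** mean and SD — not the training
statistics — which is what makes cross-platform transfer possible and
mirrors the per-study scaling used at fit time; deflation of the new
study uses its own partial loadings, mirroring training.

Leave-one-study-out cross-validation refits on the remaining studies and
predicts the held-out one, pooling predictions into overall, per-class
and balanced error rates per component (BER = unweighted mean of
per-class error rates; the integration presets use mildly unbalanced
classes, 18 lean vs 22 obese per study, precisely so BER and overall
error differ and both are exercised). ROC curves sweep the predicted
dummy score for the positive class on component 1; the AUC equals the
tie-corrected Mann–Whitney estimate.

`tune_keepx()` evaluates a candidate grid by LOGOCV BER; the *best*
value minimizes the mean BER and the *chosen* value is the smallest
candidate whose per-study BERs are not significantly worse than the best
(one-sided paired t-test across held-out studies, α = 0.05; identical
BER vectors are treated as comparable, so complete ties resolve to the
sparsest model). The default grid
`{5, 10, 20, 35, 50, 75, 100, panel size}` spans sparse to dense on the
panel sizes this workflow produces.

## The signature workflow

`discover_signature()` chains the stages: per-dataset VIP lists →
three-way intersection → q-value exclusion (a gene is dropped only if
`q > 0.05` in *every* dataset — significance anywhere rescues it) →
alignment across the integration studies → MINT ranking. Gene ids are
canonicalized to uppercase symbols before any set operation, so mouse
"Sfrp4" meets human "SFRP4"; a user-supplied ortholog table can override
the case-insensitive default. The stage sets are nested by construction
(`tuned ⊆ aligned ⊆ q_filtered ⊆ intersection ⊆ each VIP list`) and
`signature_report()` validates that invariant, naming the offending
stage on violation. The loading cutoff used for display tables (e.g.
`|loading| > 0.12`) is a presentation parameter only and never feeds
selection logic.

## The synthetic data generator

The generator emulates the study design the workflow targets:

* a phenotyped cohort of 27 animals in three latent sensitivity classes
  of sizes 7/9/11, with class-specific percent gains in weight and fat
  (defaults: 8/25/45% weight gain, within-class SD 5%) — separable blobs
  that Ward.D2 should recover;
* two-class (lean/obese) expression studies on either platform:
  microarray values are gene baseline + per-study per-gene Gaussian
  batch shift + planted class effect + Gaussian noise, with planted
  effects expressed as *standardized* mean shifts (in units of the
  residual SD); RNA-seq counts are negative-binomial
  (variance `μ + φμ²`, the standard count-model parameterization;
  `φ = 0` gives the Poisson limit) with per-sample library sizes and
  planted log2 fold-changes;
* a seven-study integration preset (three mouse-like: two microarray,
  one RNA-seq; four human-like: three microarray, one RNA-seq; 40
  samples each, 280 total) with per-study 5% gene-panel dropout so the
  shared panel is a strict subset of the universe, and human/mouse id
  casing differences so alignment is exercised. Per-study sample sizes
  of real compendia vary widely; 40 per study is this package's choice
  of a desk-scale size that keeps every study informative.

Planted effects have study-consistent signs, and each study records
which planted genes survived its panel dropout, so recovery can always
be scored against ground truth. Batch effects are additive per-study
per-gene shifts with no gene×class×study interaction — exactly the
nuisance structure the per-study centering of MINT absorbs; generators
do not model probe chemistry, covariates (sex, age), longitudinal
trajectories, or study-specific effect heterogeneity. Passing tests on
these data therefore demonstrate correctness of the machinery and
recovery under idealized batch structure, not robustness to confounding
of the kind real public datasets carry.

## Numerical conventions

* NIPALS converges on the weight vector to 1e-14 (max 1000 iterations);
  degenerate zero-weight components raise an error.
* PCA fixes each component's sign so the largest-|loading| entry is
  positive; scores/loadings are otherwise the direct SVD.
* Confidence ellipses use the Gaussian mean/covariance scaled by
  `sqrt(qchisq(level, 2))` (≈ 2.4477 at 95%).
* ANOVA with zero within-group variance and equal means is an explicit
  error (no finite F exists); constant genes in the matrix-level screen
  are flagged with `p = 1` instead, as documented above.
* All generators take integer seeds and restore the caller's RNG state;
  identical configuration and seed give byte-identical output.

## Test and benchmark scale

The test suite and `scripts/acceptance.R` run the workflow at sizes
chosen to finish in about a minute while keeping every stage
informative: 2,000-gene single studies with 100 planted genes at
standardized effect 1.5 and 20 samples per class for VIP recovery;
the 280-sample seven-study preset for integration; 100 seeded null
datasets (24 samples × 50 genes, 49 permutations each) for permutation
calibration; and a three-dataset discovery design (60/60/30 samples,
500 genes, 40 planted) for the end-to-end workflow.

## Known limitations

* The VIP ≥ 1.5 rule is a fixed-threshold heuristic. Because VIPs are
  normalized to `mean(VIP²) = 1`, the fraction of null genes exceeding
  any fixed threshold depends on sample size and on how much response
  variance the true signal explains; at desk-scale n (tens of samples
  per class) a substantial minority of pure-noise genes passes 1.5, as
  the acceptance script's recovery numbers show. The workflow controls
  false positives *downstream* — a noise gene must pass the threshold
  independently in all three datasets and evade the q-value exclusion —
  and the end-to-end tests confirm the final set is nearly free of
  false discoveries. Single-list VIP selections should be treated as
  liberal screens, not final signatures.
* The ordinary ANOVA screen ignores variance moderation; at very small
  group sizes its q-values are noisier than shrinkage-based
  alternatives.
* MINT assumes the shared panel is measured (after alignment) in every
  study and that batch effects are additive at the study level;
  study-specific effect *directions* would violate the planted-signature
  assumption and are not modelled.
* The permutation test reuses one fold scheme across permutations;
  p-values are calibrated (the tests check uniformity under the null)
  but discrete, bounded below by `1/(B+1)`.
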