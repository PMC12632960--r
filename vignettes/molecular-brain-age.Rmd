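---
title: "Molecular-enriched brain-age modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-enriched brain-age modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molbrainage)
library(tibble)
```

## The problem

Brain-age models regress chronological age on MRI-derived features; the
signed residual — the brain-age gap, predicted minus true age — is a widely
used summary of apparent brain aging. Structural morphometry dominates this
literature. This package implements an alternative feature family:
*molecular-enriched functional connectivity*, in which resting-state BOLD
fluctuations are projected onto the spatial density patterns of monoamine
transporter systems (DAT, NET, SERT), yielding connectivity maps weighted by
a neurotransmitter system's anatomy. The package covers the full analysis
chain — dual regression, parcellation into feature blocks, multi-site
harmonization, and nested cross-validated support-vector regression — and
ships a synthetic-data module so that every stage can be validated against
known ground truth without any imaging downloads.

## The two-stage dual regression

Let $Y \in \mathbb{R}^{T \times V}$ be a subject's BOLD matrix and
$X_1 \in \mathbb{R}^{V \times K}$ the matrix of $K$ transporter-density
templates, each min-max scaled to $[0, 1]$.

* **Stage 1 (spatial GLM)** $Y^\top$-wise: for each time frame, the voxel
  vector is regressed jointly on all $K$ templates, giving a weight time
  series $\hat\beta_1 \in \mathbb{R}^{T \times K}$: how strongly each
  molecular distribution modulates the ongoing signal.
* **Stage 2 (temporal GLM)**: each voxel's time series is regressed jointly
  on the $K$ columns of $\hat\beta_1$, giving enriched connectivity maps
  $\hat\beta_2 \in \mathbb{R}^{V \times K}$.

Stage 1 runs on the intersection of each template's positive support with
the gray-matter mask; stage 2 runs on the gray-matter mask alone.

Design normalization is a genuinely open choice: we demean the response in
each regression and standardize every design column (zero mean, unit
variance) within the relevant mask. This makes $\hat\beta_2$ read as *BOLD
change per 1 SD of the weight time series*, comparable across subjects, and
makes the maps invariant to affine rescaling of the raw templates. Both
stages solve the joint multivariate least-squares problem by QR; fitting all
targets in one design (rather than one at a time) is what motivates the
collinearity guard: a rank-deficient design is an error naming the collinear
targets, and a condition number above $10^6$ triggers a warning. The joint
fit uses a single stage-1 voxel set — the intersection across all targets —
because one design needs one row set; per-target support is retained in the
mask object.

## Parcellation and feature blocks

Enriched maps are reduced to regional means over a composite atlas of 247
ROIs: 200 cortical parcels grouped into the seven canonical resting-state
networks, 15 subcortical regions, and 32 cerebellar regions. ROI means use
in-mask voxels only; mismatched grids are an error, never an implicit
resample. Six feature-block configurations are assembled: the three
single-transporter blocks (247 features each), their concatenation MEF
($3 \times 247 = 741$), a structural block SMF (649 features: 85
subcortical/global volumes, $2 \times 31$ cortical regions $\times$ 8
surface metrics, 68 white-matter volumes), and the multimodal union MMF
($741 + 649 = 1390$).

Image-quality screening uses the inner Tukey fences: a value is flagged when
it falls below $Q_1 - 1.5\,\mathrm{IQR}$ or above $Q_3 + 1.5\,\mathrm{IQR}$.
The quantile estimator is not fixed by the rule itself; we use type-7
(linear interpolation) quantiles, the R default, and the test oracle uses
the same rule. A zero IQR yields no flags.

## Harmonization

Multi-site feature tables carry per-site location and scale effects. The
ComBat model per feature $g$ and batch $i$ is

$$x_{jg} = \alpha_g + \mathbf{x}_j^\top \beta_g + \gamma_{ig} +
\delta_{ig}\,\varepsilon_{jg},$$

with age (linear, in years) and sex (0/1) preserved as covariates. Two
strategies are exposed:

* **CBI** — per-feature location/scale adjustment without empirical-Bayes
  pooling: $\gamma$ and $\delta$ are the batch mean and SD of the
  standardized data.
* **CBE** — parametric empirical-Bayes pooling (normal prior on locations,
  inverse-gamma on scales, method-of-moments hyperparameters, the standard
  iterative conditional estimates), fitted *separately within homogeneous
  feature subgroups*: transporter $\times$ parcel set (seven networks,
  subcortical, cerebellar — 27 functional subgroups) and, for structural
  features, source stats-file $\times$ measure nature (18 subgroups).
  Borrowing of strength therefore happens only among features of the same
  type; the corrected subgroups are recombined in the original column order.

Numerical conventions follow the reference implementations (sva,
neuroCombat) exactly — pooled residual variance with denominator $n$,
per-batch variances with $n_i - 1$, batch intercepts constrained by a
batch-size-weighted sum to zero, EB iteration stopped when the maximum
relative parameter change falls below $10^{-4}$ (cap 100 iterations). The
test suite verifies agreement with `sva::ComBat` to $10^{-14}$ and with an
independently coded iterative oracle to $10^{-6}$. One consequence of the
mixed variance denominators is worth knowing: refitting ComBat on its own
output recovers zero location effects exactly, but scale effects of
$n/(n - B)$ rather than exactly 1; this is a property of the reference
model, not an implementation artifact. A single-batch table adjusts to the
identity. Harmonization is fitted on the full table before cross-validation,
matching the usual workflow in this literature; fitting inside folds is a
possible alternative we deliberately did not default to.

## Brain-age prediction

The learner is $\varepsilon$-SVR with an RBF kernel (libsvm via e1071).
The protocol:

* **Outer loop**: 10-fold CV repeated 10 times (100 fitted models),
  folds stratified by age — ages are cut into quantile bins (as many bins as
  folds), shuffled within bins, and dealt round-robin, so every fold spans
  the age range. Fold assignment is regenerated per repeat from a derived
  seed.
* **Scaling**: median/IQR robust scaling fitted on the outer-training rows
  only (type-7 quantiles; a zero IQR gets scale 1).
* **Inner loop**: 5-fold grid search on the outer-training portion,
  selecting $(C, \gamma, \varepsilon)$ by inner MAE. Published protocols of
  this kind rarely state grid values or the inner scoring metric; our
  defaults are
  $C \in \{0.1, 1, 10, 100\}$, $\gamma \in \{0.1, 1, 10\}/d$ with $d$ the
  feature count, $\varepsilon \in \{0.1, 1, 2\}$ years, inner MAE as the
  criterion, and ties broken toward the smallest $C$, then $\gamma$, then
  $\varepsilon$, so reruns are reproducible.
* **Metrics**, per test fold: MAE, RMSE, Pearson $r$, prediction
  $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$, and the age-bias Spearman
  $\rho$ between the prediction error $\Delta = \hat y - y$ and age.
  Summaries are the mean over all folds and repeats with the SD computed
  across per-repeat means only. A correlation of a constant vector is
  reported as `NA`, never silently 0. No post-hoc bias correction is applied
  to the predictions; $\Delta$ is reported raw.

## What the synthetic data emulates

The generators define the study conditions:

* **Templates**: sums of Gaussian blobs at random centers, min-max scaled,
  resampled until every pairwise voxel correlation is $\le 0.5$ — the
  simplest construction that respects the low-collinearity requirement of a
  joint fit.
* **BOLD runs**: $Y = \beta_1 Z^\top + \varepsilon$ with $Z$ the template
  matrix standardized within the stage-1 mask (exactly the standardization
  the dual regression applies), so the noiseless recovery chain is an
  algebraic identity; planted weight series are smooth AR(1) processes.
* **Cohorts**: ages uniform on 18–90 years (broad support is what the
  stratification and bias metrics need; the real cohorts in this literature
  are roughly uniform over adulthood), sex Bernoulli(0.5), site effects
  following exactly the ComBat generative model (default: location shifts
  of $\pm 1$ residual-SD units and scale factors 1–1.5 across sites), a
  default linear age slope of 0.5 feature units/year. Feature scales are
  arbitrary, since the source analyses publish no distributional summaries
  of their features; this is documented rather than hidden.
* **IQM tables**: background values are truncated normals at $\pm 2$ SD —
  strictly inside the Tukey fences — so the planted 6.5-SD outliers are
  recovered exactly and exclusively, making the QC test sharp.

What the synthetic data does *not* emulate: hemodynamics, motion,
physiological noise, non-linear aging, site-by-age interactions, and
realistic feature covariance. Passing tests demonstrate correctness of the
algorithms and recoverability of planted effects, not real-data performance;
the headline accuracies of the motivating literature depend on real cohorts
of thousands of subjects and are out of scope here.

## Problem sizes used in tests

Unit tests run on $12^3$-voxel grids, $T \le 200$, cohorts of 60–1,000
subjects, and reduced CV protocols (3 folds, small grids); the end-to-end
checks use a 200-subject cohort with the full default protocol, chosen as
the smallest sizes at which the statistical properties under test (recovery
bounds, harmonization benefit, protocol counts) are stable.

## A worked example

```{r example, eval = FALSE}
meta <- tibble(name = sprintf("f%02d", 1:20), block = "DAT", group = "all")
coh <- make_cohort(sim_config(n_subjects = 200, beta_age = 0.5,
                              site_shift = c(-3, 3), site_scale = c(1, 2),
                              seed = 1), meta)
adj <- harmonize(coh$table, "cbi")
pred <- nested_cv_svr(adj, cv_config(n_repeats = 2, seed = 1))
compute_metrics(pred)
autoplot(brain_age_delta(pred))
```

## Known limitations

* Only parametric EB priors are implemented (no non-parametric mode).
* No resampling between grids: atlas and maps must share a voxel grid.
* Age enters the harmonization design linearly; non-linear age trends in
  real data would leak into the batch estimates.
* The SVR grid is small by design; very high-dimensional blocks (MMF) may
  prefer a wider $\gamma$ range.
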