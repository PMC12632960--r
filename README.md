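# molbrainage

Molecular-enriched brain-age modeling in R: from resting-state BOLD and
neurotransmitter-transporter density templates to harmonized feature tables
and cross-validated brain-age predictions — with a synthetic-data module
that makes the entire chain testable against known ground truth.

## Who this is for

Neuroimaging researchers who want to (a) compute transporter-enriched
functional-connectivity features by dual regression, (b) harmonize
multi-site feature tables with ComBat — including a subgroup-wise
empirical-Bayes variant that pools information only among features of the
same type — and (c) evaluate brain-age models under a leakage-free repeated
nested-CV protocol with bias metrics.

## The model in brief

**Dual regression (REACT).** With BOLD matrix `Y (T x V)` and template
matrix `X1 (V x K)` (densities of the DAT, NET, SERT transporters, min-max
scaled to [0, 1]):

- Stage 1 (spatial GLM): `Y' = X1 b1 + e` per time frame, giving a weight
  time series `b1 (T x K)`;
- Stage 2 (temporal GLM): `Y = b1 b2' + e` per voxel, giving enriched
  connectivity maps `b2 (V x K)`.

Design columns are standardized within the analysis mask and the response is
demeaned, so maps read as BOLD change per 1 SD of the weight time series.

**Features.** Maps are parcellated into 247 ROI means (200 cortical / 15
subcortical / 32 cerebellar) and assembled into six blocks: DAT, NET, SERT
(247 each), MEF (741), SMF (649 structural features), MMF (1,390).

**Harmonization.** Per feature `g`, batch `i`:
`x = alpha_g + X beta_g + gamma_ig + delta_ig * eps`, preserving age and
sex. Strategy `cbi` adjusts per feature without empirical Bayes; `cbe`
applies parametric EB shrinkage separately within homogeneous feature
subgroups (transporter x parcel set; stats-file x measure nature).

**Brain age.** RBF-kernel SVR under 10x10-fold age-stratified CV with an
inner 5-fold grid search over `(C, gamma, epsilon)`; metrics per test fold:
MAE, RMSE, Pearson r, prediction R², and the age-bias Spearman rho between
`predicted - true` age and age. The per-subject brain-age gap is
`predicted - chronological` age.

## Worked example

```r
library(molbrainage)
library(tibble)

meta <- tibble(name = sprintf("f%02d", 1:20), block = "DAT", group = "all")
coh  <- make_cohort(sim_config(n_subjects = 200, beta_age = 0.5,
                               site_shift = c(-3, 3), site_scale = c(1, 2),
                               noise_sd = 1, seed = 1), meta)
adj  <- harmonize(coh$table, "cbi")
pred <- nested_cv_svr(adj, cv_config(n_repeats = 2, seed = 1))
compute_metrics(pred)
#> <metrics_report> mean over folds/repeats (SD across repeats):
#>   mae      1.115 (0.001)
#>   rmse     1.302 (0.010)
#>   r        0.998 (0.000)
#>   r2       0.996 (0.000)
#>   rho     -0.074 (0.007)
```

The cohort plants a linear age effect of 0.5 units/year plus two-site batch
effects; after ComBat the SVR recovers age to about 1.1 years MAE with R²
0.995, and the age-bias rho near zero says the residual error is not
age-dependent. On the same cohort *without* harmonization the pooled MAE
roughly quadruples — the multi-site shift masquerades as signal. A noiseless
dual-regression chain recovers the planted weight time series and maps to
machine precision (`run_react` on `make_bold_run(..., noise_sd = 0)`).

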