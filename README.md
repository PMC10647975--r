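# hepamap

Voxelwise liver-function quantification from multiparametric MRI, built
around a non-contrast route: Bayesian fitting of the intravoxel
incoherent motion (IVIM) diffusion model, validated side by side with
the contrast-based readouts (dual-flip-angle T1 mapping with percent T1
reduction after gadoxetate, and hepatic extraction fraction from
dynamic contrast-enhanced MRI by truncated-SVD deconvolution).

The package is aimed at quantitative-MRI researchers who want a tested,
fully seeded implementation of this analysis chain, driven by a digital
liver phantom with known ground truth in place of (undeposited) scan
data.

## The models in brief

**IVIM.** Per voxel, the diffusion signal over b-values decays
biexponentially,

    S(b)/S0 = F_p exp(-b D_fast) + (1 - F_p) exp(-b D_slow) + noise,

separating capillary pseudo-diffusion (`D_fast`, perfusion fraction
`F_p`) from tissue water diffusion (`D_slow`). Two fitters are
provided: the classic segmented least-squares estimator and an
independent per-voxel Metropolis-within-Gibbs sampler on transformed
parameters with flat bounded priors, whose posterior-median maps shrink
the notoriously unstable `D_fast` estimates (about half the RMSE of
least squares at SNR 20 on the phantom).

**T1 / ΔT1%.** Spoiled gradient-echo volumes at 3° and 15° (TR 5.08 ms)
are fit voxelwise (DESPOT1 initialisation + Gauss–Newton), with the
flip angle scaled by a B1 map; liver function is summarised as
`ΔT1% = 100 (T1_pre - T1_post)/T1_pre`.

**HEF.** Tissue enhancement curves are deconvolved against the input
function with a trapezoid-quadrature causal operator and truncated SVD;
the extraction fraction is the late-retention plateau over the fitted
early peak of the impulse retention function.

**Statistics.** Repeatability CVs, exact/approximate Mann-Whitney U,
rank AUC with Youden cutoffs and stratified bootstrap CIs, voxelwise
Pearson correlation with Fisher-Z pooling, Dice registration QC.

## Worked example

Generate a synthetic two-cohort study (10 healthy volunteers, 12
patients with mild cirrhotic impairment, distributions at the package's
study defaults) and run the global-level analysis:

```r
library(hepamap)
cfg <- cohort_config(shape = c(16L, 16L, 3L), seed = 7L)
study <- make_cohort(cfg)
report <- run_study(study, pipeline_config(method = "lsq",
                                           bootstrap_n = 1000L, seed = 7L))
report$group_comparison[, c("parameter", "healthy_median",
                            "patient_median", "p_value", "significant")]
#>  parameter healthy_median patient_median  p_value significant
#>     d_slow           1.05          0.974 0.306762       FALSE
#>        f_p          29.11         20.373 0.000869        TRUE
#>     d_fast          85.51         43.517 0.003344        TRUE
report$roc[, c("parameter", "auc", "auc_lower", "auc_upper",
               "optimal_cutoff", "sensitivity", "specificity")]
#>  parameter   auc auc_lower auc_upper optimal_cutoff sensitivity specificity
#>     d_slow 0.633     0.375      0.85           1.04       0.750         0.6
#>        f_p 0.925     0.783      1.00          25.59       0.917         0.8
#>     d_fast 0.875     0.692      1.00          60.85       0.833         0.9
```

Reading the output: global medians are in 10⁻³ mm²/s (`d_slow`,
`d_fast`) and percent (`f_p`). The perfusion-linked parameters `F_p`
and `D_fast` separate the cohorts (Mann-Whitney p < 0.05) and carry the
high AUCs, while pure diffusion `D_slow` does not — the qualitative
signature of early liver-function impairment, where microvascular
perfusion degrades before tissue architecture. The `optimal_cutoff`
column is the Youden-index threshold in reporting units with its
sensitivity/specificity (disease = positive class).

Bayesian maps for one subject:

```r
fit <- fit_ivim_bayes(study$subjects$S11$dwi,
                      config = mcmc_config(n_iterations = 2000L,
                                           n_burn_in = 1000L, seed = 1L))
global_liver_summary(fit$maps)
```

## Analysis workflow

Numbered drivers under `analysis/` walk the full study end to end and
write tables under `results/`:

1. `01_simulate_cohort.R` — build and write the synthetic study (NIfTI
   layout + ground-truth table)
2. `02_fit_ivim.R` — Bayesian vs segmented-LSQ IVIM maps, error against
   truth
3. `03_t1_hef_maps.R` — T1 pre/post, ΔT1% and HEF maps for patients
4. `04_group_discrimination.R` — Mann-Whitney and ROC with bootstrap
5. `05_voxelwise_correlation.R` — Dice-gated single-slice correlations,
   Fisher-Z pooled
6. `06_repeatability.R` — digital-phantom CVs and scan-rescan
   within-subject CV

Each is a thin script over the package functions; run them in order
with `Rscript analysis/01_simulate_cohort.R` etc.

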