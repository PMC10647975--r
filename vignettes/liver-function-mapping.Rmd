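---
title: "Non-contrast liver function mapping: models, estimators and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-contrast liver function mapping: models, estimators and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepamap)
```

# The problem

Cirrhotic liver disease impairs function heterogeneously: some segments
keep working while others fibrose. Voxel-level maps of liver function
would let radiotherapy planning spare the functioning tissue, but the
standard functional readouts (gadoxetate uptake seen as T1 shortening, or
hepatic extraction fraction from dynamic contrast-enhanced MRI) need a
contrast agent. Intravoxel incoherent motion (IVIM) diffusion MRI offers
a non-contrast alternative: capillary blood flowing through the
microvasculature dephases like a very fast diffusion process, so the
diffusion signal over many b-values separates into a perfusion-linked
fast compartment and a tissue-water slow compartment.

`hepamap` implements the full analysis chain — IVIM fitting (Bayesian and
segmented least-squares), B1-corrected dual-flip-angle T1 mapping with
percent T1 reduction, extraction-fraction mapping by truncated-SVD
deconvolution, and the biomarker statistics layer — together with a
digital liver phantom that stands in for scan data, so that every
estimator can be validated against known ground truth.

# Models

## IVIM signal model

Per voxel, the diffusion-weighted signal at weighting $b$ (s/mm²) is

$$\frac{S(b)}{S_0} = F_p\,e^{-b\,D_{fast}} + (1 - F_p)\,e^{-b\,D_{slow}} + \xi,$$

with $D_{slow}$ the tissue water diffusion coefficient, $D_{fast}$ the
pseudo-diffusion coefficient of capillary blood, $F_p$ the perfusion
fraction, and $\xi$ Gaussian noise with variance $\sigma_y^2$. The
default acquisition scheme is the 13-b-value liver protocol
(b = 0, 10, …, 80, 100, 200, 400, 800 s/mm²) with 1/2/3 signal averages
per b as b grows.

Two fitters share this model:

* **Segmented least squares** (`fit_ivim_lsq`): a log-linear fit over
  b ≥ 200 s/mm² (where the fast compartment has decayed) gives $D_{slow}$
  and the tissue intercept; $F_p$ follows from the gap between that
  intercept and the measured b = 0 signal; $D_{fast}$ from a
  one-parameter nonlinear fit of the low-b residual. The 200 s/mm²
  threshold is the common liver convention and is configurable.
* **Bayesian voxelwise fit** (`fit_ivim_bayes`): independent per-voxel
  Metropolis-within-Gibbs on transformed parameters
  $(\log D_{slow},\ \log D_{fast} - \log D_{slow},\ \mathrm{logit}\,
  F_p/0.6,\ \log S_0)$, flat priors inside the physiologic box
  $D_{slow} \in [0.1, 3]\times10^{-3}$,
  $D_{fast} \in [3, 300]\times10^{-3}$ mm²/s, $F_p \in [0, 0.6]$, and a
  conjugate inverse-gamma step for $\sigma_y^2$ (near-Jeffreys
  hyperparameters $a_0 = 10^{-3}$, $b_0 = 10^{-8}$). The log-gap
  parameterisation enforces $D_{fast} > D_{slow}$ by construction. Chains
  are initialised at the segmented-LSQ estimate, proposal scales adapt
  toward 35% acceptance during burn-in, and the point map is the
  posterior median (robust to the skewed $D_{fast}$ posterior; the mean
  is available). Defaults are 10,000 iterations with 5,000 burn-in;
  the validation suite uses 2,500–4,000 iterations, which this phantom's
  posteriors do not distinguish from the default.

Why a sampler at all? At realistic SNR the $D_{fast}$ likelihood is very
flat, and per-voxel least squares scatters estimates across the whole
parameter range, producing the familiar salt-and-pepper pseudo-diffusion
maps. The posterior median under bounded priors shrinks those voxels
toward the supported range — at SNR 20 on this phantom the $D_{fast}$
RMSE falls to roughly half of the least-squares value, and the map SD
over a homogeneous region drops accordingly. That shrinkage is asserted,
not just asserted visually, in the test suite.

Voxels whose post-burn-in acceptance rate leaves [0.1, 0.6], or whose
posterior median sits against a support bound, are flagged in the
returned posterior summary rather than silently accepted.

## Preprocessing

The standard pipeline applies a slicewise 3×3 median filter before
fitting (edge handling by reflection with edge duplication — the filter
is compared against a brute-force sliding-window oracle in the tests).
In-plane resampling supports the acquisition-matrix workflow
(down-sample 340×218 → 128×128 for fitting, bilinear up-sampling of the
maps back to native resolution): down-sampling uses mean-preserving
area-overlap weights, up-sampling bilinear interpolation; both preserve
constant fields exactly and exclude non-finite voxels from local
averages. The synthetic phantom is generated at map scale, so resampling
is off by default in the pipeline and exercised by its own tests.

## Dual-flip-angle T1 and percent T1 reduction

The spoiled gradient-echo steady state at flip angle $\alpha$ is
$S = M_0 \sin\alpha_e (1 - E_1)/(1 - E_1\cos\alpha_e)$ with
$E_1 = e^{-TR/T_1}$ and $\alpha_e = \alpha \cdot B_1$; the B1 map is a
dimensionless flip-angle scaling. With two angles (3°/15°, TR 5.08 ms)
the DESPOT1 linearisation ($S/\sin\alpha_e$ against $S/\tan\alpha_e$,
slope $E_1$) gives the starting point and a damped Gauss–Newton
refinement on $(\log T_1, \log M_0)$ enforces the fit bounds
$T_1 \in [50, 5000]$ ms. Ignoring a true $B_1 = 0.8$ biases $T_1$ by
roughly −36% at 800 ms; supplying the map removes the bias to numerical
precision — the quantitative argument for acquiring the correction map.

Liver function is then summarised as the percent T1 reduction after
gadoxetate, $\Delta T_1\% = 100\,(T_{1,pre} - T_{1,post})/T_{1,pre}$:
functioning hepatocytes take up the agent and shorten T1, so higher
$\Delta T_1\%$ means better function.

## Hepatic extraction fraction by TSVD deconvolution

The tissue enhancement curve is modelled as the convolution of an input
function with an impulse retention function
$R(t) = (1 - HEF)\,e^{-t/\tau_{fast}} + HEF\,e^{-t/\tau_{slow}}$: a
vascular compartment that washes out quickly and a hepatocyte
compartment that retains extracted contrast. `build_convolution_matrix`
discretises the convolution with trapezoid quadrature on the (possibly
non-uniform, breath-hold-spaced) acquisition grid, giving a causal
lower-triangular operator; `tsvd_deconvolve` inverts it after zeroing
singular values below a fraction (default 0.15) of the largest.

HEF is read from the deconvolved $R$ as late plateau over early peak,
split at 300 s, with two numerical choices worth stating:

* the terminal sample is excluded from the late window — when the input
  function is zero at $t = 0$ its operator column vanishes, so a causal
  deconvolution carries no information about $R$ at the final time and
  the minimum-norm solution pins it to zero;
* the "peak" is the maximum of a *fitted* early window
  ($plateau + a\,e^{-t/\tau}$ by least squares, plateau fixed at the
  measured late mean), because truncation ringing and noise inflate a
  raw sample maximum and would bias HEF downward.

Regularisation strength is matched to noise: noise-free verification
uses truncation 0 (nothing to regularise), noisy runs the 0.15 default.
On this operator every cutoff between roughly 0.05 and 0.15 drops the
same singular values; the map-level error at SNR 20 stays within ±0.12
of truth across HEF ∈ [0.1, 0.9], and a heavier-noise test shows the
regularisation benefit directly.

## Statistics layer

The biomarker statistics mirror standard imaging-biomarker practice:
signed percent difference to a reference; intra-/inter-session and
within-subject coefficients of variation (sample SD throughout — group
sizes are small); exact Mann-Whitney U for ≤ 12 observations without
ties and the tie-corrected normal approximation otherwise; rank-based
AUC with ties counted half, direction auto-chosen so AUC ≥ 0.5, Youden
optimal cutoff with ties broken toward higher specificity; stratified
percentile bootstrap (default 1000 resamples, 95% level); voxelwise
Pearson correlation with Fisher-transform CIs and the conventional
strength bands (|r| 0.1–0.3 small, 0.3–0.5 medium, ≥ 0.5 large);
Fisher-Z pooling of per-subject correlations; Dice overlap as
registration QC. A Kolmogorov–Smirnov normality check is reported as a
diagnostic only and gates nothing. The significance level defaults to
0.05 and is configurable (stricter conventions such as 0.005 exist for
descriptive tables).

Every statistic is validated against an independent oracle: full
enumeration of the Mann-Whitney null for all splits of 8 values,
brute-force pairwise ordering for the AUC, long-hand covariance ratios
for Pearson, hand-computed Fisher/Dice values, and a 200-study coverage
simulation for the bootstrap CI.

# The digital liver phantom

The generator's role is to define study conditions with known truth, not
to imitate anatomy. Each subject is an ellipsoidal "liver" on a default
64×64×8 grid (desk-scale; the validation suite uses 16×16×3, the
analysis scripts 32×32×6) divided into four segment-like angular
regions.

* **Cohort distributions.** Subject-level parameters are drawn from
  per-cohort distributions parameterised by median and SD: log-normal
  for diffusivities, logit-normal for fractions, positively-truncated
  normal for T1 — families chosen so the support respects the parameter
  constraints while matching the configured medians exactly. The IVIM
  defaults reproduce the two-cohort global statistics of the study
  population (10 healthy volunteers, 12 CP-A patients; e.g. healthy
  $F_p$ 29.2% ± 5.1% vs patient 21.6% ± 4.0%). T1 and HEF locations are
  literature-informed choices (3T liver T1 ≈ 810 ms pre-contrast;
  post-gadoxetate T1 much shorter in well-functioning liver; HEF high in
  healthy liver, reduced in CP-A) since the study reports no tables for
  them.
* **Stratified cohort sampling.** Subject draws use randomized
  stratified quantiles (Latin-hypercube style): subject $i$ receives a
  uniform draw inside the $i$-th of $n$ equal probability strata, in
  scrambled order. Small cohorts therefore represent their configured
  distribution, and empirical cohort medians converge to the configured
  medians quickly (asserted at n = 200 within 2%).
* **Within-liver heterogeneity.** Region offsets are drawn on the
  log/logit scale with SD equal to `heterogeneity` (default 0.3) times
  the cohort's relative SD, smoothed, and renormalised so each subject's
  in-mask median equals the drawn subject value. Setting the cohort SD
  to zero therefore yields perfectly homogeneous livers — the degenerate
  case used by several tests. Real within-liver variance is unreported
  in the source population, so this knob is a documented free choice.
* **Signal simulation.** DWI: the biexponential forward model plus
  Gaussian noise per excitation (the model's stated error term), with
  per-b averaging simulated as the mean of independent noisy repeats;
  Rician noise (magnitude of complex Gaussian) is available since
  magnitude MR data is Rician. Default noise 0.05 of the b0 signal
  (SNR 20). SPGR: closed-form steady state under a smooth polynomial B1
  field in [0.8, 1.2]. DCE: curves built with the *same* discrete
  convolution operator the deconvolution inverts, with
  $\tau_{fast} = 60$ s (vascular washout) and $\tau_{slow} = 2\times10^4$ s
  (hepatocyte retention is effectively static over the 20-minute window —
  gadoxetate excretion runs on hours). Healthy volunteers carry IVIM
  data only, mirroring a protocol without contrast administration in
  volunteers.

What the phantom does **not** emulate: k-space/EPI artefacts, motion and
breathing, registration error (volumes are born co-registered, so Dice
QC is exercised by constructed degradations), tumours, and — important
for interpreting the correlation stage — physiologic coupling between
parameters. Truth fields are drawn independently per parameter, so
pooled voxelwise correlations hover near zero except where the fitters
themselves couple estimates; the correlation machinery is validated by
oracles, not by reproducing any particular in-vivo correlation table.
Passing tests therefore demonstrate estimator correctness under the
stated noise model, not robustness to everything real scans do.

# Pipeline and reproducibility

`run_study` ties the stages together: per-subject maps, global liver
summaries (reported in 10⁻³ mm²/s and %), Mann-Whitney group
comparison and ROC with bootstrap CI on the global means, then the
single-slice voxelwise correlation table (segment ROI on one slice, as
whole-volume correlation across differently-acquired maps is dominated
by registration error in practice; whole-volume is an explicit opt-in)
with Fisher-Z pooling, gated per subject by a Dice floor (default 0.8).
`run_pipeline` is the on-disk variant over a NIfTI study layout; derived
outputs land under `derived/` with the producing stage, config hash and
seed recorded in every NIfTI header and CSV comment line, and inputs are
never modified.

Everything stochastic flows from explicit integer seeds (R's default
RNG): phantoms, noise, the sampler, the bootstrap. Rerunning a study
with the same config and seed reproduces the report digest (an MD5 over
the canonical-JSON serialisation of the result tables) bit for bit.

Validation problem sizes are chosen to make each property measurable at
desk scale: 100 noise-free parameter draws spanning the healthy-to-
cirrhotic liver range ($D_{slow} \in [0.7, 1.3]\times10^{-3}$,
$D_{fast} \in [30, 140]\times10^{-3}$ mm²/s, $F_p \in [0.10, 0.45]$ —
inside the regime where segmented fitting is well-posed); 500 voxels at
the healthy medians for the SNR-20 shrinkage comparison; 50 replicate
cohorts (16×16×3 grids, segmented-LSQ route — the cohort-level claims
concern group discrimination, which both fitters support, while the
Bayesian-specific claims are tested directly) for the
group-discrimination reproduction; a 9-point HEF sweep; and 200
simulated studies for bootstrap coverage.

# Known limitations

* The Bayesian model is per-voxel with flat bounded priors; no spatial
  prior or full hierarchical shrinkage across voxels is implemented
  (matching the per-voxel independence of the reference approach), and
  the likelihood is Gaussian, not Rician — at very low SNR the magnitude
  floor biases all fitters.
* The HEF definition (late plateau over fitted early peak, 300 s split)
  is one member of a family of deconvolution readouts; alternative
  formulas from the deconvolution literature amount to a config change,
  and absolute HEF values should be compared only within a fixed
  definition.
* T1 fitting uses exactly the acquired flip angles with a scalar B1
  factor; slice-profile and incomplete-spoiling effects are outside the
  model, so agreement with any vendor's in-line maps is approximate by
  design.
* Cohort T1/HEF distribution locations are package choices informed by
  literature, not fitted to any deposited dataset.
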