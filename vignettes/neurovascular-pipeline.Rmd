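---
title: "Quantifying cerebrovascular function from multimodal MRI: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebrovascular function from multimodal MRI: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurovasc)
```

`neurovasc` implements a complete analysis chain for studies of
neurovascular coupling and cerebrovascular reactivity in ageing cohorts,
together with a fully synthetic cohort generator that stands in for scanner
data. This vignette explains the science behind each stage, the modelling
choices that were genuinely open, and what the synthetic data can and cannot
tell you about behaviour on real acquisitions.

## The measurement problem

Neuronal activity drives a local increase in cerebral blood flow (CBF)
through neurovascular coupling; CO~2~ accumulation during a breath hold
drives a global increase through direct relaxation of vascular smooth
muscle. Both responses weaken with age and in neurodegenerative disease,
and both can be quantified with MRI:

* **Visual activation** — a dual-echo pCASL sequence yields
  perfusion-weighted (control − label) and BOLD-weighted images
  simultaneously while a flickering checkerboard is shown in 54-s blocks.
  The quantities of interest are the percent CBF and BOLD changes in the
  most strongly activated part of the visual cortex
  (`delta_cbf`, `delta_bold`).
* **Breath holding** — a combined phase-contrast / susceptibility-oximetry
  sequence over the sagittal sinus gives per-dynamic blood flow and venous
  saturation through two 36-s holds; percent changes in flow, arteriovenous
  oxygen difference (A-V.O~2~ = S~a~O~2~ − S~v~O~2~) and Fick-derived CMRO~2~
  follow from a baseline-normalised GLM.
* **Resting physiology** — vessel flows from velocity maps sum to global
  CBF (normalised to brain weight at 1.05 g/ml); the inter-echo phase shift
  of venous blood gives S~v~O~2~; the Fick principle
  gCMRO~2~ = [Hgb]·gCBF·(S~a~O~2~ − S~v~O~2~) closes the loop
  (monomer [Hgb] convention in mmol/l, so no tetramer factor).
* **Metabolism of activation** — long-TE PRESS spectra at rest and during
  stimulation quantify lactate (1.33 ppm) and NAA (2.01 ppm); the percent
  lactate increase indexes the metabolic response.
* **Cohort statistics** — robust regressions of cognition scores on the
  cerebrovascular responses, Benjamini–Hochberg FDR control within each
  predictor family, forward stepwise health-covariate models, standardised
  longitudinal intelligence change scores, and an attrition ledger.

## The activation estimator

The per-subject chain is
`compute_cbf_series() → preprocess() → build_block_regressor() →
fit_voxelwise_glm() → select_activation_roi() → estimate_responses() →
qc_filter()`.

**Regressor.** The stimulation boxcar is convolved with a gamma-density HRF
of mean lag 6 s and SD 3 s (shape (6/3)² = 4, scale 3²/6 = 1.5 s). We
evaluate the convolution in closed form as differences of gamma CDFs and
sample it exactly at the acquisition times; a sufficiently long block
therefore plateaus at exactly 1, which is what makes the regression
coefficient read directly in percent.

**Preprocessing.** Spatial smoothing uses a separable Gaussian kernel
(default FWHM 5 mm, converted per axis by the voxel size) with reflective
boundaries, so a spatially constant image is a fixed point. Temporal
high-pass filtering is Gaussian-weighted running-line detrending with
sigma = cutoff/2 (default cutoff 90 s, a full period): a linear drift is
removed exactly, while a 20-s oscillation passes essentially untouched. The
90-s default partially attenuates the 108-s paradigm fundamental; we do not
"fix" this, because the same filter is applied to the regressor, so the
attenuation cancels in the coefficient — the standard resolution in fMRI
GLM practice.

**Percent scaling.** Each voxel's series is expressed as percent of its
rest-baseline level, defined as the value of the raw two-column fit
(`[intercept, regressor]`) at regressor = 0. An alternative is percent of
the grand temporal mean, but that reference includes the response itself:
for a true response δ it returns δ/(1 + δ·x̄/100) (x̄ ≈ 0.42 for this
paradigm), i.e. a ~25 % compression at typical visual responses and worse
for large ones. Percent *change from rest* is what a cohort mean like
"77 % CBF increase" means physiologically, and the baseline reference makes
the estimator exactly invert the generator in the noise-free limit.

**Inference.** Because the high-pass filter correlates the residuals, the
t statistic uses the filtered-noise covariance V = FFᵀ with Satterthwaite
effective degrees of freedom (tr(RV)²/tr(RVRV)) — the classic
fMRI GLM correction. t maps to z by tail-probability matching, capped at
z = 40 for numerically perfect fits. Monte-Carlo null simulations in the
test suite confirm the z > 3.1 exceedance sits at the normal tail
probability (≈ 10⁻³).

**ROI rule.** Voxels with z > 3.1 are clustered by 26-connectivity; within
the largest cluster (ties broken by smallest linear voxel index) the upper
decile of z survives, using the inclusive linear-interpolation percentile.
The selection is implemented as a top-*m* ranking that is provably
identical for distinct z values; ties — which occur only when z saturates
at its cap on noise-free data — fall back to ranking by effect size and
then voxel index, keeping the rule deterministic and preventing the ROI
from ballooning to every saturated voxel.

**Responses and QC.** `delta_bold` is the ROI mean of the BOLD
coefficients; `delta_cbf` refits the ROI-*median* perfusion series (median,
not mean, for robustness to partial-volume voxels at the ROI edge). A
subject is excluded when no cluster forms (`no_activation`), when the ROI
perfusion fit is not significant at p < 0.05 (`no_cbf_response`), or when
the CBF response exceeds 400 % (`anomalous`), mirroring standard cohort QC.

## The breath-hold estimator

Each series is expressed as percent change from the mean of the dynamics
fully inside the 50-s pre-hold baseline. The cohort-mean response curve,
normalised to its largest absolute excursion (sign preserved — the
A-V.O~2~ response is negative), serves as the regressor in a two-pass
design: pass one builds the regressor from all subjects, pass two fits each
subject by OLS on `[intercept, regressor]`. With the regressor peaking at
magnitude 1, the coefficient *is* the percent change at the response peak;
the signed peak change is reported per measure. All percent results are
invariant to the absolute flow scale, and the derived series satisfy the
pointwise Fick identity (1 + δCBF)(1 + δA-V.O~2~) − 1 = δCMRO~2~ to 10⁻¹⁰.

## Susceptibility oximetry

The inter-echo phase difference between sagittal-sinus blood and
surrounding tissue follows the infinite-cylinder model
Δφ = γ·B₀·ΔTE·(Δχ_do·Hct·(1 − S~v~O~2~)/6)·(3cos²θ − 1). The constants are
not universal across the literature, so Δχ_do (default 4π·0.27·10⁻⁶, SI),
Hct (0.42) and the vessel angle (0, i.e. a slice perpendicular to a vessel
parallel to B₀) are all exposed in `oximetry_calibration()`; generator and
estimator share the forward model, so round trips are exact by
construction. Aliased phases are corrected automatically: each vessel
voxel's inter-echo difference is shifted by the multiple of 2π that lands
it within π of the tissue median (a manual step in clinical practice). A
difference within π/100 of the ±π boundary is flagged ambiguous. The model
degenerates at the magic angle (3cos²θ = 1), which is an error, and a
Δφ = 0 contrast correctly reads S~v~O~2~ = 1.

## MRS quantification

Both metabolites are modelled as single Lorentzians (the lactate doublet is
not resolved at this linewidth) with centers bounded to ±0.1 ppm of the
standard shifts, fitted by Levenberg–Marquardt least squares. Absolute
concentrations need an external calibration scale; when a reference
metabolite with known concentration is supplied the quantification is
invariant to global spectral scaling, and percent changes are invariant
always. Zero spectra short-circuit to zero concentrations rather than
relying on the optimiser at a degenerate point.

## The synthetic cohort

`generate_cohort()` draws each subject's true physiology from configurable
population distributions and derives every raw input from it
deterministically via per-subject, per-modality child seeds
(`child_seed()`), so a single integer reproduces the entire cohort.
Defaults follow the cohort summary values this package is designed around
where those are published (visual-activation CBF response 77.1 ± 30.5 %,
breath-hold response 22.5 ± 7.4 %, lactate increment 0.060 ± 0.126 mmol/l
on a resting level of ≈ 0.723 mmol/l, 187-subject-scale attrition
patterns, a current-intelligence coupling of slope 0.112 with R² = 0.13);
the remaining fields (gCBF 50 ± 8 ml/100g/min, S~v~O~2~ 0.62 ± 0.04,
[Hgb] 9.3 ± 0.6 mmol/l, brain volume 1300 ± 110 ml, BOLD response
1.5 ± 0.6 %, NAA 10 ± 1.2 mmol/l, sagittal-sinus baseline flow 350 ml/min)
are values a physiologist would call typical for healthy men in their
mid-sixties, chosen once and not tuned.

Cognition scores are linear in the true activation response with the
configured slope; the noise SD is calibrated as
σ² = slope²·var(x)·(1 − R²)/R² so the expected sample R² matches the
configured one (an R² of 1 gives an exactly deterministic score).

Design choices worth knowing:

* The activation region is a full-depth column covering the central ~45 %
  of the in-plane field of view. Constant-along-z patterns are fixed points
  of reflective-boundary smoothing in z, so the region keeps a fully
  interior core and noise-free recovery is exact; region shape and size are
  arguments, since the true spatial extent of activation is not something
  the emulated study reports.
* The generator convolves the paradigm with the *same* HRF the estimator
  assumes, making noise-free recovery an identity; passing different
  `hrf_mean`/`hrf_sd` to the generator creates a controlled
  HRF-mismatch robustness scenario.
* The breath-hold response shape is a raised-cosine ramp over each hold
  with exponential recovery (τ = 15 s), normalised so its sampled maximum
  is exactly 1; the saturation series can be parameterised either through
  the CMRO~2~ trajectory or directly through the A-V.O~2~ trajectory.
* Default image matrices are reduced (32 × 32 × 8 for pCASL, single-slice
  2D maps for flow and oximetry) so that a 40-subject cohort simulates in
  well under a minute on one core; geometries scale up to acquisition size
  by configuration.
* Laminar vessels are rendered by pixel-center sampling of the parabolic
  profile; at the default 0.025-cm grid the discretised flow agrees with
  the closed form πR²v_max/2 to well under 3 %.

What the phantom does *not* emulate: realistic anatomy, motion (beyond a
QC pathway), arterial-transit-time effects, k-space/MR physics,
cardiac-cycle velocity variation, baseline drifts beyond what the filter
removes, and spectral artefacts (eddy currents, phase errors,
macromolecule baselines). Passing tests therefore demonstrate correctness
of the estimators under their stated models, not robustness to every
real-world confound.

## Numerical and degenerate-input policy

* Zero-variance voxels are flagged and report β = 0, z = 0; perfect fits
  report z at the cap (40).
* Empty ROIs are a *valid outcome* (`no_activation`), not an error; an
  empty ROI passed to `estimate_responses()` is an error.
* Exactly collinear data short-circuit `robust_fit()` to the exact line
  (IRLS weights are undefined at zero scale).
* Ties in stepwise selection resolve to the earliest candidate in declared
  order; equal-size largest clusters resolve to the smallest voxel index.
* `fdr_adjust()` refuses p values outside (0, 1]; the magic angle and
  degenerate baselines are errors, not NaNs.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
s <- generate_pcasl_series(
  acq_geometry(), block_paradigm(),
  truth = list(true_dcbf_visact = 77.1, true_dbold_visact = 1.5),
  noise_sd = 10, seed = 5)
res <- asl_activation(s)
tidy(res)
#> delta_bold ~ 1.56, delta_cbf ~ 77.2, qc_status "ok"
```

A cohort-scale run (`run_all(cohort_config(n_subjects = 40, seed = 1),
out_dir)`) writes the resolved configuration, per-subject results, the
truth-vs-estimate recovery report, the correlation and attrition tables,
and a checksummed manifest.

## Problem sizes used by the shipped checks

The test-suite and the reproduction script work at deliberately desk-scale
sizes: cohorts of 40 subjects on the reduced default geometry for the two
stochastic cohort recoveries, 200 replicate cohorts of n = 150 for the
coupling-slope recovery, 100 random maps for the ROI-rule equivalence,
10⁴ voxels for the GLM null calibration, and 10³ random vectors for the
FDR oracle. These sizes give Monte-Carlo error comfortably inside the
tolerances being checked while keeping a full run in minutes on a single
core.

## Known limitations

* Plain OLS (with filter-aware inference) is used voxelwise; no
  prewhitening of intrinsic physiological autocorrelation.
* The robust-slope p value relies on the normal approximation of the IRLS
  estimate; its finite-sample size is verified by simulation at n ≈ 100
  but will be less accurate for very small cohorts.
* Absolute CBF calibration (M0, labelling efficiency, T1 of blood) is out
  of scope: every downstream quantity is relative (%), matching the way
  the responses are used.
* The oximetry constants are configuration, not claims: reported S~v~O~2~
  is only as good as Δχ_do and Hct.
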