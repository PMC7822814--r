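---
title: "Methods: fluorine-19 saturation-recovery oximetry of the placenta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluorine-19 saturation-recovery oximetry of the placenta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorox)
```

## The measurement principle

Perfluoro-15-crown-5-ether (PFCE) nanoemulsion circulates with the blood
pool, contributes all of the fluorine-19 MR signal (there is no biological
¹⁹F background), and its longitudinal relaxation rate responds linearly to
dissolved oxygen:

$$R_1 = \frac{1}{T_1}, \qquad \mathrm{PO_2\,[mmHg]} = a\,R_1 - b,
\quad a = 470.81\ \mathrm{mmHg\,s},\ b = 200.14\ \mathrm{mmHg}.$$

The constants come from an in vitro calibration and are treated as fixed
inputs (`oxygen_calibration()`); the package never re-estimates them and
applies no temperature or field-strength correction. Sampling the ¹⁹F
signal at several repetition times under a saturation-recovery scheme gives

$$\mathrm{SNR}(TR) = S_0\left(1 - e^{-TR/T_1}\right),$$

a two-parameter curve per region of interest (ROI): the equilibrium signal
$S_0$ (proportional to local agent concentration) and $T_1$, which the
calibration converts into the oxygen partial pressure of the tissue's
blood pool. In the pregnant mouse the placenta is a favourable target
because roughly two thirds of its volume is maternal plasma, reached by a
simple i.v. injection.

## The processing chain

`run_pipeline()` sequences five stages; each is exposed on its own.

**1. Noise estimation** (`estimate_noise`). Magnitude MR images have Rician
noise. In a signal-free ROI the magnitude follows a Rayleigh distribution,
so the measured SD $\sigma_m$ relates to the underlying Gaussian channel
noise as $\sigma_g = \sigma_m/\sqrt{2 - \pi/2}$. The SD is taken from the
background ROI of the longest-TR image and reused for all TRs of a session
(identical receiver settings within a series); `noise_per_tr = TRUE`
estimates it per TR instead.

**2. SNR conversion** (`magnitude_to_snr`). Voxelwise
$\mathrm{SNR} = \sqrt{SI_m^2 - \sigma_g^2}\,/\,\sigma_g$, the
Gudbjartsson–Patz correction for Rician bias. Where $SI_m < \sigma_g$ the
radicand is negative; those voxels are below the noise floor and are
clamped to SNR 0 — a choice the TR₄ exclusion threshold makes immaterial
downstream.

**3. Interpolation** (`resample_between_grids`). SNR volumes are pulled
from the coarse ¹⁹F grid (64 × 84, 8 slices of 2 mm + 0.4 mm gap) up to the
anatomical ¹H grid (196 × 256, 20 slices of 1 mm + 0.2 mm gap) through
world coordinates; both stacks share centre and orientation by acquisition
prescription, and slice gaps are carried in the affine's slice-direction
spacing. The default interpolant is separable cubic convolution with the
Catmull–Rom kernel ($a = -0.5$, the "bicubic" of common image tools);
orders 0 and 1 are available. ROIs always stay on the anatomical grid —
quantitative maps travel up, only the background-noise ROI is transported
down (nearest neighbour) for noise estimation.

**4. Smoothing** (`smooth_snr`). In-plane 2-D Gaussian filtering with
SD = 3 anatomical pixels by default. The width follows the ImageJ
convention in which the blur parameter is the Gaussian SD; it is a config
knob (`smooth_sd`), as is a 3-D mode (`in_plane = FALSE`), off by default
because slices are thick (2 mm) and gapped relative to the 0.2 mm in-plane
resolution.

**5. Exclusion** (`build_validity_mask`). Voxels whose smoothed SNR on the
TR = 5 s image falls below 5 are excluded from all further analysis;
the comparison keeps SNR ≥ 5, reading the exclusion rule "SNR < 5"
literally. The order of stages 2–5 is fixed (conversion → interpolation →
smoothing → exclusion) and tested; where the original description leaves
smoothing-versus-masking order ambiguous, the numbered-list order (smooth,
then exclude) is followed.

**Fitting** (`satrec`). ROI-mean SNR per TR is fitted by
Levenberg–Marquardt least squares with box bounds $S_0 > 0$,
$T_1 \in [0.05, 30]$ s (far beyond physiology; present only to stop
pathological excursions), initialised at $S_0^{(0)} = \mathrm{SNR}(TR_4)$,
$T_1^{(0)} = 1.5$ s. Fits are ROI-mean based, not voxelwise: error
propagation from $T_1$ to PO₂ makes voxelwise PO₂ unusable at this SNR.
Weighting across TRs is uniform (ordinary least squares); an
inverse-variance `weights` knob exists. A failed fit returns a flagged
object, never an exception. PO₂ outside $[0, 760]$ mmHg is physically
impossible but retained with QC flags (`placenta_qc_flags`) rather than
censored, mirroring how such values arise from error propagation in vivo.

**Inference** (`fit_full_model`, `fit_posthoc_model`). Mothers are the
independent statistical unit; placentas are nested within mothers and each
placenta is measured under 30/60/100% inspired O₂. The full model per
outcome is

```
outcome ~ genotype * oxygen + (1 | mother) + (1 | placenta-in-mother)
```

fitted by REML, with type-III F tests using Satterthwaite denominator
degrees of freedom — chosen to emulate the repeated-measures mixed-model
output of mainstream statistics packages; exact df replication is not
promised because the original covariance structure is not fully stated,
and the random-intercept structure here (mother, plus placenta within
mother) is this package's explicit resolution of that gap, recorded in the
result object. Estimated marginal means carry 95% CIs. Each of the seven
outcomes (PO₂, T₁, SNR(TR₁..₄), S₀) is modelled independently with no
cross-outcome multiplicity correction. A significant interaction triggers
per-oxygen-level post-hoc genotype models with a mother random intercept;
where that intercept is unidentifiable (one placenta per mother, or zero
residual variance) the model falls back to the fixed-effects `lm`, whose
genotype F test equals the pooled two-sample t-test. Optional unpaired
t-tests are an auxiliary report column, not the primary inference.

## The synthetic phantom

`phantom_config()` / `generate_study()` emulate the study the analysis was
built for, so the whole chain is testable without scanner data:

* **Design.** WT: 3 mothers / 19 placentas; KO: 4 / 17; three
  within-subject oxygen conditions; TRs 318/719/1398/5000 ms. Placenta
  totals are distributed as evenly as possible across mothers (7/6/6 and
  5/4/4/4) — a per-mother range would not reproduce the study's exact
  totals.
* **Ground truth.** Per placenta × condition,
  PO₂ = condition baseline + KO offset + mother intercept + placenta
  intercept + condition-level jitter, then $T_1 = a/(\mathrm{PO_2} + b)$
  exactly. Defaults: baselines (100, 150, 250) mmHg at (30, 60, 100)% O₂;
  KO offset (−64, 0, 0) mmHg, the estimated 30% genotype gap; mother and
  placenta SDs 15 mmHg each and jitter SD 20 mmHg, free choices sized to
  the substantial between-animal and between-placenta heterogeneity the
  fitted curves show in vivo. Draws are floored just above $-b$ so the
  implied $T_1$ stays positive; configured group means at or below $-b$
  are rejected outright.
* **Signal.** Each placenta is a homogeneous axis-aligned ellipsoid placed
  on a fixed non-overlapping lattice inside the shared FOV, sized to 20–80
  ¹⁹F-grid voxels. Noiseless voxel signal is
  $S_0\,s_{scale}(1 - e^{-TR/T_1})$; `s0_range` defaults to (6, 12)
  equilibrium-SNR units, the scale the in vivo SNR values imply
  (SNR(TR₂) ≈ 2.5 at $T_1 \approx 1.66$ s gives $S_0 \approx 7$). Every
  voxel receives Rician noise — the magnitude of signal plus complex
  Gaussian noise of SD $\sigma_g$ — because the downstream correction
  presumes magnitude statistics. Background voxels carry zero signal; a
  signal-free box in a corner of the FOV is exported as its own label for
  noise estimation. Within-placenta PO₂ texture is not simulated (none is
  reported to emulate); each placenta is homogeneous per condition.
* **Determinism.** Everything derives from one integer seed;
  regenerating and rewriting a study is byte-identical.
* **Record-level mode.** `simulate_records()` skips the imaging chain and
  adds a 25 mmHg measurement-error term standing in for noise-plus-fitting,
  so mixed-model Monte-Carlo runs take milliseconds per replicate.
* **Compartments.** `compartment_model()` / `mix_compartments()` implement
  the three-pool signal (maternal 64.4%, fetal 23.7%, trophoblast 11.9%)
  for multiexponential experiments; `fit_multiexponential()` exposes
  bootstrap CI widths so the non-identifiability of six-parameter fits at
  four TRs is visible rather than hidden.

What passing synthetic tests do **not** show: the phantom has no motion,
no B₀/B₁ inhomogeneity, no chemical-shift or isoflurane artefacts, no
k-space simulation and no fetal physiology; real-data performance depends
on those. Conversely the phantom shares the real protocol's geometry, SNR
scale, noise family and nesting structure, so calibration of the
statistics and conditioning of the fit transfer.

## Numerical choices and known limitations

* **Problem sizes.** The package's own validation uses 5000-point
  calibration grids, 10⁵-voxel noise simulations, 200 fit-recovery curves,
  500 null and 200 effect replicates for the mixed model, and one full
  default-design imaging run — sizes at which Monte-Carlo error is well
  below every asserted tolerance while a complete validation pass stays in
  the minutes range.
* **Resampling edges.** Source indices are clamped at volume edges; target
  voxels whose centre falls more than half a voxel outside the source
  field of view are filled with 0. Cubic overshoot below zero is clamped
  to 0 after resampling (negative SNR has no meaning).
* **Low-SNR bias.** At the in vivo operating point the TR₁ image sits at
  voxel SNR ≈ 1.3–2.4, below the regime (SNR ≥ 3) where the
  Gudbjartsson–Patz estimator is nearly unbiased. The residual upward SNR
  bias at short TRs shortens fitted T₁ by a few percent, which the convex
  $T_1 \to \mathrm{PO_2}$ map turns into a mean PO₂ overshoot proportional
  to $\mathrm{PO_2} + b$ (roughly +10 mmHg at 100 mmHg, +20 at 250 mmHg at
  default noise). ROI smoothing does not remove it because the nonlinear
  correction is applied, per the fixed stage order, before smoothing. The
  end-to-end tests therefore bound mean PO₂ recovery error relative to
  $\mathrm{PO_2} + b$ (under 10%) rather than absolutely; monotonicity of
  the gas-challenge response and the sign and approximate size of the
  genotype gap are unaffected.
* **S₀ attenuation.** Interpolation and smoothing dilute ROI edges, so
  fitted S₀ underestimates the configured equilibrium signal by a
  TR-independent factor; T₁ and PO₂ are unaffected (the factor cancels in
  the curve shape). S₀ comparisons are therefore relative, never absolute.
* **Ill-conditioning at long T₁.** With a maximum TR of 5 s, curves with
  $T_1 \gtrsim 5$ s barely bend; fits converge but with inflated variance,
  and PO₂ near the $-b$ asymptote is extremely sensitive to $T_1$.
  Out-of-range values are flagged, not removed — downstream summaries
  decide.
* **Real data.** The loader accepts any NIfTI-converted series plus ROI
  label volumes and a design table (`study.yaml`); conversion from
  scanner raw formats and ¹H–¹⁹F registration are out of scope (the
  protocol relies on identical stack prescription). No assumption is made
  about the layout of any particular archive; an adapter script can map a
  download onto `load_series()`/`read_roi_set()` inputs.

## A worked example

```{r example, eval = FALSE}
cfg <- phantom_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "study_out", posthoc_all = TRUE)
print(res)
res$inference$full$po2_mmhg      # Tests of fixed effects for PO2
make_report(res, "study_out/report.pdf")
```
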