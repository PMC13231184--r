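---
title: "Methods: photoacoustic monitoring of implant-overlying skin vasculature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photoacoustic monitoring of implant-overlying skin vasculature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paskin)
```

## The problem and the measurement model

Skin stretched over a subcutaneous implant can become ischemic and break
down. Photoacoustic (PA) imaging reads optical absorption — dominated in
skin by hemoglobin — through ultrasound detection, so a co-registered US/PA
scan yields both the skin geometry (US) and its blood content (PA) on one
grid. `paskin` turns a biweekly series of such scans into three scalar
vascular biomarkers per visit, asks whether their temporal profile separates
subjects whose implants become exposed from those that stay healthy, whether
their decline *precedes* the decline of an ordinal 1–5 skin-health score,
and *where* in the field the hemoglobin loss happens.

The per-session model is deliberately simple and linear:

* US amplitude is treated as linear-scale echo intensity; water is anechoic,
  tissue hyperechoic. (Whether exported scanner data are log-compressed is
  unknowable from the data itself; the pipeline documents the assumption
  rather than guessing a decompression.)
* PA amplitude at wavelength λ in a voxel is proportional to
  fluence(λ) · [ε_Hb(λ) C_Hb + ε_HbO₂(λ) C_HbO₂]. Fluence is unknown per
  session, which motivates both the water normalization (global scale) and
  the use of *relative*, baseline-normalized biomarkers.

## Pipeline stages, parameters, defaults

**Resampling.** All volumes are interpolated trilinearly to 0.1 mm isotropic
voxels (`resample_isotropic()`, `target_mm = 0.1`), the working resolution of
every downstream constant (the 0.5 mm shell is 5 voxels; the vesselness
scale 4 px is 0.4 mm). Edge samples are clamped; the interpolation order is
a design choice — the source pipeline says only "interpolated".

**Segmentation.** Otsu's threshold separates water from tissue; per lateral
column, the first run of at least `min_run = 2` super-threshold voxels marks
the interface (a single-voxel run is more often a noise spike than skin).
The interface map is then *despiked*: a column is replaced by its 3×3
lateral median only when it deviates from it by more than 2 voxels. A plain
median filter would also shift border columns of smoothly curved (mounded)
interfaces by one voxel, breaking the exactness we require on noiseless
phantoms; despiking preserves smooth surfaces exactly while still removing
speckle spikes. The shell is the first `round(0.5 mm / 0.1 mm) = 5` tissue
voxels of each column — a Z-directed erosion, matching a layer defined
"along the Z axis"; an isotropic 3-D structuring element would bevel the
shell at mound flanks.

**Water normalization.** Each PA volume is divided by its mean over the
water mask. Every downstream biomarker is therefore invariant to global
rescaling of the raw data; the test suite asserts this end to end. The
phantom generator gives water a small constant PA amplitude (default 0.05)
precisely so this division is exercised rather than degenerate.

**Unmixing.** Six wavelengths (700–950 nm; 532 nm is excluded — it is the
vasculature wavelength, not an unmixing band), two chromophores. With two
unknowns the per-voxel non-negative least-squares solution is closed-form:
take the unconstrained 2×2 solution if it is feasible, otherwise the better
of the two single-chromophore fits clamped at zero. This is exact NNLS,
deterministic, and vectorizes over the whole volume. Concentrations are in
arbitrary units tied to the bundled extinction table (an approximate
digitization of the standard oxy/deoxyhemoglobin compilation, Prahl/OMLC,
500–1000 nm); no molar calibration is attempted, and no fluence-with-depth
correction is applied — which is also why the optional sO₂ map should be
read cautiously.

**Vessel enhancement.** The 532 nm water-normalized volume is projected
(skin-masked MIP), rescaled to [0, 1], and filtered with the Jerman 2-D
Hessian vesselness at a single scale of 4 px with regularization τ = 0.5
(the reference default; only the scale was fixed by the source pipeline).
Derivatives are Gaussian-derivative convolutions with reflective boundaries
and zero-sum-corrected kernels (so constant images give exactly zero
response). One behaviour worth knowing: the Jerman response *plateaus at 1*
for any structure whose sign-flipped principal eigenvalue exceeds
τ · frame-max / 2. Equal-amplitude blobs and tubes of the same width
therefore both saturate; blob suppression is only partial in 2-D, and our
tests probe it with compact blobs and probe scale tuning at τ = 1, where the
plateau recedes. Vessel orientation is the Frangi eigenvector of the
smaller-magnitude Hessian eigenvalue at the same scale (a configurable
choice — the source pipeline does not say which scale fed the direction
estimate), expressed as the angle from the image-vertical (Y) axis of the
en-face map. Pixels with |angle| < 0.5 rad are zeroed: implant-surface
ridges run vertically in these maps, while murine skin vessels are
predominantly horizontal. The band is config-exposed; (−0.5, 0.5) is the
study value.

**Biomarkers.** PA vasculature and total hemoglobin are 3-D means over
shell ∩ ROI (the 2-D ROI broadcast down Z); vascular density is the 2-D mean
of the suppressed vesselness map over the full ROI (the MIP is already
skin-restricted — whether the source restricted further is unknown; full ROI
is assumed). Baseline normalization divides by the week-0 value; missing
weeks stay missing (no imputation) and truncated series (death mid-study)
are processed at their observed length.

**Statistics.** The group-separation test is
`normalized ~ week * group + (1 | subject)` fitted by maximum likelihood in
`lme4`, with the interaction tested by a likelihood-ratio test against the
no-interaction model. The source describes "analysis of variance on the
fitted model"; `lme4` deliberately provides no denominator-df F-tests, and
the LRT is the standard equivalent in that framework — this is the package's
own choice, recorded here. Time is continuous; group is a two-level factor.
If the mixed fit errors, the test falls back to OLS with the same fixed
effects and says so in the result.

Cross-correlation lag: for integer shifts on the biweekly grid up to
±8 weeks, the Pearson correlation pairs biomarker(w) with score(w − lag);
negative lag ⇔ the biomarker leads. Ties break toward the smallest |lag|,
then toward the negative lag (conservative about claiming long leads). Lags
with fewer than 3 overlapping points, or with a constant series over the
overlap, are skipped; healthy subjects scoring 5 throughout have no defined
correlation anywhere and are excluded from the t-tests with a notice. (How
the source computed healthy-group correlations against all-constant score
series is not reconstructable — Pearson correlation is undefined there — so
we do not guess.) Per-subject lags are necessarily multiples of 2 weeks;
group means may be fractional.

**Spatial maps.** Weekly THb maps are flattened by MIP (consistent with the
vasculature path; a sum projection is available), normalized to unit ROI
mean — making consecutive-week differences blind to global scale and
sensitive only to spatial redistribution — smoothed with σ = 0.3 mm, and
differenced. Pixels with a drop below −0.15 (mean-normalized units) form the
reduction mask. Both σ and the threshold are package choices, config-exposed
and recorded in outputs: the source states neither. The week 0→2 pair is
excluded by default (early post-implantation skin movement).

## The synthetic world

The generator states one fixed world; its defaults are not tuned to tests.

* **Phantom** (`phantom_spec()`): anechoic water over a hyperechoic block
  whose surface is flat or raised by a Gaussian mound; a 0.5 mm shell;
  vessels as straight tubes with Gaussian cross-section (σ = radius/2 —
  matched to what a scale-tuned Hessian filter expects), lying inside the
  shell and following the surface; vertical ridge artifacts as
  depth-extended sheets; additive Gaussian noise per modality, clamped at
  zero. PA amplitudes follow the linear absorption model with the bundled
  spectra. No acoustic propagation, speckle texture, or depth-dependent
  fluence is simulated — so a green segmentation or unmixing test
  establishes correctness of the *algorithm under the stated model*, not
  robustness to speckle or spectral coloring of real tissue.
* **Cohort** (`cohort_spec()`): biweekly weeks 0–12; 11 healthy subjects
  flat up to 5% multiplicative noise; 5 exposed subjects declining
  geometrically from week 2 to 50% of baseline at week 12 (mirroring the
  reported decline of up to ~48%); skin scores stepping 5→4→3→2→1 one visit
  at a time, starting `lag_weeks = 4` after decline onset (inside the
  reported 2–4-week lead). Both the multiplier and the score first deviate
  from baseline one visit after their respective onsets, so `lag_weeks = 0`
  aligns their first detectable changes. Per-subject baselines are
  log-normal (σ = 0.1). Noise and contrast defaults are chosen for
  testability; the source system's noise figures are unpublished.

## Numerical choices and degenerate inputs

* Constant maps: `normalize01()` returns zeros with a warning; constant
  images give exactly zero vesselness (derivative kernels are corrected to
  zero sum, and a relative floor guards the frame-max rescale).
* Empty masks, missing wavelengths, rank-deficient spectra, inverted
  suppression bands, sub-voxel shell thickness, degenerate (length-1) axes:
  all are errors naming the offending object, never silent recovery.
* sO₂ is masked (NA) wherever THb is below 1% of its 99th percentile;
  masked voxels never enter means.
* Seeds: every generator takes an explicit seed and derives per-stream
  seeds below 2³¹; fixed seed ⇒ bit-identical output.

## What the acceptance suite establishes — and one red result

`scripts/acceptance.R` recomputes, from scratch: exact unmixing on noiseless
stacks (≤1e-6 relative error); shell Dice = 1 noiseless and ≥ 0.90 across 20
noisy seeds; ≥ 90% ridge-mass removal with ≥ 90% vessel-mass retention and
the 90°-rotation swap; exact lag recovery at zero noise; mixed-model power
≥ 95/100 with type-I ≈ 5% on the emulated cohort; localization Dice ≥ 0.5
across 20 seeds; and the normalization invariants.

One property falls short and is reported as measured: with 10% per-point
noise on the 7-visit series, the injected −4-week lead is recovered within
±2 weeks in ~86% of 200 seeds, against a 90% target. The failures are
concentrated at |lag| = 8, where only 3 points overlap and the sample
correlation of 3 noisy points can exceed the true-lag correlation computed
on 5 — the maximize-r rule cannot tell these apart on so short a series. We
left the estimator faithful to its contract rather than raising the overlap
floor or shrinking the lag window after seeing the result; on real 7-visit
studies, lag estimates of ±8 weeks should simply be read with suspicion.

## Known limitations

* No deformable registration across weeks: spatial difference maps assume
  the skin–implant geometry is stable after week 2.
* No melanin/water/lipid chromophores, no fluence-depth correction: unmixed
  concentrations are relative and sO₂ is qualitative.
* 2-D single-scale vesselness: vessels far from 0.4 mm diameter, or
  vertically oriented true vessels, are attenuated by design.
* NIfTI-1 is the only volume format (the environment provides no TIFF
  reader); orientation matrices are ignored in favour of the documented
  axis convention.
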