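---
title: "Methods: QUS spectroscopy, texture derivatives and the outcome-prediction protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QUS spectroscopy, texture derivatives and the outcome-prediction protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `qusradiomics`, in the order of the analysis chain. Everything
stated here as an empirical behaviour is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from external data.

## 1. The RF phantom simulator

The simulator is the package's substitute for a clinical RF acquisition;
it exists so that every estimator can be validated against known ground
truth.

Each scan line is synthesised in the frequency domain as a sum of
point-scatterer echoes. A scatterer at depth `z` contributes
`a · exp(-i 2π f t)` with round-trip delay `t = 2z/c`, shaped by:

- a Gaussian pulse envelope whose −6 dB *power* points sit at the band
  edges (4 and 9 MHz around the 7 MHz centre; σ ≈ 2.13 MHz);
- a Rayleigh `f²` amplitude factor, giving the `f⁴` power dependence of
  sub-resolution scattering;
- the square root of the scatterer form factor at the phantom's effective
  diameter — the *same* form factor family the fitting stage uses, so the
  ASD round trip is convention-free;
- an acoustic-concentration gain `10^(AAC/20)`, with the reference phantom
  defined as 0 dB;
- frequency-linear attenuation: the power-spectrum loss at depth `z` is
  `2 α f (2z)` dB with `α` in dB/cm/MHz and `f` in MHz. The estimator
  inverts exactly this convention (`ACE = −mean(slope_f/4f)`), so recovery
  does not depend on how the factor of two is split between path and
  pulse-echo conventions.

Scatterer amplitudes are unit normal; per-line sums are normalised by the
expected scatterer count so that expected echo power is independent of
density. Lateral structure is per-line only (no elevational dimension, no
lateral point-spread function): windows average adjacent lines as
independent speckle realisations, which makes spectral averaging slightly
more efficient than in a real scanner. 2-D frames suffice because the
whole analysis is per-frame.

**Speckle density.** Fully developed speckle needs several scatterers per
resolution cell (~0.23 mm pulse length × 0.234 mm line pitch). The default
of 200 scatterers/mm² gives roughly ten per cell; below ~150/mm² the
amplitude statistics become visibly sub-Rayleigh and the default should
not be lowered.

**Scatterer-spacing lattice.** A quasi-regular axial lattice (default
spacing jitter 2%, coherent across lines, echo amplitude three times the
diffuse RMS) is superposed when `mean_spacing` is set. These values are a
deliberate design point: a 2.2 mm window spans only two to three lattice
periods, and the windowed spectrum blurs the spacing ripple to roughly a
fifth of its free-field contrast, so a weaker or more disordered lattice
is not identifiable at single-window scale. With the defaults the spacing
estimator resolves a 1 mm lattice to within a few percent (ROI-median
across windows).

**Cohorts.** `simulate_cohort()` draws week-0 phantom parameters per
patient (AAC ~ N(25, 4) dB, ASD ~ N(110, 10) µm, ACE ~ N(0.5, 0.08)
dB/cm/MHz) and applies group-specific week-4 shifts. The defaults encode
the response hypothesis — treatment response (the non-recurring group)
raises acoustic concentration (+6 dB vs +1 dB) and shrinks effective
scatterer size (−20 µm vs −3 µm) — with patient-level noise on top.
Recurrence times are exponential with median 24 months; non-recurring
patients use a ~12× flatter hazard; administrative censoring is uniform on
48–118 months, so non-events have at least four years of follow-up. These
choices support Kaplan–Meier and log-rank testing but make no claim of
clinical calibration: no quantitative description of how the outcome
groups' parameters actually differ is available, so all effect sizes are
free parameters of the experiment, not estimates.

`simulate_feature_cohort()` generates the 190-feature model rows directly
(independent standard normals plus named group shifts in SD units). It is
the right tool for studying the *classifier protocol*, because it can
place a known effect in any feature tier — including texture derivatives,
which cannot be targeted selectively through phantom parameters.

## 2. Spectral estimation

- **Windows.** Square 10λ blocks (2.2 mm) with a 6%-of-side step (94%
  overlap; 0.132 mm). Steps snap to ≥ 1 pixel per axis: with a 256-element
  / 60 mm array the lateral pitch (0.234 mm) exceeds the nominal step, so
  the lateral step is one line. Windows are kept only if fully inside the
  ROI (no partial windows, no boundary spectra), and the window lattice is
  anchored to the ROI bounding box.
- **Periodograms.** Hann taper per line, averaged across the window's
  lines, zero-padded to 2048 points (19.5 kHz bin spacing).
- **Reference.** The reference phantom is homogeneous, attenuation-free
  and Rayleigh (form factor 1, AAC 0 dB), so its expected window spectrum
  is depth-invariant; reference periodograms are therefore pooled over
  frames, depths and lateral positions. This matters: a per-depth
  reference injects depth-structured noise that the attenuation regression
  amplifies into a spurious ACE.
- **Attenuation.** ACE is estimated once per ROI from the depth regression
  and then applied as a single-pass spectral correction
  (`+2·ACE·f·2z` dB) before the parameter fits. An iterated
  estimate-correct loop was considered and rejected: the correction term
  is linear in ACE, so one pass is exact up to estimator noise.
- **Line fit.** SS and SI are the OLS slope and 0 MHz intercept of the
  corrected dB spectrum against frequency in MHz (intercept extrapolated
  to zero frequency, the standard convention); MBF is the fitted value at
  7 MHz, so `MBF = SI + SS·fc` holds to machine precision by construction.
- **SAS.** The dB spectrum over a widened 3–11 MHz band is detrended with
  a quadratic, its autocorrelation is searched for the dominant local peak
  at lags corresponding to spacings of 0.4–2 mm, and the peak is refined
  by parabolic interpolation; `SAS = c/(2Δf)`. Peaks below correlation 0.3
  are sentinels (`NA`): they are excluded from the SAS map mean and their
  count is reported. On diffuse media most windows are sentinels and the
  remainder are false detections — an intrinsic property of spacing
  estimators at this gate length, which is why SAS is the noisiest map.
- **ASD/AAC.** The backscatter coefficient is
  `BSC(f) = BSC_ref(f) · 10^(normalised dB/10)` with
  `BSC_ref = f_MHz⁴` fixed by the reference convention. The fit minimises
  the mean squared dB deviation from `A·f⁴·FF(f; d)`; for fixed `d` the
  optimal `A` in dB is the mean residual, so the search is 1-D in `d`
  (40-point log grid then local refinement, diameter parameterised in µm;
  bounds 10–400 µm, bound-pinned fits flagged). The Gaussian form factor
  `exp(−0.827 k² (d/2)²)` is the default; the Anderson fluid-sphere
  solution (partial-wave series in spherical Bessel functions, truncated
  at 30 terms, normalised to its Rayleigh limit; default density and
  sound-speed ratios 1.1 and 1.05) is available behind the same interface.

Measured at the test suite's problem size (512 × 32-sample frames,
~330-window ROIs, ten seeds), mean recovery errors are ~3% for ASD, ~2%
for AAC, ~0.03 dB/cm/MHz for ACE, ~3% for SAS — comfortably inside the
documented tolerances (10%, 15%, 0.15, 5%).

## 3. Texture features and derivatives

GLCM settings follow the defaults of the numerical environment that
popularised this feature family: 16 grey levels, distance 1, four angles
(0°, 45°, 90°, 135°) pooled, symmetric counts, homogeneity denominator
`1 + |i − j|`. All are exposed in `texture_config()` because contrast in
particular scales with the quantisation. Quantisation is per-map min–max
(so texture values are invariant to monotone linear rescaling of a map,
but *not* comparable across cohort-fixed absolute scales — a config choice
to revisit for multi-centre data). Absent (non-ROI) cells never pair.
Correlation of a zero-variance matrix is the 0 sentinel (0/0 otherwise).

First-order texture scalars (Tex¹) are computed from the whole-ROI map
GLCM by default; the alternative reading — means of local texture maps —
is available as `tex1_mode = "local_mean"`, since either is defensible at
this locality scheme. Texture maps for the derivative stage use a
5 × 5-cell kernel with step 1 (global grey levels, so a kernel equal to
the whole map reproduces the whole-map features exactly); the kernel size
is a design choice, not a published constant. Derivatives exclude the SAS
and SS parents, leaving 4 parents × 4 features = 16 maps and 64
Tex¹-Tex² values. Bookkeeping — 24 Tex¹, 16 maps, 64 Tex², 95 per time
point, 190 per model row — is asserted structurally in the tests.

## 4. Classification protocol

Class imbalance (e.g. 28 vs 55) is handled by seven balanced subsets: each
contains every minority patient plus an equal-size majority draw without
replacement; seven is odd, so majority votes cannot tie, and the vote
fraction (k/7) provides a non-degenerate ROC score. Base learners are
k-NN (k = 3, Euclidean on z-scored features, distance ties broken by
lowest training index for bit-for-bit determinism) and RBF-SVM (C = 1,
kernel width 1/n_features on z-scored features). Standardisation
statistics come from the training remainder of each fold only; the
held-out patient is removed from every subset at its own fold.

Forward selection (≤ 3 features, greedy on LOPO balanced accuracy, ties by
name order) by default wraps the LOPO loop once on the full cohort. This
matches the reporting style of single selected-feature triples, but it
leaks selection information into the reported metrics: with ~190
candidate features and no signal, the *reported* AUC of the selected model
is optimistically biased (roughly 2–3 null standard deviations, i.e. up to
~0.65–0.70 at n = 83) even though each candidate's own LOPO estimate is
unbiased. The unbiased variant — selection re-run inside every fold — is
provided (`nested = TRUE`) and is the right choice when the AUC itself is
the scientific claim; it is roughly n times slower. The package's null
calibration therefore fixes the feature set: with zero injected effect the
ensemble's LOPO AUC is 0.50 ± 0.07 across seeds.

Metrics: Sn, Sp, Acc as percentages from the confusion counts; AUC from
the mid-rank (Mann–Whitney) statistic over vote fractions; 95% CIs from a
2000-resample patient bootstrap (percentile method; degenerate one-class
resamples skipped). Univariate screening applies Shapiro–Wilk per group at
α = 0.05 and then a pooled-variance t-test or Mann–Whitney U, two-sided,
significant at p < 0.05 with no multiplicity correction — a screening
convention, not an inferential claim, given 190 correlated features.

## 5. Survival

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package, with conventions fixed here: events precede
censorings at tied times; the five-year read-out is the step value at the
last event time ≤ 60 months; median follow-up is computed over all
patients. Predicted-group comparison requires both predicted classes to be
non-empty and errors informatively otherwise.

## 6. Problem sizes and limitations

The shipped tests and the acceptance script run on deliberately small
instances chosen as the package's reference experiment sizes: 512 × 32
frames with ~280 × 22-pixel ROIs (≈ 330 windows), ten-seed recovery runs,
a 5 + 5-patient end-to-end RF pipeline, and an 83-patient feature-level
cohort for the classifier protocol. Larger frames and cohorts scale
linearly.

Known limitations, in decreasing order of importance:

- The simulator is a convolution model: no diffraction, no lateral PSF,
  no elevational beam, no nonlinear propagation, no electronic noise.
  Passing recovery tests shows the estimators invert the simulator's
  physics; it does not certify performance on scanner data.
- Texture-derivative effects can only be injected at the feature level;
  the RF-level cohort generator moves mean-QUS features (and, indirectly,
  their textures), so the tier-comparison experiment uses the
  feature-level generator.
- Per-window SAS at 2.2 mm gates is intrinsically noisy; treat the SAS
  map mean with caution and prefer the ROI median.
- The cohort persistence format is RDS + JSON sidecar, chosen for lossless
  float64 round-tripping within R.
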