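# qusradiomics

Quantitative ultrasound (QUS) radiomics with texture derivatives, for
predicting treatment outcome from raw radiofrequency (RF) echo data.

In locally advanced breast cancer, tumours are imaged with a ~7 MHz linear
array before systemic therapy (week 0) and again early during treatment
(week 4). Treatment-induced cell death changes tissue microstructure, and
those changes are visible in the *spectrum* of the raw backscattered RF
signal well before any morphological response. This package implements the
full analysis chain that turns two RF scans per patient into a recurrence
prediction and a survival comparison — plus a synthetic RF phantom cohort
generator with known ground truth, so that every stage is testable without
clinical data.

## What it computes

**Spectral parameters.** Each tumour ROI is tiled with 10λ × 10λ analysis
blocks (2.2 mm at c = 1540 m/s, f_c = 7 MHz) with 94% adjacent overlap.
Per window, the Hann-tapered, line-averaged power spectrum is normalised by
a homogeneous reference phantom and corrected for frequency-linear
attenuation. Over the −6 dB band (4–9 MHz):

- **MBF, SS, SI** — a least-squares line `S(f) = SI + SS·f` through the
  normalised dB spectrum; MBF = value at f_c (so MBF = SI + SS·f_c
  identically).
- **SAS** — mean scatterer spacing from the dominant ripple of the
  spectral autocorrelation, `SAS = c / (2 Δf)`.
- **ASD, AAC** — effective scatterer diameter and acoustic concentration
  from a form-factor fit `BSC(f) = A · f⁴ · FF(f; d)` (Gaussian form
  factor by default, Anderson fluid-sphere available).
- **ACE** — attenuation slope (dB/cm/MHz) from the depth regression of the
  normalised spectrum, `ACE = −mean(slope_f / 4f)`; used both as the
  spectral correction and as a feature.

**Texture and texture derivatives.** Six parametric maps (MBF, SS, SI,
SAS, ASD, AAC) are quantised to 16 grey levels and summarised by GLCM
contrast, correlation, energy and homogeneity → 24 first-order texture
features (Tex¹). Sliding-kernel texture maps of the MBF/SI/ASD/AAC parents
(16 maps) are summarised again → 64 texture derivatives (Tex¹-Tex²,
"texture of texture"). With the 7 mean spectral parameters this gives 95
features per time point, and each patient's model row combines week-0
values with week-4 − week-0 differences: 190 features.

**Classification protocol.** Because outcome groups are imbalanced, seven
class-balanced training subsets each train one classifier (k-NN, k = 3, or
RBF-SVM) on z-scored features; the predicted label is the majority of the
seven votes and the vote fraction is the ROC score. Features are chosen by
greedy forward selection (≤ 3), and everything is evaluated by
leave-one-patient-out cross-validation with sensitivity, specificity,
accuracy and AUC plus bootstrap 95% CIs.

**Survival.** Predicted groups are compared by Kaplan–Meier product-limit
curves and the log-rank test, with a five-year recurrence-free-survival
read-out.

## Worked example

Estimate parametric maps from a simulated speckle phantom with known
ground truth (ASD 120 µm, AAC 30 dB, attenuation 1.0 dB/cm/MHz):

```r
library(qusradiomics)
cfg   <- acq_config(n_samples = 512L, n_lines = 32L)
ref   <- simulate_reference_frames(cfg, n_frames = 6, seed = 402)
roi   <- matrix(FALSE, cfg$n_samples, cfg$n_lines); roi[140:420, 6:27] <- TRUE
ph    <- phantom_spec(scatterer_diameter = 120e-6, acoustic_concentration = 30,
                      attenuation = 1.0, rng_seed = 77)
frame <- simulate_rf_frame(ph, cfg)
build_parametric_maps(frame, roi, ref, cfg)
#> QUS parametric maps:
#>     MBF      SS      SI     SAS     ASD     AAC     ACE
#>  16.735  -3.132  38.662   0.898 126.533  28.942   0.876
#>   336 windows, 290 SAS sentinel cells
```

ASD is recovered within ~5%, AAC within ~1 dB, ACE within ~0.12; the SAS
sentinels mark windows of this diffuse phantom with no resolvable spacing
ripple. Fit the classifier protocol on a synthetic 28/55 cohort whose
response signal lives in texture derivatives:

```r
rows <- simulate_feature_cohort(28, 55,
          effect = c("dASD-CON-CON" = 1.5, "dAAC-CON-CON" = 1.5), seed = 1)
fit <- qus_model(rows, candidates = feature_tier("all"), seed = 1)
fit
#> Balanced-subset KNN ensemble (7 subsets, cohort-level selection)
#> Selected features: dAAC-CON-CON, dASD-HOM-HOM, SI_W0
#> LOPO-CV metrics (n = 83, positive = 'recurrence'):
#>   sensitivity   92.86%  (95% CI 81.82-100.00)
#>   specificity   81.82%  (95% CI 70.69-92.00)
#>   accuracy      85.54%  (95% CI 77.11-92.77)
#>   auc            0.89  (95% CI 0.81-0.95)

predicted_group_survival(fit$preds, rows[, c("patient_id", "time", "event")])
#> Predicted-group recurrence-free survival:
#>   predicted nonrecurrence  five-year RFS 93.4% (n = 47)
#>   predicted recurrence     five-year RFS 30.3% (n = 36)
#> Log-rank test: chi-square = 44.475 (df = 1), p = 2.577e-11
```

The selection lands on the injected texture-derivative features, and the
predicted groups separate sharply in recurrence-free survival. Restricting
candidates to `feature_tier("qus_tex1")` (no texture derivatives) drops the
AUC to ~0.69 — the incremental value of the higher-order features.

`run_qus_pipeline()` chains all stages (RF simulation → feature extraction
→ classification → survival) from one global seed and can write the
feature CSV, a JSON report and a reproducibility manifest.

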