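Package: qusradiomics
Title: Quantitative Ultrasound Radiomics with Texture Derivatives for
    Treatment-Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative ultrasound (QUS) spectroscopy and delta
    radiomics from raw radiofrequency (RF) echo data.  Estimates spectral
    parameters (mid-band fit, spectral slope and intercept, scatterer
    spacing, effective scatterer diameter and acoustic concentration via
    form-factor fits, and the attenuation coefficient) over sliding analysis
    windows, builds parametric maps, computes grey-level co-occurrence
    texture features and higher-order texture derivatives, and assembles
    per-patient two-time-point feature vectors.  Includes a synthetic RF
    speckle-phantom cohort generator with known ground truth, a
    class-balanced subset majority-voting classifier protocol (k-NN and
    RBF-SVM) with forward feature selection and leave-one-patient-out
    cross-validation, and Kaplan-Meier / log-rank survival comparison of
    predicted outcome groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    e1071,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, png, tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
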