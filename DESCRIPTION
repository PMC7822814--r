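Package: fluorox
Title: Placental Oximetry from Fluorine-19 Saturation-Recovery MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative oximetry pipeline for fluorine-19 (19F) magnetic
    resonance imaging of the mouse placenta. Converts multi-TR 19F magnitude
    volumes into oxygen partial pressure (PO2) per placenta: Rician noise
    estimation from a signal-free region, Gudbjartsson-Patz corrected
    signal-to-noise conversion, interpolation to the anatomical grid,
    in-plane Gaussian smoothing and SNR thresholding, region-of-interest
    saturation-recovery T1 fitting, and a linear calibration from the
    longitudinal relaxation rate of perfluoro-15-crown-5-ether to PO2.
    Group inference uses nested linear mixed-effects models (placentas
    within mothers, oxygen challenge as the within-subject factor) with
    Satterthwaite degrees of freedom. A synthetic phantom generator
    reproduces the study design end to end so every stage is testable
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    minpack.lm,
    lme4,
    lmerTest,
    emmeans,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
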