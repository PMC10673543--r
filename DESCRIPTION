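Package: acidocest
Title: Ratiometric CEST-MRI Tumor pH Imaging with Digital Phantom Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracellular tumor pH (pHe) mapping from iopamidol
    CEST (chemical exchange saturation transfer) MRI. Implements an N-pool
    Bloch-McConnell simulator for continuous-wave saturation, a self-generated
    ratiometric calibration linking the 4.2/5.5 ppm saturation-transfer
    contrast ratio to pH, digital mouse-tumor phantom cohorts with known
    ground-truth pH fields and Rician noise, the per-voxel Z-spectrum
    processing pipeline (smoothing-spline interpolation, B0 correction,
    saturation-transfer and contrast-difference maps), pixel-wise pHe and
    acidity-score maps over tumor ROIs, and the cohort statistics used in
    preclinical treatment-efficacy studies (tumor volume, summary-statistic
    t tests, ANOVA with Bonferroni correction, Shapiro-Wilk normality checks,
    and Kaplan-Meier survival with log-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    rlang,
    stats,
    survival,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
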