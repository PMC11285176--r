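Package: frocdwi
Title: Fractional-Order Calculus Modelling of Multi-b-Value Breast
    Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of multi-b-value diffusion-weighted
    MRI of breast lesions with the fractional-order calculus (FROC)
    diffusion model. Provides the FROC and mono-exponential forward signal
    models, voxel-wise bounded Levenberg-Marquardt fitting of D, beta and
    mu parameter maps, digital phantoms with Rician noise and two-group
    lesion cohort generators, ROI signal-to-noise and contrast-to-noise
    metrics, and the full benign-versus-malignant diagnostic statistics
    stage: normality-gated group tests, Spearman and intraclass-correlation
    agreement with category labels, Bland-Altman limits of agreement, ROC
    analysis with Youden cutoffs and DeLong comparisons, multivariate
    logistic modelling with nomogram construction, Hosmer-Lemeshow and
    bootstrap calibration, and decision-curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pROC,
    RNifti,
    jsonlite,
    yaml,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
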