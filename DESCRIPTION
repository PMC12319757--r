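Package: ivimretest
Title: IVIM Model Fitting and Test-Retest Reliability for Spinal Cord
    Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the intravoxel incoherent motion (IVIM) biexponential
    model to diffusion-weighted MRI signal decays using constrained
    one-step and two-step (segmented) algorithms built on a Differential
    Evolution global optimizer, voxel-wise or region-wise. Includes a
    synthetic cervical-cord phantom generator with Rician noise and
    known ground truth, quality-control utilities (SNR maps, mask
    erosion), and a complete test-retest reliability battery:
    within-subject coefficients of variation, intraclass correlation
    (two-way model, absolute agreement), Bland-Altman analysis, Pearson
    correlation, and two-factor repeated-measures ANOVA on the CVs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    minpack.lm,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
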