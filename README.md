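# ivimretest

Intravoxel incoherent motion (IVIM) model fitting and test-retest
reliability analysis for diffusion-weighted MRI of the cervical spinal
cord — or any organ where a biexponential perfusion/diffusion decomposition
and a scan-rescan repeatability battery are needed.

IVIM separates the diffusion-weighted signal decay into a fast
pseudo-diffusion component from capillary blood and a slow thermal-diffusion
component:

```
S(b) = S0 · exp(−b·D) · [ F·exp(−b·D*) + 1 − F ]
```

where `F` is the microvascular volume fraction, `D*` the pseudo-diffusion
coefficient, `D` the tissue diffusion coefficient, and `F·D*` a blood-flow
related product. The package provides:

- **Constrained fitting** of the model by two standard algorithms built on an
  in-package Differential Evolution global optimizer: a *one-step* fit of all
  parameters over all b-values (with a mono-exponential high-b prior for `D`
  and a 95–105% fine-tuning pass), and a *two-step* "segmented" fit that
  fixes `D` to the high-b mono-exponential estimate. Both voxel-wise (maps)
  and ROI-wise (probability-weighted average decay per slice).
- **A synthetic cervical-cord phantom**: multi-subject, two-session,
  three-direction acquisitions with known ground truth, between-subject and
  between-session variance components, and Rician noise at a configurable
  SNR — the test bed for the whole pipeline.
- **A reliability battery**: within-subject coefficients of variation, ICC
  (two-way, absolute agreement), Bland-Altman bias and limits of agreement,
  Pearson scan-rescan correlation, and a 2×2 repeated-measures ANOVA of the
  CVs across fitting approaches and algorithms.
- **Pipeline utilities**: NIfTI + FSL-bval I/O, repetition averaging,
  voxel-wise SNR maps with the √Nrep convention, spherical mask erosion,
  direction averaging, per-ROI metric extraction, and a one-call
  `run_study()` orchestrator.

## Worked example

Fit a noiseless decay generated from published white-matter cord values
(F = 5.45 %, D* = 24.41 × 10⁻³ mm²/s, D = 3.74 × 10⁻⁴ mm²/s):

```r
library(ivimretest)

scheme <- bvalue_scheme()            # 0..650 s/mm2, step 50, cutoff 400
truth  <- ivim_params(S0 = 1, F = 0.0545, Dstar = 24.41e-3, D = 3.74e-4)
decay  <- forward_signal(truth, scheme)
fit    <- fit_one_step(decay, fit_config("one_step", seed = 1))
print(fit)
#> IVIM one_step fit (voxel_wise): R2 = 1.0000, converged = TRUE
#> IVIM parameters: S0 = 1, F = 5.45%, D* = 24.410 e-3 mm2/s, D = 3.740 e-4 mm2/s, F.D* = 13.303 e-4 mm2/s
```

The generating values are recovered exactly (to optimizer tolerance). A
small end-to-end test-retest study on the synthetic phantom:

```r
spec <- phantom_spec(n_subjects = 5, grid = c(14L, 14L, 3L),
                     n_repetitions = 4, seed = 42)
res <- run_study(spec, fit_config(seed = 1), modes = "roi_wise", anova = FALSE)
subset(res$report$stats, parameter == "D",
       select = c(roi, algorithm, wscv_mean, wscv_sd, icc, icc_label, pearson_r))
#>    roi algorithm wscv_mean wscv_sd   icc icc_label pearson_r
#> 1   gm  one_step      4.63    6.19 0.610      good     0.660
#> 2   gm  two_step      4.69    6.28 0.545      fair     0.674
#> 9   wm  one_step      5.65    3.32 0.913 excellent     0.927
#> 10  wm  two_step      6.85    3.52 0.880 excellent     0.909
```

Each row summarizes the scan-rescan repeatability of the diffusion
coefficient `D` in one ROI under one fitting algorithm: the mean ± SD of the
per-subject within-subject CVs (in percent), the absolute-agreement ICC with
its Cicchetti label, and the Pearson correlation between the two sessions.
A command-line wrapper over the same functions lives in
`inst/cli/ivim_pipeline.R` (subcommands `simulate`, `fit`, `reliability`,
`run-study`).

See `vignettes/ivim-test-retest.Rmd` for the model, the optimizer's
numerical choices, what the phantom does and does not emulate, and the
statistical conventions.

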