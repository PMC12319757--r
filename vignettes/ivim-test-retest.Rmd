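---
title: "IVIM fitting and test-retest reliability: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IVIM fitting and test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimretest)
```

## The signal model

Diffusion-weighted MRI of perfused tissue mixes two decay processes. Water in
the capillary bed undergoes pseudo-random displacement far faster than thermal
diffusion, so its signal contribution collapses at low diffusion weighting;
the remaining tissue water decays mono-exponentially with the diffusion
coefficient. The intravoxel incoherent motion (IVIM) model writes the signal
at b-value $b$ as

$$S(b) = S_0\, e^{-bD}\left[F e^{-bD^*} + 1 - F\right]$$

with $S_0$ the amplitude, $F$ the microvascular volume fraction, $D^*$ the
pseudo-diffusion coefficient (proportional to capillary blood velocity), and
$D$ the tissue diffusion coefficient. The product $F \cdot D^*$ tracks blood
flow. `forward_signal()` implements this for any non-negative b grid, so
simulation can use denser sampling than the 14-point acquisition scheme
(0 to 650 s/mm² in steps of 50) that the package defaults assume.

Internally $F$ is always a fraction in $[0,1]$; percent appears only in
reported tables. This avoids unit mistakes inside the optimizer.

## Constrained fitting: one-step and two-step

Both algorithms bound the parameters to published physiological ranges for
cord and brain tissue:

| parameter | lower | upper | units |
|---|---|---|---|
| $F$ | 0 | 0.20 | fraction |
| $D^*$ | 0.3e-3 | 50e-3 | mm²/s |
| $D$ | 1.5e-4 | 54e-4 | mm²/s |
| $S_0$ | 0.5 × | 1.5 × | observed $S(0)$ |

The **one-step** algorithm runs three stages: (1) a mono-exponential
least-squares fit of $\log S$ against $b$ restricted to $b > 400$ s/mm²
(above this cut-off the perfusion term is below $10^{-6}$ of the signal at
cord-typical parameters, so the tail is effectively mono-exponential) gives a
prior estimate of $D$; (2) a global fit of $(S_0, F, D^*, D)$ over all
b-values by Differential Evolution minimizing the sum of squared residuals
inside the bounds; (3) a fine-tuning pass that shrinks every parameter's
bounds to 95--105% of its stage-2 estimate (intersected with the global
bounds, one-sided if the estimate sits on a bound) and refits.

The **two-step** (segmented) algorithm fixes $D$ to the stage-1
mono-exponential estimate and never revisits it: stage 2 fits $(S_0, F, D^*)$
with $D$ held fixed, and the fine-tuning pass refines $F$ and $D^*$ only.
The returned $D$ is therefore *exactly* the closed-form high-b slope
(clipped into the $D$ bounds), which the tests assert without invoking the
optimizer at all.

$S_0$ is fitted as a free parameter by default because it absorbs noise in
the $b=0$ frames; `s0_mode = "fixed"` pins it to the observed $b=0$ value
for users who prefer normalization-only handling.

The role of the prior $D$ is genuinely ambiguous in the segmented-fit
literature: it can either seed the optimizer or narrow the search interval.
The package always injects it into the initial population, and additionally
narrows the $D$ interval to 0.5--2 times the prior when
`use_prior_bounds = TRUE`; the published global bounds remain the outer
constraint in every case. The default keeps the global bounds only, which is
the more conservative reading.

## Numerical choices in the optimizer

No R package in the installed stack provides Differential Evolution, and the
optimizer is load-bearing here (the biexponential least-squares surface has a
well-known spurious basin where a large-$F$, small-$D^*$, small-$D$
combination mimics the true decay), so `de_optimize()` implements DE
directly:

- **Strategy** best/1/bin, population 15 per free parameter.
- **Mutation dithering**: the differential weight is redrawn uniformly in
  $[0.5, 1]$ each generation. With a fixed weight the best/1 strategy
  occasionally collapsed the whole population into the spurious basin on
  noiseless decays; dithering maintains diversity and removed those failures
  in a 150-truth stress test.
- **Seeded initial population**: the mono-exponential prior $D$ is combined
  with a coarse 4 × 3 grid over $(F, D^*)$, including $F = 0$, so both the
  perfusion basin and the no-perfusion solution are always represented among
  the initial candidates. The $F = 0$ candidates matter for decays that are
  truly mono-exponential, where $D^* \approx D$ solutions are
  near-degenerate with the truth.
- **Convergence** when the population costs collapse:
  $\mathrm{sd}(\mathrm{cost}) \le 10^{-7}\,|\overline{\mathrm{cost}}| + 10^{-14}$,
  capped at 1000 generations. Non-convergence is reported via
  `converged = FALSE` with the best member found, never an exception.
- **Degeneracy tie-break**: if the stage-2 $F$ is numerically zero
  ($\le 10^{-6}$), $D^*$ is unidentifiable and is reported at its lower
  bound with `dstar_identifiable = FALSE` rather than left at an arbitrary
  position in the interval.
- **Determinism**: every fit carries an explicit seed; per-voxel seeds are
  derived from the configuration seed and the voxel's linear index only —
  not the session or execution order — so identical decays always produce
  identical results and a noiseless scan-rescan simulation yields *exactly*
  zero within-subject CV.

A fit of one 14-point decay takes about 30 ms on one CPU core. Voxel-wise
fitting memoizes identical decays, which makes homogeneous noiseless
phantoms nearly free.

## Voxel-wise and ROI-wise application

`fit_voxelwise()` fits every masked voxel per diffusion-encoding direction
and returns per-direction maps of $F$, $D^*$, $D$, $F\cdot D^*$, $S_0$ and
$R^2$; `average_maps_across_directions()` then forms the voxel-wise mean
with NA propagation. `fit_roiwise()` instead averages the signal first —
for each slice, the probability-weighted mean
$\sum_i p_i s_i / \sum_i p_i$ over the ROI's probabilistic mask — and fits
that single decay per slice and direction. Slices without ROI support, or
whose fit fails, are recorded and skipped, never zero-filled.

Repetition averaging happens before ROI averaging; for fixed weights the two
orders are mathematically identical for arithmetic means, so the cheaper
order is used.

## The synthetic phantom

Because no deposited cohort data exist, the package ships a generator that
emulates the statistical structure the reliability analysis assumes, with
the acquisition geometry of a cervical-cord protocol:

- elliptical cord cross-section (default 16 × 16 × 9 grid), central
  grey-matter region with a soft probabilistic boundary inside a
  white-matter annulus, identical across sessions (as for template-aligned
  data); slices split into three vertebral-level groups;
- 14 b-values 0--650 s/mm², 20 repetitions per b-value, three in-plane
  diffusion-encoding directions with $D$ scaled by (1.0, 0.9, 1.1) to mimic
  the direction-dependent diffusivity that motivates per-direction fitting
  (the magnitudes are a modeling choice);
- tissue means and between-subject SDs set to published session-1
  voxel-wise one-step cord values (WM: $F$ 5.45 ± 0.75%, $D^*$
  24.41 ± 2.61 × 10⁻³, $D$ 3.74 ± 0.49 × 10⁻⁴ mm²/s; GM: 9.61 ± 1.55%,
  17.14 ± 2.89 × 10⁻³, 4.17 ± 0.42 × 10⁻⁴);
- a zero-mean between-session perturbation per subject; its SD defaults to
  6% of each tissue mean. No published within-subject variance
  decomposition exists for these parameters, so this is a calibration: it
  places simulated within-subject CVs in the few-percent to mid-teens range
  reported for voxel-wise cord IVIM. It was chosen once and is not a fitted
  quantity;
- Rician magnitude noise (complex Gaussian followed by the modulus), with
  the noise SD set so the single-repetition $b=0$ SNR is 27; after
  averaging 20 repetitions the effective SNR is $27\sqrt{20} \approx 121$,
  matching the regime of gated cord acquisitions at 3T. A Gaussian mode is
  retained as a switch for oracle tests. The analytic Rician mean
  (`rician_mean()`) quantifies the positive magnitude bias the tests verify
  at high b and low SNR.

What the phantom does **not** emulate: motion, EPI distortion,
eddy currents, cardiac-driven signal fluctuations, CSF pulsation,
registration error, or segmentation variability. Passing reliability tests
on the phantom therefore demonstrate the correctness of the fitting and
statistics machinery under the assumed variance structure — not the field
performance of an acquisition protocol, whose test-retest variability
includes the entire preprocessing chain.

## The reliability battery

All statistics operate on a table of one scalar per subject × session ×
ROI × parameter × fitting configuration:

- **Within-subject CV**: $100\,\sigma_{ws}/\mu_{ws}$ with the sample
  ($n-1$) SD, i.e. $100\,|x_1-x_2|/(\sqrt2\,\bar x)$ for a scan-rescan
  pair — the standard paired-scan convention; the formula's denominator
  choice is stated because conventions differ.
- **ICC**, two-way model, absolute agreement, single measures:
  $(MS_R - MS_E)/(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$, labeled
  on the Cicchetti scale (poor < 0.4 < fair < 0.6 < good < 0.75 <
  excellent). The mean-squares ratio is consistent but biased low in small
  samples (a Jensen-type property of the nonlinear ratio, not of this
  implementation — which matches an independent `aov()` decomposition to
  10 decimal places and an external reference implementation); the unit
  tests demonstrate the bias vanishing at large $n$. Reliability studies
  with ~10 subjects should read ICC point estimates accordingly.
- **Bland-Altman**: differences fixed as session1 − session2 (a stated
  convention), bias ± 1.96 SD limits, per-subject points returned for
  plotting.
- **Pearson correlation** between sessions.
- **2 × 2 repeated-measures ANOVA** on the CVs with factors fitting
  approach (voxel-wise vs ROI-wise) and algorithm (one-step vs two-step),
  subject as the blocking factor, each effect tested against its own
  effect-by-subject interaction. Run separately per ROI and parameter.
  A plain fixed-effects two-way option (`method = "fixed"`) is kept for
  comparison. No multiple-testing correction is applied across ROIs or
  parameters; p-values are raw and reported as such.

Degenerate inputs raise typed errors (`degenerate-variance`,
`insufficient-subjects`, `undefined-CV`); the report assembler converts
them to NA with a note rather than producing spurious finite values — on a
noiseless, zero-session-effect phantom every CV is exactly zero and no ICC
is silently fabricated from a constant table.

## Problem sizes

The shipped tests use deliberately small instances: phantoms of
12--14 × 12--14 × 3 voxels (roughly 140--200 cord voxels), 1--2 subjects
for pipeline-structure checks, 1000 replicates for estimator-recovery
simulations and 2000 for the ANOVA type-I calibration. These sizes were
chosen so the full suite runs in well under a minute while keeping
Monte-Carlo error small relative to the tolerances being asserted; the
statistical machinery itself is size-agnostic and the default
`phantom_spec()` reproduces the full 10-subject, 9-slice study design.

## Known limitations

- $D^*$ is weakly identified whenever $F$ is small — a property of the
  model, handled by flagging rather than hiding.
- The spurious large-$F$ basin of the least-squares surface is suppressed
  by the seeded population and dithering, but with heavy noise the global
  minimum itself can sit in that basin; bounds then do the containment.
- The ROI-wise approach inherits the heterogeneity sensitivity it has in
  practice: averaging decays across a region with mixed parameters yields
  a fit that is not the average of the voxel fits except in homogeneous
  regions (the tests assert equality only there).
- The phantom's geometry is convex and static; none of the spatial
  preprocessing (registration, distortion, denoising) that a real pipeline
  needs is simulated, and the package deliberately contains no such stages.
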