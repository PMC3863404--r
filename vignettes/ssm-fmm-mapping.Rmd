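---
title: "Signal-strength and fluctuation-magnitude mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-strength and fluctuation-magnitude mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echomap)
```

## The signal model and the two mapping parameters

A multiecho gradient-echo acquisition images one slice at `n` ascending
echo times, so each pixel carries a decay curve sampled at the schedule
`TE_1 < ... < TE_n`. Under the monoexponential model the noiseless curve
is `V_k = W exp(-TE_k / T2*)`, with `W` mixing proton density, T1
weighting and system gain, and T2\* the effective transverse relaxation
time. The echoes are assumed spatially registered — the package performs
no registration — and intensities are magnitudes, hence nonnegative.

Given a reference curve `R`, `fit_ssm_fmm()` fits every pixel
independently by ordinary least squares of `V` on `R`:

$$\mathrm{MSE}_{ij} = \frac{1}{n}\sum_{k=1}^{n}
  \left(V_{ijk} - \lambda_{ij} R_k - \xi_{ij}\right)^2,$$

minimized in closed form by

$$\lambda_{ij} = \frac{\overline{VR} - \bar V\,\bar R}
                      {\overline{R^2} - \bar R^2},\qquad
  \xi_{ij} = \bar V - \lambda_{ij}\,\bar R,$$

with the overbar the plain arithmetic mean over the `n` echoes. The slope
map is the signal-strength map (SSM); the intercept map is the
fluctuation-magnitude map (FMM). The one-parameter similarity coefficient
map (SCM, `fit_scm()`) is the nested special case `xi = 0`, i.e.
`lambda = sum(V R) / sum(R^2)`; its exact historical formula is not fixed
in the literature we extend, and we deliberately implement it as the
intercept-free least-squares scale so that the two baselines are nested —
the two-parameter residual can then never exceed the SCM residual, a
property the test suite asserts pixelwise. The log-linear T2\* baseline
(`fit_t2star_map()`) regresses `log V` on TE over the echoes with `V > 0`.

Useful exact symmetries, all tested: scaling the stack by `c > 0` scales
both `lambda` and `xi` by `c`; scaling the reference by `c` divides
`lambda` by `c` and leaves `xi` unchanged; a pixel equal to the reference
returns `lambda = 1, xi = 0` to machine precision.

## Contrast index and contrast improvement

Map quality is scored with a no-reference windowed contrast index
(`local_contrast_index()`): for every fully interior `w x w` window
(default `w = 7`),

$$c = \frac{|m_f - m_b|}{m_f + m_b},$$

with `m_f` the centre pixel and `m_b` the mean of the remaining
`w^2 - 1` pixels; CI is the mean of `c` over retained windows. Windows
with zero denominator or containing invalid pixels are skipped. CI is
scale-invariant (so it can compare maps whose units differ), bounded in
`[0, 1]` on nonnegative input, and strictly decreases when a constant is
added to a non-constant image. The contrast improvement index is the
plain ratio `CII = CI_map / CI_ori` against an original echo; reports
average it over all echoes.

Three conventions here were genuinely open and are package decisions:

* **Foreground/background in the window.** We use the standard
  single-pixel convention (centre = foreground, other 48 pixels =
  background). Any larger foreground patch would smooth the index and
  change no qualitative conclusion, but the single-pixel form is the
  common definition of local contrast.
* **Absolute value in the numerator.** The signed form would let positive
  and negative local contrasts cancel in the average; a magnitude is
  required for CI to act as a quality score, so we fold the sign.
* **Signed maps.** CI presumes nonnegative luminance while the fitted
  maps are signed. `map_for_contrast()` clamps SSM/SCM slopes at zero
  (a slope below zero carries no signal-strength meaning and the map is
  defined on `[0, Inf)`) and scores FMM on `|xi|`, consistent with its
  reading as a fluctuation *magnitude*. The optimizer uses the same
  conventions.

## Automatic reference selection

`optimize_reference()` removes the manual-ROI step: for each candidate
T2\* on a grid (default 1–120 ms in 1 ms steps, matching the precision at
which optima are meaningfully reported), it generates the model reference,
fits SSM and FMM, and evaluates `CI(SSM) + CI(FMM)`; the returned
reference sits at the grid argmax. The grid is sorted and deduplicated and
the first maximum is taken, so ties break to the smallest candidate — a
pure reproducibility convention. The search is exhaustive with no
interpolation: the objective is cheap (one closed-form fit plus two
integral-image CI passes per candidate; the full 120-point sweep on a
96×96 stack takes under a second) and the objective is not guaranteed
unimodal.

The reference amplitude is `W = 0.8 x` the stack maximum. The objective
is exactly invariant to this choice: rescaling `R` by `c` divides every
slope by `c`, leaves every intercept unchanged, and CI is
scale-invariant. The test suite asserts the full trace is identical to
`1e-10` between `w_fraction` 0.2 and 0.8; `W` therefore only sets the
output maps' scale.

## Numerical and degenerate-input choices

* A reference with zero variance is rejected at construction — the slope
  denominator would be zero — rather than producing NaN maps.
* T2\*-map pixels with fewer than two positive echoes, a degenerate TE
  subset, or a non-decaying fit (slope ≥ 0, infinite or negative T2\*)
  are flagged invalid and stored as `NA`; CI windows touching them are
  skipped, and `write_map()` serializes them as NaN.
* Negative slopes are *retained* in the stored SSM (the algebra allows
  them and they carry information); clamping happens only when a map
  enters CI.
* Pixels are always fit unmasked. An optional intensity-threshold air
  mask (`mask_threshold` in `contrast_report()`, `--mask-threshold` in
  the CLI) can exclude background pixels from CI scoring; it is off by
  default, so by default background pixels participate in both fitting
  and CI.
* CI uses an integral-image (summed-area table) implementation; the test
  suite checks it against a naive two-loop oracle to `1e-10`.

## What the phantom emulates — and what it does not

`vein_phantom_spec()` is the package's standard synthetic object,
emulating a single T2\*-weighted brain slice on the 12-echo schedule
TE = 2.61 + 3.3·k ms (k = 0..11): a large tissue disk (`W = 100`,
T2\* = 48 ms) containing two thin vein-like line segments with fast decay
(T2\* = 12 ms, `W = 110`) and a small slow-decaying nodule (`W = 80`,
T2\* = 70 ms), over an air background (`W = 0`). Default noise is Rician
with `sigma = 1` (1 % of tissue `W`): the clean signal plus complex
Gaussian noise, taken in magnitude — the noise law of magnitude MR
images. The seed is an explicit required field; generation is
bit-reproducible and leaves the caller's RNG stream untouched.

The noise law matters more than it may appear. In air, Rician noise gives
strictly positive Rayleigh-distributed intensities, so original echoes
show moderate local contrast there; the SSM slope in air fluctuates
around zero with both signs, and clamping at zero creates many exact
zeros, which drives windowed contrast up. This is the mechanism by which
the derived maps out-contrast the original echoes on real magnitude data,
and with it the phantom reproduces the qualitative behaviour expected of
the method: echo CI rising slowly with TE, `CII(SCM) < 1`,
`CII(SSM) > 1`, `CII(FMM) > CII(SSM)`, and a sweep argmax at the tissue
T2\* of 48 ms. An earlier design with a weak-tissue background and
clipped-Gaussian noise did not show the SSM gain, precisely because it
lacked the magnitude-noise air floor.

What the phantom does **not** emulate: partial-volume mixing at tissue
borders, coil-sensitivity/bias fields, susceptibility artifacts, motion,
anatomical texture within tissue, and multi-slice geometry. Passing the
phantom-based tests therefore demonstrates correctness of the estimators
and the direction of the contrast gains under ideal piecewise-constant
conditions, not performance on real brain data; the in-vivo magnitudes of
the contrast gains are data-dependent.

## Problem sizes and determinism in the test suite

The suite fits 96×96 and smaller phantoms, uses a 100-pixel random stack
for the least-squares oracle comparison, 16×16 images for the CI oracle,
and coarse sub-grids of the T2\* sweep where the full 120-point grid adds
nothing; the end-to-end CLI check runs the phantom → optimize → contrast
pipeline twice and compares file checksums. All stochastic tests fix
their seeds; the only randomness in the package itself is the phantom's,
governed by its explicit seed.

## Limitations

The method assumes monoexponential decay per pixel and a single global
reference curve; multi-compartment decay, flow, and strong field
inhomogeneity violate both. CI compares maps with different physical
units through a unitless ratio — it ranks contrast, not diagnostic
value. DICOM input is not currently supported; supply NIfTI with a JSON
`EchoTimes` sidecar (ms).
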