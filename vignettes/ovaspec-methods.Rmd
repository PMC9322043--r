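---
title: "Methods: hyperspectral calibration and mapping of egg S-ovalbumin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral calibration and mapping of egg S-ovalbumin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

S-ovalbumin is the thermostable form into which egg-white ovalbumin
converts irreversibly during storage; its share of total ovalbumin is a
freshness index that matters to food processors because it weakens
heat-induced albumen gels. The reference assay is destructive wet
chemistry: heat an albumen suspension, measure soluble-protein
absorbance before and after, and report
`100 * O_heated / O_unheated` percent. `ovaspec` implements a
non-destructive alternative: visible/near-infrared hyperspectral
*transmittance* imaging of intact eggs, calibrated against that assay,
down to per-pixel concentration maps.

The package covers the whole chain: cube calibration, region-of-interest
(ROI) spectra, scatter correction, sample partitioning, two regression
families, wavelength selection, and chemical mapping — plus a seeded
synthetic-data generator so every stage is testable without instrument
data.

## Pipeline stages and their models

### Cube calibration

Raw counts are converted to transmittance with white (~99% transmittance
board) and dark (covered lens) references:
`T = (I_o - I_d) / (I_w - I_d)`. Voxels where `|I_w - I_d| < eps`
(default `1e-6`) are set to 0 and counted in a message, keeping cubes
finite for downstream algebra.

### ROI and spectra

The egg is segmented by thresholding the single band nearest 700.4 nm
(a high-transmission band) at transmittance 0.1, with a strict `>` so an
all-background image unambiguously raises an error. No interpolation and
no morphological cleanup: plain thresholding suffices at the
transmittance contrast the study design produces (ROI ≈ 0.4–1.0 vs
background ≈ 0.005). The ROI's per-band pixel mean is the sample
spectrum. Bands below 435 nm are discarded for poor signal-to-noise; on
the nominal 478-band grid this leaves exactly 449 effective bands.
Because a per-band mean commutes with band selection, cropping before or
after the mean is equivalent; the package crops last.

### SNV and SPXY

Standard normal variate (SNV) standardises each spectrum by its own mean
and sample standard deviation (n − 1 denominator), removing per-sample
multiplicative scatter and additive offsets; constant spectra raise a
dedicated error. Samples are split 2/3 : 1/3 into calibration and
prediction sets by SPXY: joint distance
`d = d_X / max(d_X) + d_y / max(d_y)`, seeded with the maximally distant
pair and grown greedily by max–min distance. Ties break to the lowest
sample index so the split is reproducible. SPXY runs on the
SNV-corrected spectra (the modelling input); a configuration switch is
not exposed because the alternative changes nothing structural. The
calibration size is `round(2n/3)`, giving 120/60 at n = 180.

### PLSR

Partial least squares regression is implemented as the classical
deflation loop on internally mean-centered data: loading weights
`w = X'y` (normalised), scores `s = Xw`, loadings `p = X's/s's`,
`q = y's/s's`, deflation `X <- X - sp'`, `y <- y - sq`, repeated for
each latent variable; coefficients `b = W (P'W)^{-1} Q`. Mean-centering
is required for the deflation algebra to be meaningful even though
textbook listings often leave it implicit. The coefficient orientation
is fixed by an oracle property: at `h = rank(X)` with `n > p` the PLSR
coefficients must equal ordinary least squares (the package tests this
to `1e-6` on random instances). The number of latent variables is chosen
by five-fold RMSECV with a 2% plateau rule: the smallest `h` whose
RMSECV is within 2% of the trace minimum — a concrete encoding of "the
decrease is no longer significant". Search range defaults to 1–16.

### LSSVM

The least-squares SVM replaces inequality constraints with equalities
and quadratic programming with one linear KKT system:
`[[0, 1'], [1, K + I/gamma]] [b; alpha] = [0; y]`, with RBF kernel
`K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`. One step of iterative
refinement pushes the KKT residual to solver precision (tested at
`1e-8`). The response is standardised internally and predictions
unscaled, so the `gamma` grid has data-independent meaning.
Hyperparameters are searched in `(log2 gamma, log2 1/sigma^2)` over
`[-8, 8]^2`: a step-1.0 coarse grid (289 points) then a step-0.1 fine
grid within ±1.0 of the coarse optimum, objective five-fold RMSECV with
a fold assignment fixed per search. The 0.1 fine step matches the
resolution at which such optima are conventionally reported.

### CARS

Competitive adaptive reweighted sampling runs `N = 100` Monte-Carlo
iterations. Each iteration fits a PLS model to a random 80% of the
calibration samples on the currently retained wavelengths and weights
each wavelength by `|b|`. The exponentially decreasing function (EDF)
`r_i = a e^{-k i}` with `r_1 = 1` and `r_N = 2/p` caps the retained
count (keeping top weights); adaptive reweighted sampling (ARS) then
draws `p` times with replacement, probability proportional to `|b|`,
and keeps wavelengths drawn at least once. Drawing `p` times (the
original variable count) rather than the current retained count is the
canonical convention: it produces the characteristic two-phase trace —
fast selection early, refined selection late — and lets the trace reach
the EDF floor of 2, whereas a draw count tied to the shrinking retained
set compounds a ~(1 − 1/e) cut per run and collapses the set within
~15 runs. Per-run subset models choose latent variables by internal
five-fold cross-validation with the same 2% plateau rule, capped at
`min(10, n_retained, n_mc - 1)` to keep tiny subsets from overfitting.
The recorded RMSECV is computed on the full calibration set with a fold
assignment fixed across runs so the trace is comparable; the subset from
the minimum-RMSECV run wins. Wavelengths with `|b| = 0` get selection
probability 0.

### Chemical maps

The fitted (simplified LSSVM by default) model is applied to every ROI
pixel: the pixel spectrum is cropped to the 449-band effective range,
SNV-corrected **on the full cropped range**, then subset to the feature
wavelengths, predicted, and clipped to [0, 100]%. SNV-before-subset
matches exactly how the training spectra were produced; this ordering is
recorded prominently because it means a future multispectral instrument
with only the selected bands would still need full-range SNV or a
recalibrated model. Maps share a global [0, 100]% linear colour range so
eggs at different storage days are directly comparable; low content
renders blue, high content red, background neutral. `render_map()`
writes the PNG as a computed RGB array (device-free, deterministic) with
a linear colour-bar strip; `autoplot()` is the ggplot2 counterpart.

## The synthetic-data generator

No public hyperspectral egg dataset accompanies the underlying study
design, so the generator emulates the statistical structure the pipeline
assumes, and its defaults *are* the study conditions:

- **Design**: 18 eggs per storage day at days 0, 3, …, 27 — 180 eggs.
- **Storage curve**: expected S-ovalbumin fraction follows a logistic
  `L + (U-L)/(1 + exp(-k(d-m)))` with `L = 0.11`, `U = 0.95`,
  `k = 0.25`/day, `m = 12` days: monotone, spanning ≈ 11–94% as a
  full-study reference range. Only the monotone trend and range are
  claimed; the exact curve is a surrogate.
- **Egg-to-egg jitter**: Gaussian SD 0.04 on the content fraction,
  clipped to [0.10, 0.95] — wide enough that day groups overlap as real
  biological replicates do.
- **Spectra**: `T = g B(λ) exp(-[a0(λ) + c a1(λ)]) + o + ε`, with static
  absorption lobes at 589/643/750/970 nm (eggshell pigment and O-H
  overtones), content-dependent lobes at 700/740/870/960 nm plus a broad
  term (so mean transmittance decreases with content), per-egg scatter
  gain `g ~ N(1, 0.08)` (clipped [0.8, 1.2]) and offset
  `o ~ N(0, 0.01)` — exactly the distortion family SNV removes — and
  band noise SD 0.005.
- **Reference assay**: relative noise CV 0.03 (the true assay error is
  unpublished; this is a configurable stand-in).
- **Cubes**: 64 × 64 pixels by default; elliptical egg on a dark
  background (background transmittance ≈ 0.005), pixel-level content
  heterogeneity as a smooth cosine-mode random field (SD 0.02) so maps
  are visibly uneven while the egg mean stays at its true content; raw
  counts reconstructed against smooth white (~3000 counts) and dark
  (~100 counts) profiles with sensor noise SD 2 counts.

What the generator does **not** emulate: shell-thickness optics, yolk
geometry, detector nonlinearity, wavelength miscalibration, stray light,
or any covariance between scatter and content. Passing tests therefore
demonstrate that the algorithms are implemented correctly and that the
pipeline recovers known structure under realistic noise — not that the
specific accuracy figures transfer to real eggs. In particular the
synthetic problem is *easier* than the real one (prediction R² near
0.99 at the defaults), because the content signal enters the spectra
noiselessly through a low-dimensional model.

## Numerical choices

- PLSR aborts with a rank-deficiency error naming the offending
  component when a deflated `X` carries no variance; weight vectors are
  normalised so `||w|| = 1`.
- RMSE uses the `n` denominator throughout (`sqrt(mean((ŷ - y)^2))`).
- Cross-validation folds are a seeded uniform shuffle with near-equal
  sizes; `k = n` reproduces leave-one-out exactly.
- SPXY and CARS tie-breaks go to the lowest index; all stochastic steps
  take explicit seeds, and the pipeline derives every internal seed from
  the design seed, so reruns are bit-identical.
- ENVI payloads are 32-bit little-endian floats (BIL written; BIL/BSQ/
  BIP read); wavelengths are written at `%.17g` so they round-trip
  exactly, while data round-trips exactly from the second write onward
  (the first write quantises doubles to float32).
- Model containers are single JSON files holding every model field at
  full precision plus preprocessing state (wavelength subset, SNV flag).

## Problem sizes

The bundled tests exercise a 16-egg, 24 × 24-pixel study for unit-level
checks and one full 180-egg, 64 × 64 × 478 study for the end-to-end
property checks; the acceptance script reruns the full study from a
caller-supplied seed. These sizes were chosen as the smallest at which
every claimed property is informative — ROI statistics stabilise above
~200 ROI pixels, and SPXY's 120/60 split needs the full 180.

## Known limitations

- The generator's content–absorbance link is linear in the exponent; a
  strongly nonlinear real relationship would favour LSSVM over PLSR more
  than the synthetic benchmark shows.
- CARS selections on highly collinear synthetic spectra are stable in
  count but not in identity across seeds; neighbouring bands carry
  nearly identical information, so different runs may pick different
  representatives of the same absorption feature.
- One egg per frame; no geometric calibration or dead-pixel handling.
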