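---
title: "Methods: label-free dual-modality cell profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free dual-modality cell profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opticyte)
```

# Scope and model

`opticyte` implements two independent measurement arms for label-free
single-cell profiling, plus the synthetic-data generator that makes both
testable against analytic ground truth.

## Quantitative-phase arm

An off-axis interferogram is modelled as
$I(x,y) = A + B\cos(2\pi \mathbf{k}\cdot\mathbf{r} + \varphi(x,y))$ with
carrier $\mathbf{k}$ in cycles/pixel. In a double-pass reflection geometry
the phase is
$\varphi = 2\int \tfrac{2\pi}{\lambda}(n_\mathrm{cell}-n_\mathrm{medium})\,dz$;
the factor 2 is **never** divided out of the phase map. Instead, dry mass
uses the $4\pi$ denominator,
$m = \tfrac{1}{\alpha}\iint_S \tfrac{\lambda}{4\pi}\varphi\,dx\,dy$, so the
measured phase is consumed exactly as recorded. Matter density is $m$
divided by the projected segmented area — the area as thresholded, not a
convex hull.

Assumptions: the specimen is thin and transparent (pure phase object), the
carrier separates the interference sidebands from DC, and the instrumental
background is dominated by tilt and offset (a first-order plane). Higher
acquisition physics — speckle statistics, partial coherence, the
interferometer layout — is out of scope: only the demodulatable fringe
image matters downstream.

## Raman arm

Preprocessing order is fixed: fingerprint restriction (600–1800 cm$^{-1}$),
fluorescence-baseline removal, SNV standardization. The order matters —
the baseline must be estimated on raw counts, and PCA consumes the SNV
representation. PCA uses column mean-centring only: SNV already
standardizes each spectrum, and no further scaling is applied. Band
intensities are window means (half-width 5 cm$^{-1}$) on the SNV spectra,
i.e. on the pipeline's terminal representation.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pixel_size` | 0.1 | µm/px | consistent with a 60×/1.0 NA objective |
| `image_size` | 512 | px | comfortably holds one fibroblast-sized cell |
| `wavelength` | 0.8 | µm | Ti:sapphire centre wavelength; the ~17 nm bandwidth is ignored (a single λ enters the mass relation) |
| `carrier_frequency` | (0.25, 0) | cycles/px | mid-band: sidebands well clear of DC and of Nyquist; validated to (0.1, 0.4) magnitude |
| `alpha` | 0.185 | µm³/pg | standard specific refractive increment of cellular dry matter |
| segmentation threshold | 0.2 | rad | phase level separating cell from medium background |
| `min_pixels` | 50 | px | rejects noise specks below any plausible cell fragment |
| baseline degree | 4 | — | polynomial order of the fluorescence background model |
| band half-width | 5 | cm⁻¹ | covers a marker band core without its neighbours |
| `n_components` | 3 | — | the factors with maximum variance contribution used for discrimination |

# The synthetic generator: what it emulates, what it does not

**Phantoms.** Cells are radially symmetric phase profiles (uniform disk,
raised-cosine disk, truncated Gaussian cap) whose phase integral — and
hence dry mass — has a closed form. This gives every downstream stage an
exact oracle. Real cells are neither symmetric nor smooth; passing the
recovery tests demonstrates the *computational* chain (demodulation,
unwrapping, background removal, Eq.-style densitometry) is correct, not
that segmentation at 0.2 rad captures a real cell's diffuse boundary.
Phantoms used for ground-truth mass comparisons exceed the threshold over
essentially their whole support, so rim truncation is negligible; for
real morphologies the sub-threshold rim is silently excluded from the
mass integral, and that budget is not modelled here.

**Dose structure.** The QPI cohorts default to mean dry masses of 300,
240, 190, 160 pg (control → T200) with 20 pg between-cell SD and 10 cells
per group — a monotone decreasing dose response with effect sizes that
make Welch tests against control decisive at this n. (Experimental data
of this kind can show a slight uptick in the heaviest-dose group caused
by debris and diffuse boundaries inflating the phase integral; the
generator models the underlying monotone trend, not that measurement
artifact.) The Raman groups share all band amplitudes except the two
apoptosis markers: 1584 cm$^{-1}$ rises strictly with dose
(0.30/0.45/0.60/0.75), and 1000 cm$^{-1}$ rises through T100 then falls
back in T200, mimicking the signal-to-noise loss typical of heavily
stressed cells. 15 spectra per group reflect a 3-repeat × 5-cell design.

**Noise.** Additive Gaussian noise (default) keeps the oracles simple; a
Poisson shot-noise option exists since both occur in CCD imaging. Raman
noise is i.i.d. Gaussian per point — no cosmic-ray spikes, detector etalon
fringes or wavenumber-calibration drift, so the preprocessing tests say
nothing about robustness to those.

**Line shapes.** Lorentzian by default (the physically conventional Raman
line shape), Gaussian selectable. The baseline is a degree-4 polynomial in
a normalized abscissa $u = (\tilde\nu - 1200)/600$ to keep coefficients
of comparable magnitude.

# Numerical choices

* **Carrier estimation** takes the strongest non-DC Fourier peak
  (bin-quantized), requiring it to exceed 3× the median off-DC spectral
  magnitude; sign fixed to the half-plane with positive first component.
* **Sideband window**: circular top-hat of radius half the carrier
  magnitude (so it can never reach DC), with an optional raised-cosine
  taper. Hard windows cause mild ringing at sharp phase edges — visible as
  an RMSE floor of a few hundredths of a radian for discontinuous (uniform
  disk) phantoms, versus ~2 mrad for smooth caps. A residual sub-bin
  carrier mismatch appears as a linear phase tilt and is absorbed by the
  background plane fit.
* **Unwrapping** defaults to the unweighted least-squares (Poisson/DCT)
  solver: it is fully vectorized, exact whenever the wrapped gradients are
  consistent (true neighbouring differences below π), and degrades
  gracefully under noise; an Itoh row/column path-following variant is
  available for comparison. A quality-guided flood fill was considered and
  rejected: per-pixel priority-queue traversal is slow in interpreted code
  and offers no accuracy benefit on smooth cell-like phases at the noise
  levels in scope. Both methods re-anchor their output so it agrees with
  the input modulo 2π (circular-mean constant, then the nearest global 2π
  multiple) and an already-continuous input passes through unchanged.
* **Background model**: least-squares plane on a cell-free region; in
  `auto` mode, the pixels whose residual after a whole-image plane fit sits
  below the 20th percentile. After subtraction the background median is
  forced to zero. Higher-order backgrounds are deliberately not fitted —
  they risk eating cell phase.
* **Baseline removal** is the iterative clipped polynomial fit: fit,
  replace points above the fit by the fit value, repeat until the fit
  moves less than `tol` (default 10⁻⁶ of the intensity range) or
  `max_iter` (100). Plain least squares would subtract part of every
  peak; clipping makes the fit hug the band-free background. The clipping
  ratchet biases the converged baseline slightly low far from bands, so
  band areas are meaningfully compared over a window around the band
  centre rather than over the whole axis; the broad residual offset is
  irrelevant after SNV.
* **Segmentation** uses strictly-greater-than thresholding and 4-connected
  labelling (delegated to `EBImage::bwlabel`), components sorted by area
  descending; interior holes are kept open by default (hole-filling is a
  flag) since the threshold definition says nothing about filling.
* **PCA sign convention**: the largest-magnitude element of each loading
  is made positive, making loadings and scores reproducible across BLAS
  implementations.
* **Cluster separation** is reported as the mean silhouette width of the
  3-PC Euclidean configuration — a scatter plot needs a number before it
  can be asserted in a test; the silhouette is that number and is an
  artifact-internal choice.
* **Welch testing** compares each exposed group against control by
  default (all-pairs by flag); no multiple-testing correction is applied,
  matching the convention of reporting raw Welch p-values for a handful of
  planned comparisons.
* **Fluence** is exact unit arithmetic, `W/m² × min × 60 / 10⁴ = J/cm²`;
  a one-decimal reporting mode exists because dose tables are customarily
  quoted at that precision.
* **RMSE metrics** exclude a 5-pixel border (window edge effects).
* **Degenerate inputs**: zero-SD spectra are rejected by SNV; empty
  segmentations return an empty list, not an error; a negative dry mass
  (over-subtracted background) is returned as-is with a warning; a
  single-spectrum group reports SD 0 with a warning.

# Problem sizes

Unit and property tests run at 128²–256² pixels where the contracts are
already sharp; the dry-mass-relation check runs once at the default 512².
The end-to-end cohort checks use the default study conditions — 4 groups ×
10 cells at 512², 1% fringe noise, and 4 × 15 spectra at 1 cm$^{-1}$
spacing — which complete in well under a minute.

# Storage formats

Images travel as single-channel 32-bit float TIFF with a YAML sidecar
carrying wavelength, pixel size, group, ground-truth mass and the
normalization scale/offset (TIFF float storage is defined on [0, 1], so
images are min/max-normalized on write; the roundtrip is lossless to
float32 precision). Spectra and labels are plain CSV; configurations are
flat YAML with a mandatory `seed`.

# Known limitations

* No refractive-index tomography: dry mass conflates thickness and index
  by design; volume and height are not estimated.
* The generator's phantoms are single, centred, radially symmetric cells;
  overlapping or touching cells are out of scope (disjoint multi-phantom
  images segment fine).
* The baseline-removal interpretation (clipped iterative fitting) is one
  member of the modified-polyfit family; instrument-specific backgrounds
  (etaloning, quartz bands) may need a different model.
* PCA separation on synthetic data reflects the configured effect sizes;
  it is a correctness property of the pipeline, not evidence about any
  particular biological system.
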