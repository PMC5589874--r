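# opticyte

Label-free, dual-modality profiling of cultured cells in R: quantitative
phase imaging (QPI) for biophysical parameters, Raman microspectroscopy for
biochemical ones. The package targets studies of graded cellular stress —
the shipped defaults emulate skin fibroblasts exposed to time-bound UV
radiation (control, T50, T100, T200 exposure groups) — but every stage works
on any off-axis interferogram or single-cell Raman dataset.

## What it computes

**Quantitative-phase arm.** An off-axis hologram records
`I(x,y) = A + B cos(2π k·r + φ(x,y))`, where the phase delay in a
double-pass reflection geometry is

    φ(x,y) = 2 ∫ (2π/λ) [n_cell(x,y,z) − n_medium] dz .

The pipeline demodulates `I` by Fourier sideband filtering, unwraps the
phase (least-squares/DCT solver by default), removes the instrumental
tilt/offset plane, segments cells at a 0.2 rad threshold (4-connected
components) and converts integrated phase to **dry mass**

    m = (1/α) ∬_S (λ/4π) φ(x,y) dx dy ,

with α = 0.185 µm³/pg the specific refractive index increment of cellular
dry matter; the 4π denominator absorbs the double-pass factor 2. **Matter
density** is m divided by the projected cell area. Group differences are
tested with Welch's unequal-variance t test.

**Raman arm.** Spectra are restricted to the fingerprint region
(600–1800 cm⁻¹), the fluorescence background is removed by an iterative
clipped 4th-order polynomial fit, and each spectrum is standardized by the
standard normal variate (SNV) transform. Marker bands — notably
1000 cm⁻¹ (phenylalanine ring breathing) and 1584 cm⁻¹ (guanine/adenine
N–H bending), both apoptosis indicators — are quantified as window means,
and group discrimination uses PCA on the SNV spectra (first three
components, silhouette coefficient as the separation summary).

**Synthetic generator.** Radially symmetric cell phantoms have closed-form
phase integrals, so their dry mass is known exactly; they are embedded in
carrier-fringe interferograms with configurable noise. Raman spectra are
built from Lorentzian bands at the fingerprint marker positions on a
polynomial baseline, with the 1584 cm⁻¹ amplitude increasing with dose.
Every downstream stage is therefore testable against analytic ground truth
with no external data.

## Worked example

```r
library(opticyte)

## -- QPI arm: one synthetic cell through the full chain ----------------
cfg <- sim_config(seed = 1, image_size = 256, noise_sd = 0.01)
ph  <- cell_phantom(radius = 8, peak_phase = 1.2)   # uniform disk
ph
#> <cell_phantom> uniform_disk, R = 8 um, peak = 1.2 rad, mass = 83.03 pg
pm  <- make_phase_map(ph, cfg)
set.seed(1)
ig  <- make_interferogram(pm, cfg)                  # 1% fringe noise
rec <- subtract_background(unwrap_phase(reconstruct_phase(ig)))
mk  <- segment_cells(rec)[[1]]
dry_mass(rec, mk)
#> 83.95        # pg; phantom truth is 83.03 pg (1.1% error at 1% noise)
dry_mass(rec, mk) / mk$area
#> 0.4038       # matter density, pg/um^2

## -- Raman arm: four dose groups ---------------------------------------
ds   <- make_group_spectra(seed = 1)                # 4 x 15 spectra
proc <- preprocess_spectra(ds)                      # restrict -> baseline -> SNV
band_intensity_by_group(proc, 1584)
#>     group  n     mean         sd
#> 1 control 15 2.672820 0.06254198
#> 2     T50 15 3.375471 0.03258024
#> 3    T100 15 3.907058 0.04464598
#> 4    T200 15 4.794949 0.02985127   # strictly increasing with dose
res <- fit_pca(proc)
res
#> <pca_result> 3 components, explained: 32.7%, 5.2%, 1.9%
score_scatter_3d(res)$silhouette
#> 0.721        # well-separated clusters in 3-PC space

## -- dosimetry ----------------------------------------------------------
fluence(1.02, c(50, 100, 200), round_to = 1)
#> [1] 0.3 0.6 1.2   # J/cm^2 for the three exposure times
```

The band-intensity means rise strictly with dose because the generator's
1584 cm⁻¹ amplitudes do — the configured composition is the oracle the
pipeline is checked against. The silhouette of 0.72 summarizes how cleanly
the four groups separate in the 3-PC score space.

A complete run (viability curve, biophysics bars with Welch annotations,
mean spectra, band bars, PC scatter, Markdown report, run manifest):

```r
run_all(system.file("extdata", "default_config.yml", package = "opticyte"),
        "results_run")
```

or from a shell via the thin wrapper `inst/cli/opticyte-run`.

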