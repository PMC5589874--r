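Package: opticyte
Title: Label-Free Single-Cell Profiling with Quantitative Phase Imaging
    and Raman Microspectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dual-modality, label-free profiling of cultured
    cells. The quantitative-phase arm demodulates off-axis interferograms
    by Fourier sideband filtering, unwraps and background-corrects the
    phase map, segments cells by phase thresholding and computes per-cell
    dry mass and matter density from the integrated optical path delay.
    The Raman arm restricts spectra to the fingerprint region, removes
    fluorescence background by iterative polynomial fitting, applies
    standard normal variate scaling, quantifies marker band intensities
    and discriminates exposure groups by principal component analysis
    with Welch two-sample testing. A synthetic-data generator produces
    phantom interferograms with analytically known dry mass and
    dose-structured Raman spectra so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    EBImage,
    grDevices,
    graphics,
    lattice,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
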