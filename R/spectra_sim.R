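#' Spectral composition of one exposure group
#'
#' Describes how synthetic Raman spectra for one dose group are built: a sum
#' of line-shaped bands on a smooth degree-4 polynomial fluorescence
#' baseline, plus Gaussian noise. Band centres default to the fingerprint
#' markers of cultured fibroblasts: nucleic acids (720, 1093, 1340,
#' 1576 cm^-1), phenylalanine/proteins (1000, 1004 cm^-1), tyrosine
#' (835 cm^-1), CH2 deformation of lipids/proteins (1440 cm^-1), guanine/
#' adenine N-H bending (1584 cm^-1) and amide I (1660 cm^-1).
#'
#' @param group group label (one of [dose_groups()] by convention).
#' @param band_centers band centres, cm^-1; must include the ten default
#'   markers.
#' @param band_amplitudes peak amplitudes (arbitrary units, all >= 0), one
#'   per band.
#' @param band_widths half width at half maximum per band, cm^-1 (recycled).
#' @param baseline_coeffs degree-4 polynomial coefficients (constant first)
#'   of the fluorescence baseline, evaluated in a normalized coordinate
#'   `u = (wavenumber - 1200) / 600` so the magnitudes stay comparable.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param n_spectra number of spectra to draw for the group.
#' @return A `spectral_group_spec` object.
#' @export
spectral_group_spec <- function(group,
                                band_centers = marker_bands(),
                                band_amplitudes,
                                band_widths = 8,
                                baseline_coeffs = c(2, -0.5, 0.8, 0.1, -0.3),
                                noise_sd = 0.02,
                                n_spectra = 15L) {
  stopifnot(length(band_amplitudes) == length(band_centers),
            all(band_amplitudes >= 0),
            length(baseline_coeffs) == 5L, noise_sd >= 0, n_spectra >= 1L)
  missing_bands <- setdiff(marker_bands(), band_centers)
  if (length(missing_bands) > 0L)
    stop("band_centers must include the marker bands: missing ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  structure(list(group = group,
                 band_centers = as.numeric(band_centers),
                 band_amplitudes = as.numeric(band_amplitudes),
                 band_widths = rep_len(as.numeric(band_widths),
                                       length(band_centers)),
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sd = noise_sd,
                 n_spectra = as.integer(n_spectra)),
            class = "spectral_group_spec")
}

#' Fingerprint marker bands
#'
#' The minimum set of band centres every synthetic group carries, cm^-1.
#' @return Numeric vector of ten wavenumbers.
#' @export
marker_bands <- function() {
  c(720, 835, 1000, 1004, 1093, 1340, 1440, 1576, 1584, 1660)
}

#' Default four-group spectral composition
#'
#' Emulates the dose response seen in UV-exposed fibroblasts: the apoptosis
#' markers at 1000 cm^-1 (phenylalanine ring breathing) and 1584 cm^-1
#' (guanine/adenine N-H bending) gain intensity with exposure. The
#' 1584 cm^-1 amplitude increases strictly with dose across control, T50,
#' T100, T200; the 1000 cm^-1 amplitude rises through T100 and falls back in
#' T200 (mimicking the signal-to-noise loss reported for heavily exposed
#' cells). All other bands are dose-invariant.
#'
#' @param noise_sd per-point Gaussian noise SD (shared by all groups).
#' @param n_spectra spectra per group (default 15: 3 repeats x 5 cells).
#' @param monotone_1000 if `TRUE`, make the 1000 cm^-1 amplitude strictly
#'   increasing as well (useful when a fully monotone configuration is the
#'   test oracle).
#' @return Named list of [spectral_group_spec()]s in dose order.
#' @export
default_group_specs <- function(noise_sd = 0.02, n_spectra = 15L,
                                monotone_1000 = FALSE) {
  base_amp <- c(`720` = 0.30, `835` = 0.25, `1000` = 0.35, `1004` = 0.50,
                `1093` = 0.30, `1340` = 0.35, `1440` = 0.60, `1576` = 0.30,
                `1584` = 0.30, `1660` = 0.55)
  amp1584 <- c(control = 0.30, T50 = 0.45, T100 = 0.60, T200 = 0.75)
  amp1000 <- if (monotone_1000)
    c(control = 0.35, T50 = 0.45, T100 = 0.55, T200 = 0.65)
  else
    c(control = 0.35, T50 = 0.45, T100 = 0.55, T200 = 0.40)
  out <- lapply(dose_groups(), function(g) {
    amp <- base_amp
    amp["1584"] <- amp1584[[g]]
    amp["1000"] <- amp1000[[g]]
    spectral_group_spec(group = g, band_amplitudes = unname(amp),
                        noise_sd = noise_sd, n_spectra = n_spectra)
  })
  names(out) <- dose_groups()
  out
}

#' Default wavenumber axis
#'
#' Fingerprint-region grid, 600 to 1800 cm^-1 in 1 cm^-1 steps.
#' @return Numeric vector.
#' @export
default_axis <- function() seq(600, 1800, by = 1)

#' Simulate Raman spectra for one group
#'
#' Each spectrum is the sum of the group's bands (Lorentzian line shapes by
#' default, Gaussian selectable), the degree-4 polynomial baseline and
#' i.i.d. Gaussian noise. The same seed always yields the identical dataset.
#'
#' @param spec a [spectral_group_spec()].
#' @param axis wavenumber grid, cm^-1; must cover every band centre of
#'   `spec`.
#' @param seed integer seed for the noise draw.
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @return A [spectral_dataset()] with `spec$n_spectra` rows.
#' @examples
#' gs <- default_group_specs()$control
#' ds <- make_spectra(gs, default_axis(), seed = 1)
#' dim(ds$matrix)
#' @export
make_spectra <- function(spec, axis = default_axis(), seed,
                         lineshape = c("lorentzian", "gaussian")) {
  stopifnot(inherits(spec, "spectral_group_spec"))
  lineshape <- match.arg(lineshape)
  axis <- as.numeric(axis)
  outside <- spec$band_centers < min(axis) | spec$band_centers > max(axis)
  if (any(outside))
    stop("axis does not cover band centre(s): ",
         paste(spec$band_centers[outside], collapse = ", "), call. = FALSE)
  template <- spectrum_template(spec, axis, lineshape)
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(spec$n_spectra * length(axis),
                               sd = spec$noise_sd),
                  spec$n_spectra, length(axis))
  mat <- matrix(template, spec$n_spectra, length(axis), byrow = TRUE) + noise
  spectral_dataset(mat, axis, rep(spec$group, spec$n_spectra),
                   cell_ids = paste0(spec$group, "_", seq_len(spec$n_spectra)))
}

# noiseless spectrum of a group: bands + baseline
spectrum_template <- function(spec, axis, lineshape = "lorentzian") {
  u <- (axis - 1200) / 600
  base <- drop(cbind(1, u, u^2, u^3, u^4) %*% spec$baseline_coeffs)
  bands <- numeric(length(axis))
  for (i in seq_along(spec$band_centers)) {
    d <- axis - spec$band_centers[i]
    w <- spec$band_widths[i]
    bands <- bands + spec$band_amplitudes[i] *
      if (lineshape == "lorentzian") w^2 / (d^2 + w^2)
      else exp(-d^2 / (2 * (w / sqrt(2 * log(2)))^2))
  }
  base + bands
}

#' Simulate all four dose groups into one dataset
#'
#' @param specs list of [spectral_group_spec()]s (default
#'   [default_group_specs()]).
#' @param axis shared wavenumber grid.
#' @param seed master seed; each group uses `seed + group index` so groups
#'   are independent yet reproducible.
#' @param lineshape passed to [make_spectra()].
#' @return A combined [spectral_dataset()].
#' @export
make_group_spectra <- function(specs = default_group_specs(),
                               axis = default_axis(), seed = 1L,
                               lineshape = "lorentzian") {
  sets <- lapply(seq_along(specs), function(i)
    make_spectra(specs[[i]], axis, seed = as.integer(seed) + i,
                 lineshape = lineshape))
  spectral_dataset(do.call(rbind, lapply(sets, `[[`, "matrix")),
                   axis,
                   unlist(lapply(sets, `[[`, "labels")),
                   unlist(lapply(sets, `[[`, "cell_ids")))
}

#' Simulate a resazurin viability plate table
#'
#' Emulates a dye-reduction survival assay read at two wavelengths: sample
#' wells carry the resorufin absorbance at 570 nm, blank wells (reagent in
#' medium, no cells) carry the 600 nm background. The configured mean
#' corrected absorbance strictly decreases with exposure time, emulating the
#' loss of metabolic activity with dose.
#'
#' @param mean_corrected named numeric vector of configured mean corrected
#'   absorbances per group, in dose order; must be positive and strictly
#'   decreasing.
#' @param blank_a600 mean blank absorbance at 600 nm.
#' @param noise_sd replicate noise SD (absorbance units); 0 gives exact
#'   configured means.
#' @param n_replicates sample replicates per group.
#' @param seed integer seed.
#' @return A data.frame with columns `well_type` ("sample"/"blank"),
#'   `group`, `exposure_min`, `replicate`, `a570`, `a600`.
#' @export
make_viability_table <- function(mean_corrected = c(control = 0.85, T50 = 0.62,
                                                    T100 = 0.45, T200 = 0.30),
                                 blank_a600 = 0.10, noise_sd = 0.015,
                                 n_replicates = 3L, seed = 1L) {
  if (any(mean_corrected < 0) || blank_a600 < 0)
    stop("configured absorbances must be non-negative", call. = FALSE)
  if (any(diff(mean_corrected) >= 0))
    stop("mean corrected absorbance must strictly decrease with dose",
         call. = FALSE)
  groups <- names(mean_corrected)
  minutes <- c(control = 0, T50 = 50, T100 = 100, T200 = 200)[groups]
  set.seed(as.integer(seed))
  rows <- lapply(seq_along(groups), function(i) {
    a570 <- unname(mean_corrected[i]) + blank_a600 +
      stats::rnorm(n_replicates, sd = noise_sd)
    data.frame(well_type = "sample", group = groups[i],
               exposure_min = unname(minutes[i]),
               replicate = seq_len(n_replicates),
               a570 = pmax(a570, 0), a600 = NA_real_)
  })
  blanks <- data.frame(well_type = "blank", group = "blank",
                       exposure_min = NA_real_,
                       replicate = seq_len(n_replicates),
                       a570 = NA_real_,
                       a600 = pmax(blank_a600 +
                                     stats::rnorm(n_replicates, sd = noise_sd),
                                   0))
  out <- rbind(do.call(rbind, rows), blanks)
  rownames(out) <- NULL
  out
}
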