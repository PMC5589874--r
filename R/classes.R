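#' Phase map
#'
#' A 2-D optical phase image in radians, as measured in a double-pass
#' reflection geometry: phi(x, y) = 2 * integral (2 pi / lambda)
#' (n_cell - n_medium) dz. The factor 2 from the double pass is never divided
#' out; downstream densitometry compensates by using 4 pi (not 2 pi) in the
#' denominator of the mass relation.
#'
#' @param phase numeric matrix, radians; must be finite everywhere.
#' @param pixel_size lateral sampling, um/pixel.
#' @param wavelength illumination wavelength, um.
#' @param background_corrected logical flag: has the instrumental background
#'   (tilt + offset) been removed?
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(phase, pixel_size, wavelength,
                      background_corrected = FALSE) {
  stopifnot(is.matrix(phase), is.numeric(phase))
  if (!all(is.finite(phase))) stop("phase must be finite everywhere")
  stopifnot(pixel_size > 0, wavelength > 0)
  structure(list(phase = phase, pixel_size = pixel_size,
                 wavelength = wavelength,
                 background_corrected = isTRUE(background_corrected)),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px @ %.3g um/px, range [%.3g, %.3g] rad%s\n",
              nrow(x$phase), ncol(x$phase), x$pixel_size,
              min(x$phase), max(x$phase),
              if (x$background_corrected) ", background-corrected" else ""))
  invisible(x)
}

#' Off-axis interferogram
#'
#' A raw fringe-intensity image I = A + B cos(2 pi k . r + phi) (+ noise),
#' where k is the spatial carrier introduced by the off-axis reference beam.
#'
#' @param intensity non-negative numeric matrix.
#' @param pixel_size lateral sampling, um/pixel.
#' @param wavelength illumination wavelength, um.
#' @param carrier_hint optional length-2 carrier frequency (cycles/pixel)
#'   known from the simulation or a prior estimate.
#' @return An object of class `interferogram`.
#' @export
interferogram <- function(intensity, pixel_size, wavelength,
                          carrier_hint = NULL) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (!all(is.finite(intensity)) || any(intensity < 0))
    stop("intensity must be finite and non-negative")
  stopifnot(pixel_size > 0, wavelength > 0)
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 wavelength = wavelength,
                 carrier_hint = if (is.null(carrier_hint)) NULL
                                else as.numeric(carrier_hint)),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d x %d px @ %.3g um/px, lambda = %.3g um\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size, x$wavelength))
  invisible(x)
}

#' Single Raman spectrum
#'
#' @param wavenumber strictly increasing grid, cm^-1.
#' @param intensity intensities (arbitrary counts), same length as the grid.
#' @param group exposure-group label.
#' @param cell_id identifier of the measured cell.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, group = NA_character_,
                           cell_id = NA_character_) {
  stopifnot(length(wavenumber) == length(intensity),
            all(is.finite(wavenumber)), all(is.finite(intensity)))
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber grid must be strictly increasing")
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity),
                 group = group, cell_id = cell_id),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.4g-%.4g cm^-1, group = %s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              as.character(x$group)))
  invisible(x)
}

#' Spectral dataset
#'
#' A set of Raman spectra sharing one wavenumber grid, stored spectrum-by-row,
#' with a group label per spectrum.
#'
#' @param matrix numeric matrix, spectra in rows.
#' @param axis shared wavenumber grid, cm^-1, strictly increasing, one entry
#'   per column.
#' @param labels group label per spectrum (length `nrow(matrix)`).
#' @param cell_ids optional per-spectrum identifiers.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(matrix, axis, labels, cell_ids = NULL) {
  stopifnot(is.matrix(matrix), ncol(matrix) == length(axis),
            nrow(matrix) == length(labels))
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  if (is.null(cell_ids)) cell_ids <- paste0("s", seq_len(nrow(matrix)))
  structure(list(matrix = matrix, axis = as.numeric(axis),
                 labels = as.character(labels),
                 cell_ids = as.character(cell_ids)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d points, groups: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(unique(x$labels), collapse = ", ")))
  invisible(x)
}

# iterate an operation on raman_spectrum over all rows of a dataset
dataset_map <- function(ds, f, ...) {
  rows <- lapply(seq_len(nrow(ds$matrix)), function(i) {
    f(raman_spectrum(ds$axis, ds$matrix[i, ], ds$labels[i], ds$cell_ids[i]), ...)
  })
  axis <- rows[[1]]$wavenumber
  spectral_dataset(do.call(rbind, lapply(rows, `[[`, "intensity")),
                   axis, ds$labels, ds$cell_ids)
}

#' Standard exposure-group labels in dose order
#'
#' Control first, then groups named by UV exposure time in minutes.
#' @return `c("control", "T50", "T100", "T200")`
#' @export
dose_groups <- function() c("control", "T50", "T100", "T200")
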