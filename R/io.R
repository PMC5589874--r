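#' Write an image with a YAML metadata sidecar
#'
#' Phase maps and interferograms are stored as single-channel 32-bit float
#' TIFF. Because TIFF float storage is defined for values in the unit
#' interval, the
#' image is min/max-normalized on write and the affine `scale`/`offset`
#' needed to undo the normalization is stored -- together with pixel size,
#' wavelength and any extra fields -- in a YAML sidecar `<file>.yml`. The
#' roundtrip is lossless to float32 precision.
#'
#' @param img a [phase_map()] or [interferogram()].
#' @param file output TIFF path; the sidecar is written to `<file>.yml`.
#' @param extra named list of additional metadata (e.g. group label,
#'   ground-truth mass).
#' @return `file`, invisibly.
#' @export
write_image <- function(img, file, extra = list()) {
  stopifnot(inherits(img, "phase_map") || inherits(img, "interferogram"))
  data <- if (inherits(img, "phase_map")) img$phase else img$intensity
  lo <- min(data); hi <- max(data)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((data - lo) / scale, file, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- c(list(
    kind = if (inherits(img, "phase_map")) "phase_map" else "interferogram",
    pixel_size_um = img$pixel_size,
    wavelength_um = img$wavelength,
    offset = lo, scale = scale
  ), extra)
  if (inherits(img, "phase_map"))
    meta$background_corrected <- img$background_corrected
  if (inherits(img, "interferogram") && !is.null(img$carrier_hint))
    meta$carrier_cycles_per_px <- as.numeric(img$carrier_hint)
  yaml::write_yaml(meta, paste0(file, ".yml"))
  invisible(file)
}

#' Read an image written by [write_image()]
#'
#' @param file TIFF path with a `<file>.yml` sidecar.
#' @return A [phase_map()] or [interferogram()], per the sidecar's `kind`,
#'   with the sidecar attached as attribute `"meta"`.
#' @export
read_image <- function(file) {
  side <- paste0(file, ".yml")
  if (!file.exists(side))
    stop("missing metadata sidecar: ", side, call. = FALSE)
  meta <- yaml::read_yaml(side)
  raw <- tiff::readTIFF(file)
  data <- raw * meta$scale + meta$offset
  out <- if (identical(meta$kind, "phase_map")) {
    phase_map(data, meta$pixel_size_um, meta$wavelength_um,
              isTRUE(meta$background_corrected))
  } else {
    interferogram(pmax(data, 0), meta$pixel_size_um, meta$wavelength_um,
                  carrier_hint = meta$carrier_cycles_per_px)
  }
  attr(out, "meta") <- meta
  out
}

#' Write a spectral dataset as CSV
#'
#' Spectra CSV: first column `wavenumber` (cm^-1), one column per spectrum
#' (named by cell id). Labels CSV: columns `cell_id`, `group`.
#'
#' @param ds a [spectral_dataset()].
#' @param file spectra CSV path.
#' @param labels_file labels CSV path (default `<file>` with a `_labels`
#'   suffix).
#' @return `file`, invisibly.
#' @export
write_spectra_csv <- function(ds, file,
                              labels_file = sub("(\\.csv)?$", "_labels.csv",
                                                file)) {
  stopifnot(inherits(ds, "spectral_dataset"))
  wide <- data.frame(wavenumber = ds$axis, t(ds$matrix),
                     check.names = FALSE)
  names(wide)[-1] <- ds$cell_ids
  utils::write.csv(wide, file, row.names = FALSE)
  utils::write.csv(data.frame(cell_id = ds$cell_ids, group = ds$labels),
                   labels_file, row.names = FALSE)
  invisible(file)
}

#' Read a spectral dataset from CSV
#'
#' @param file spectra CSV (wavenumber column + one column per spectrum).
#' @param labels_file labels CSV with columns `cell_id`, `group`.
#' @return A [spectral_dataset()].
#' @export
read_spectra_csv <- function(file,
                             labels_file = sub("(\\.csv)?$", "_labels.csv",
                                               file)) {
  wide <- utils::read.csv(file, check.names = FALSE)
  lab <- utils::read.csv(labels_file)
  ids <- names(wide)[-1]
  groups <- lab$group[match(ids, lab$cell_id)]
  if (any(is.na(groups)))
    stop("labels file is missing entries for: ",
         paste(ids[is.na(groups)], collapse = ", "), call. = FALSE)
  spectral_dataset(t(as.matrix(wide[, -1, drop = FALSE])), wide[[1]],
                   groups, cell_ids = ids)
}

#' Read a pipeline configuration file
#'
#' A flat YAML file; recognized keys mirror the arguments of [sim_config()]
#' plus the group-level simulation settings (`mass_means`, `mass_sd`,
#' `raman_noise_sd`, `spectra_per_group`, `viability_means`). `seed` is
#' mandatory.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set 'seed'", call. = FALSE)
  cfg
}
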