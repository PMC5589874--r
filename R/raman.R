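#' Restrict a spectrum to the fingerprint region
#'
#' Keeps the wavenumbers in `[lo, hi]` (inclusive), by default the
#' biomolecular fingerprint region 600-1800 cm^-1.
#'
#' @param s a [raman_spectrum()] or [spectral_dataset()].
#' @param lo,hi region bounds, cm^-1.
#' @return The clipped object, same class as the input.
#' @export
restrict_fingerprint <- function(s, lo = 600, hi = 1800) {
  UseMethod("restrict_fingerprint")
}

#' @export
restrict_fingerprint.raman_spectrum <- function(s, lo = 600, hi = 1800) {
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  if (!any(keep))
    stop("spectrum does not overlap the [", lo, ", ", hi, "] cm^-1 region",
         call. = FALSE)
  raman_spectrum(s$wavenumber[keep], s$intensity[keep], s$group, s$cell_id)
}

#' @export
restrict_fingerprint.spectral_dataset <- function(s, lo = 600, hi = 1800) {
  keep <- s$axis >= lo & s$axis <= hi
  if (!any(keep))
    stop("dataset does not overlap the [", lo, ", ", hi, "] cm^-1 region",
         call. = FALSE)
  spectral_dataset(s$matrix[, keep, drop = FALSE], s$axis[keep],
                   s$labels, s$cell_ids)
}

#' Remove the fluorescence baseline by iterative polynomial fitting
#'
#' Fits a polynomial of the given degree (default 4) to the spectrum,
#' replaces every point lying above the fit by the fit value, and repeats
#' until the fitted curve changes by less than `tol` (a fraction of the
#' intensity range) or `max_iter` is reached; the converged baseline is then
#' subtracted. The clipping step makes the fit hug the band-free background
#' rather than the peaks (the modified-polyfit approach); the output may go
#' slightly negative at the noise level.
#'
#' @param s a [raman_spectrum()] or [spectral_dataset()].
#' @param degree polynomial degree.
#' @param max_iter maximum clipping iterations.
#' @param tol convergence tolerance as a fraction of the input intensity
#'   range.
#' @return Baseline-subtracted object, same class as the input.
#' @export
remove_baseline <- function(s, degree = 4, max_iter = 100, tol = 1e-6) {
  UseMethod("remove_baseline")
}

#' @export
remove_baseline.raman_spectrum <- function(s, degree = 4, max_iter = 100,
                                           tol = 1e-6) {
  if (length(s$wavenumber) < degree + 2)
    stop("need at least degree + 2 points", call. = FALSE)
  base <- polyfit_clipped(s$wavenumber, s$intensity, degree, max_iter, tol)
  raman_spectrum(s$wavenumber, s$intensity - base, s$group, s$cell_id)
}

#' @export
remove_baseline.spectral_dataset <- function(s, degree = 4, max_iter = 100,
                                             tol = 1e-6) {
  dataset_map(s, remove_baseline, degree = degree, max_iter = max_iter,
              tol = tol)
}

# iterative-clipped polynomial baseline; returns the fitted baseline
polyfit_clipped <- function(x, y, degree, max_iter, tol) {
  rng <- diff(range(y))
  if (rng == 0) return(y)               # flat spectrum is its own baseline
  u <- (x - mean(x)) / (diff(range(x)) / 2)   # conditioned abscissa
  A <- stats::poly(u, degree, raw = FALSE)
  A <- cbind(1, A)
  yy <- y
  fit_old <- NULL
  for (it in seq_len(max_iter)) {
    fit <- drop(A %*% stats::.lm.fit(A, yy)$coefficients)
    yy <- pmin(yy, fit)
    if (!is.null(fit_old) && max(abs(fit - fit_old)) < tol * rng) break
    fit_old <- fit
  }
  fit
}

#' Standard normal variate scaling
#'
#' Per-spectrum standardization: subtract the mean and divide by the sample
#' standard deviation (n - 1 denominator). The output has mean 0 and SD 1;
#' applying it twice is a no-op.
#'
#' @param s a [raman_spectrum()] or [spectral_dataset()].
#' @return SNV-scaled object, same class as the input.
#' @export
snv <- function(s) UseMethod("snv")

#' @export
snv.raman_spectrum <- function(s) {
  sd_ <- stats::sd(s$intensity)
  if (!is.finite(sd_) || sd_ == 0)
    stop("constant spectrum: SNV undefined (zero standard deviation)",
         call. = FALSE)
  raman_spectrum(s$wavenumber, (s$intensity - mean(s$intensity)) / sd_,
                 s$group, s$cell_id)
}

#' @export
snv.spectral_dataset <- function(s) dataset_map(s, snv)

#' Full spectral preprocessing chain
#'
#' Fixed order: fingerprint restriction, then baseline removal, then SNV --
#' the background must be removed before standardization, and PCA consumes
#' the SNV-scaled result.
#'
#' @param ds a [spectral_dataset()].
#' @param lo,hi fingerprint bounds passed to [restrict_fingerprint()].
#' @param degree baseline polynomial degree.
#' @return Preprocessed [spectral_dataset()].
#' @export
preprocess_spectra <- function(ds, lo = 600, hi = 1800, degree = 4) {
  snv(remove_baseline(restrict_fingerprint(ds, lo, hi), degree = degree))
}

#' Mean intensity of a marker band
#'
#' Mean of the (preprocessed) intensity over the window
#' `center +/- half_width`.
#'
#' @param s a [raman_spectrum()].
#' @param center band centre, cm^-1.
#' @param half_width half window width, cm^-1.
#' @return Mean intensity over the window (scalar).
#' @export
band_intensity <- function(s, center, half_width = 5) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (center - half_width < min(s$wavenumber) ||
      center + half_width > max(s$wavenumber))
    stop("band window [", center - half_width, ", ", center + half_width,
         "] cm^-1 falls outside the spectral grid", call. = FALSE)
  win <- abs(s$wavenumber - center) <= half_width
  mean(s$intensity[win])
}

#' Per-group band intensity summary
#'
#' Band intensity per spectrum, then mean and sample SD per group, in dose
#' order.
#'
#' @param ds a preprocessed [spectral_dataset()].
#' @param center,half_width passed to [band_intensity()].
#' @param groups group ordering.
#' @return data.frame with columns `group`, `n`, `mean`, `sd`.
#' @export
band_intensity_by_group <- function(ds, center, half_width = 5,
                                    groups = dose_groups()) {
  vals <- vapply(seq_len(nrow(ds$matrix)), function(i)
    band_intensity(raman_spectrum(ds$axis, ds$matrix[i, ]), center,
                   half_width), numeric(1))
  present <- groups[groups %in% ds$labels]
  out <- do.call(rbind, lapply(present, function(g) {
    v <- vals[ds$labels == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  out$group <- factor(out$group, levels = groups)
  out
}

#' Group mean spectra with SD envelopes
#'
#' Pointwise mean and sample standard deviation per group. A group with a
#' single spectrum gets an SD of 0 with a warning.
#'
#' @param ds a [spectral_dataset()].
#' @param groups group ordering; only represented groups are returned.
#' @return Named list (by group) of lists with fields `axis`, `mean`, `sd`,
#'   `n`.
#' @export
group_mean_spectra <- function(ds, groups = dose_groups()) {
  stopifnot(inherits(ds, "spectral_dataset"))
  present <- groups[groups %in% ds$labels]
  if (length(present) == 0L) present <- unique(ds$labels)
  out <- lapply(present, function(g) {
    sub <- ds$matrix[ds$labels == g, , drop = FALSE]
    if (nrow(sub) == 1L) {
      warning("group '", g, "' has a single spectrum; SD reported as 0")
      sdv <- rep(0, ncol(sub))
    } else {
      sdv <- apply(sub, 2, stats::sd)
    }
    list(axis = ds$axis, mean = colMeans(sub), sd = sdv, n = nrow(sub))
  })
  names(out) <- present
  out
}

#' Resample a spectrum onto a reference grid
#'
#' Linear interpolation onto `axis`; used when spectra arrive on slightly
#' different grids and must share one axis before forming a dataset.
#'
#' @param s a [raman_spectrum()].
#' @param axis target grid, cm^-1, inside the range of `s`.
#' @return A [raman_spectrum()] on `axis`.
#' @export
resample_spectrum <- function(s, axis) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (min(axis) < min(s$wavenumber) || max(axis) > max(s$wavenumber))
    stop("target axis extends beyond the measured range", call. = FALSE)
  raman_spectrum(axis,
                 stats::approx(s$wavenumber, s$intensity, xout = axis)$y,
                 s$group, s$cell_id)
}
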