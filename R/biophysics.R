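#' Segment cells from a background-corrected phase map
#'
#' Cells are the 4-connected components of the pixels whose phase strictly
#' exceeds the threshold (default 0.2 rad). Components smaller than
#' `min_pixels` are discarded and the survivors are returned sorted by area,
#' largest first. Interior holes are kept open unless `fill_holes = TRUE`.
#'
#' @param pm a background-corrected [phase_map()].
#' @param threshold segmentation threshold, radians.
#' @param min_pixels minimum component size kept, pixels.
#' @param fill_holes fill interior holes of each component?
#' @return A list of `cell_mask` objects, each with fields `mask` (logical
#'   matrix), `n_pixels`, `area` (um^2, `n_pixels * pixel_size^2`) and
#'   `component_id`. Empty list if nothing survives.
#' @examples
#' cfg <- sim_config(seed = 1, image_size = 256)
#' pm <- make_phase_map(cell_phantom(radius = 6, peak_phase = 1), cfg)
#' length(segment_cells(pm))
#' @export
segment_cells <- function(pm, threshold = 0.2, min_pixels = 50L,
                          fill_holes = FALSE) {
  stopifnot(inherits(pm, "phase_map"))
  if (!pm$background_corrected)
    warning("segmenting a phase map that is not background-corrected")
  fg <- pm$phase > threshold
  if (!any(fg)) return(list())
  lab <- EBImage::bwlabel(fg * 1)
  if (fill_holes) lab <- EBImage::fillHull(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_pixels)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  out <- lapply(seq_along(keep), function(i) {
    mk <- matrix(lab == keep[i], nrow(pm$phase), ncol(pm$phase))
    structure(list(mask = mk, n_pixels = sizes[keep[i]],
                   area = sizes[keep[i]] * pm$pixel_size^2,
                   component_id = i),
              class = "cell_mask")
  })
  out
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> component %d: %d px, %.4g um^2\n",
              x$component_id, x$n_pixels, x$area))
  invisible(x)
}

#' Cell dry mass from integrated phase
#'
#' Dry mass from the phase integral over the segmented cell,
#' `m = lambda / (4 pi alpha) * sum(phi) * pixel_size^2`, in picograms.
#' The 4 pi (rather than 2 pi) denominator absorbs the factor 2 that the
#' double-pass reflection geometry puts into the measured phase, so the
#' phase map is used exactly as measured. `alpha` is the specific refractive
#' index increment (0.185 um^3/pg for typical cellular dry matter).
#'
#' A negative total (possible when the background was over-subtracted) is
#' returned as-is with a warning.
#'
#' @param pm a background-corrected [phase_map()].
#' @param mask a `cell_mask` from [segment_cells()], sharing the geometry of
#'   `pm`.
#' @param alpha specific refractive index increment, um^3/pg.
#' @return Dry mass, pg.
#' @examples
#' cfg <- sim_config(seed = 1, image_size = 256)
#' pm <- make_phase_map(cell_phantom(radius = 5.6419, peak_phase = 1), cfg)
#' mk <- segment_cells(pm)[[1]]
#' dry_mass(pm, mk)  # ~ 34.4 pg
#' @export
dry_mass <- function(pm, mask, alpha = 0.185) {
  stopifnot(inherits(pm, "phase_map"), inherits(mask, "cell_mask"),
            alpha > 0)
  if (!all(dim(mask$mask) == dim(pm$phase)))
    stop("phase map and mask geometries differ", call. = FALSE)
  m <- pm$wavelength / (4 * pi * alpha) *
    sum(pm$phase[mask$mask]) * pm$pixel_size^2
  if (m < 0)
    warning("negative dry mass (", format(m),
            " pg): background may be over-subtracted")
  m
}

#' Matter density of a cell record
#'
#' Dry mass normalized by the projected (segmented) cell area, pg/um^2.
#'
#' @param record a `cell_record` row or any list/data.frame with numeric
#'   fields `dry_mass` (pg) and `area` (um^2).
#' @return Matter density, pg/um^2.
#' @export
matter_density <- function(record) {
  if (any(record$area <= 0)) stop("area must be > 0", call. = FALSE)
  record$dry_mass / record$area
}

#' Build a per-cell record table from a phase map
#'
#' Convenience wrapper: segment, then compute dry mass and matter density per
#' component.
#'
#' @param pm a background-corrected [phase_map()].
#' @param group exposure-group label attached to every record.
#' @param image_id identifier of the source image.
#' @param threshold,min_pixels,alpha passed to [segment_cells()] and
#'   [dry_mass()].
#' @return A data.frame with one row per cell: `image_id`, `component_id`,
#'   `group`, `area_um2`, `dry_mass_pg`, `matter_density_pg_per_um2`.
#' @export
cell_records <- function(pm, group = NA_character_, image_id = NA_character_,
                         threshold = 0.2, min_pixels = 50L, alpha = 0.185) {
  masks <- segment_cells(pm, threshold = threshold, min_pixels = min_pixels)
  if (length(masks) == 0L)
    return(data.frame(image_id = character(), component_id = integer(),
                      group = character(), area_um2 = numeric(),
                      dry_mass_pg = numeric(),
                      matter_density_pg_per_um2 = numeric()))
  rows <- lapply(masks, function(mk) {
    m <- dry_mass(pm, mk, alpha = alpha)
    data.frame(image_id = image_id, component_id = mk$component_id,
               group = group, area_um2 = mk$area, dry_mass_pg = m,
               matter_density_pg_per_um2 = m / mk$area)
  })
  do.call(rbind, rows)
}

#' Per-group summary of biophysical parameters
#'
#' Mean and sample standard deviation (n - 1 denominator) of dry mass,
#' matter density and area per exposure group, in dose order (control, T50,
#' T100, T200; any other labels must not appear).
#'
#' @param records a data.frame of cell records as returned by
#'   [cell_records()] (columns `group`, `dry_mass_pg`, `area_um2`,
#'   `matter_density_pg_per_um2`).
#' @param groups group ordering; defaults to [dose_groups()].
#' @return A data.frame with one row per represented group and columns
#'   `group`, `n`, `<quantity>_mean`, `<quantity>_sd`.
#' @export
summarize_groups <- function(records, groups = dose_groups()) {
  unknown <- setdiff(unique(records$group), groups)
  if (length(unknown) > 0L)
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  present <- groups[groups %in% records$group]
  rows <- lapply(present, function(g) {
    r <- records[records$group == g, ]
    data.frame(group = g, n = nrow(r),
               dry_mass_mean = mean(r$dry_mass_pg),
               dry_mass_sd = stats::sd(r$dry_mass_pg),
               density_mean = mean(r$matter_density_pg_per_um2),
               density_sd = stats::sd(r$matter_density_pg_per_um2),
               area_mean = mean(r$area_um2),
               area_sd = stats::sd(r$area_um2))
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = groups)
  out
}
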