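#' Generate phantom cohorts with dose-structured dry mass
#'
#' Draws one uniform-disk phantom per synthetic cell, with per-cell dry mass
#' sampled from a Gaussian around the group mean and the disk's peak phase
#' set so the analytic mass equals the draw exactly. The defaults emulate the
#' dose response of UV-exposed fibroblasts: mean dry mass decreasing with
#' exposure (300, 240, 190, 160 pg for control, T50, T100, T200) with 20 pg
#' between-cell scatter, radii around 15 um -- effect sizes large enough that
#' Welch tests against control reject decisively at 10 cells per group.
#'
#' @param config a [sim_config()]; `phantoms_per_group`, wavelength, alpha
#'   and the field of view come from it.
#' @param mass_means named numeric vector of group mean dry masses, pg, in
#'   dose order.
#' @param mass_sd between-cell SD of dry mass, pg.
#' @param radius_range uniform range of disk radii, um.
#' @param seed integer seed (defaults to `config$seed`).
#' @return Named list (by group) of lists of [cell_phantom()]s.
#' @export
make_group_phantoms <- function(config,
                                mass_means = c(control = 300, T50 = 240,
                                               T100 = 190, T200 = 160),
                                mass_sd = 20,
                                radius_range = c(13, 17),
                                seed = config$seed) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  n <- config$phantoms_per_group
  half <- config$image_size * config$pixel_size / 2
  if (max(radius_range) >= half)
    stop("radius_range exceeds the field of view half-width (",
         format(half), " um)", call. = FALSE)
  out <- lapply(names(mass_means), function(g) {
    lapply(seq_len(n), function(i) {
      mass <- stats::rnorm(1, mass_means[[g]], mass_sd)
      r <- stats::runif(1, radius_range[1], radius_range[2])
      # peak phase that makes the uniform disk's analytic mass equal `mass`
      peak <- mass * 4 * pi * config$alpha /
        (config$wavelength * pi * r^2)
      if (peak <= 0.25 || peak >= 0.95 * pi)
        stop("configured masses/radii give peak phase ", format(peak),
             " rad outside the demodulatable range (0.25, 0.95*pi)",
             call. = FALSE)
      cell_phantom(center = c(0, 0), radius = r, peak_phase = peak,
                   profile = "uniform_disk", wavelength = config$wavelength,
                   alpha = config$alpha, group = g)
    })
  })
  names(out) <- names(mass_means)
  out
}

#' Run the full quantitative-phase arm on synthetic cohorts
#'
#' For every phantom: rasterize the phase, simulate the off-axis
#' interferogram (with the configured noise), demodulate, unwrap, subtract
#' the background plane, segment at 0.2 rad and compute dry mass and matter
#' density. Ground truth is carried alongside the measurements.
#'
#' @param config a [sim_config()].
#' @param phantoms output of [make_group_phantoms()]; generated from
#'   `config` when omitted.
#' @param unwrap_method passed to [unwrap_phase()].
#' @return A data.frame with one row per phantom: `group`, `image_id`,
#'   `true_mass_pg`, `area_um2`, `dry_mass_pg`,
#'   `matter_density_pg_per_um2`.
#' @export
simulate_qpi_arm <- function(config, phantoms = NULL,
                             unwrap_method = "lsq") {
  validate_sim_config(config)
  if (is.null(phantoms)) phantoms <- make_group_phantoms(config)
  set.seed(config$seed + 1L)   # noise stream, distinct from phantom draws
  rows <- list()
  for (g in names(phantoms)) {
    for (i in seq_along(phantoms[[g]])) {
      ph <- phantoms[[g]][[i]]
      pm <- make_phase_map(ph, config)
      ig <- make_interferogram(pm, config)
      rec <- reconstruct_phase(ig)
      rec <- unwrap_phase(rec, method = unwrap_method)
      rec <- subtract_background(rec)
      cr <- cell_records(rec, group = g,
                         image_id = sprintf("%s_%02d", g, i),
                         alpha = config$alpha)
      if (nrow(cr) >= 1L) {
        cr <- cr[1, ]      # the phantom is the dominant component
        cr$true_mass_pg <- ph$true_dry_mass
        rows[[length(rows) + 1L]] <- cr
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
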