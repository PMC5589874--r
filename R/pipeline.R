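#' Validate a pipeline configuration file
#'
#' Checks the configuration against every invariant declared by the typed
#' settings of the simulation and analysis stages (acquisition geometry,
#' carrier bounds, alpha, group structure, noise levels, viability means).
#'
#' @param config_path path to a YAML configuration file, or an equivalent
#'   named list.
#' @return `TRUE` (invisibly) when valid; otherwise a character vector of
#'   violations is returned (and printed) -- callers wanting an error can
#'   use `stopifnot(isTRUE(validate_config(p)))`.
#' @export
validate_config <- function(config_path) {
  cfg <- if (is.character(config_path)) read_run_config(config_path)
         else config_path
  bad <- character()
  sc <- try(as_sim_config(cfg), silent = TRUE)
  if (inherits(sc, "try-error")) {
    bad <- c(bad, conditionMessage(attr(sc, "condition")))
  } else {
    bad <- c(bad, sim_config_violations(sc))
  }
  mm <- config_mass_means(cfg)
  if (any(diff(mm) >= 0))
    bad <- c(bad, "mass_means must strictly decrease with dose")
  vm <- config_viability_means(cfg)
  if (any(vm < 0))
    bad <- c(bad, "viability_means must be non-negative")
  if (any(diff(vm) >= 0))
    bad <- c(bad, "viability_means must strictly decrease with dose")
  if (!is.null(cfg$raman_noise_sd) && cfg$raman_noise_sd < 0)
    bad <- c(bad, "raman_noise_sd must be >= 0")
  if (!is.null(cfg$spectra_per_group) && cfg$spectra_per_group < 4)
    bad <- c(bad, "spectra_per_group must be >= 4 (PCA needs n > components)")
  if (length(bad) > 0L) {
    message("config violations:\n  - ", paste(bad, collapse = "\n  - "))
    return(bad)
  }
  invisible(TRUE)
}

# assemble a sim_config from the flat run configuration
as_sim_config <- function(cfg) {
  sim_config(
    seed = cfg$seed,
    image_size = cfg$image_size %||% 512L,
    pixel_size = cfg$pixel_size %||% 0.1,
    wavelength = cfg$wavelength %||% 0.8,
    carrier_frequency = unlist(cfg$carrier_frequency %||% c(0.25, 0)),
    fringe_background = cfg$fringe_background %||% 1,
    fringe_amplitude = cfg$fringe_amplitude %||% 0.8,
    noise_model = cfg$noise_model %||% "gaussian",
    noise_sd = cfg$noise_sd %||% 0.01,
    alpha = cfg$alpha %||% 0.185,
    phantoms_per_group = cfg$phantoms_per_group %||% 10L
  )
}

config_mass_means <- function(cfg) {
  mm <- unlist(cfg$mass_means %||%
                 list(control = 300, T50 = 240, T100 = 190, T200 = 160))
  mm[dose_groups()[dose_groups() %in% names(mm)]]
}

config_viability_means <- function(cfg) {
  vm <- unlist(cfg$viability_means %||%
                 list(control = 0.85, T50 = 0.62, T100 = 0.45, T200 = 0.30))
  vm[dose_groups()[dose_groups() %in% names(vm)]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the complete dual-modality pipeline
#'
#' Executes, in order: viability simulation and correction; QPI-arm
#' simulation, phase reconstruction and densitometry with Welch tests
#' against control; Raman-arm simulation, preprocessing, marker-band
#' quantification and PCA with the silhouette separation summary. Writes
#' all tables as CSV, the figures as PNG, a Markdown report and a YAML run
#' manifest (config hash, seed, stage outputs, version, timestamps) into
#' `out_dir`. A stage failure aborts with the failing stage named; outputs
#' of earlier stages are retained.
#'
#' @param config_path YAML configuration path (see [read_run_config()]) or
#'   an equivalent named list.
#' @param out_dir output directory, created if needed.
#' @param only `"all"` (default), `"qpi"` or `"raman"`: the two arms are
#'   analytically independent and can run standalone. The skipped arm is
#'   marked SKIPPED in the report.
#' @return The run manifest (named list), invisibly.
#' @export
run_all <- function(config_path, out_dir, only = c("all", "qpi", "raman")) {
  only <- match.arg(only)
  cfg <- if (is.character(config_path)) read_run_config(config_path)
         else config_path
  v <- validate_config(cfg)
  if (!isTRUE(v))
    stop("invalid configuration:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # echo the config; its digest is the run identity
  cfg_file <- file.path(out_dir, "config_echo.yml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    version = as.character(utils::packageVersion("opticyte")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage_outputs = list()
  )
  report <- c("# Label-free profiling run report", "",
              sprintf("- seed: %d", cfg$seed),
              sprintf("- config hash: %s", manifest$config_hash), "")
  add_out <- function(stage, files) {
    manifest$stage_outputs[[stage]] <<- files
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## stage: viability ------------------------------------------------------
  via_summary <- run_stage("viability", {
    tab <- make_viability_table(mean_corrected = config_viability_means(cfg),
                                noise_sd = cfg$viability_noise_sd %||% 0.015,
                                seed = cfg$seed)
    corr <- viability_correct(tab)
    f_csv <- file.path(out_dir, "viability.csv")
    utils::write.csv(corr, f_csv, row.names = FALSE)
    f_png <- file.path(out_dir, "fig_viability.png")
    grDevices::png(f_png, width = 700, height = 500)
    graphics::plot(corr$exposure_min, corr$corrected_mean, type = "b",
                   pch = 19, xlab = "UV exposure (min)",
                   ylab = "corrected absorbance (570 nm - blank 600 nm)",
                   main = "Cell viability vs exposure time",
                   ylim = range(c(corr$corrected_mean - corr$corrected_sd,
                                  corr$corrected_mean + corr$corrected_sd)))
    graphics::arrows(corr$exposure_min,
                     corr$corrected_mean - corr$corrected_sd,
                     corr$exposure_min,
                     corr$corrected_mean + corr$corrected_sd,
                     angle = 90, code = 3, length = 0.05)
    grDevices::dev.off()
    add_out("viability", c(f_csv, f_png))
    corr
  })
  report <- c(report, "## Viability", "",
              "![viability](fig_viability.png)", "",
              md_table(via_summary), "")

  ## stage: qpi ------------------------------------------------------------
  if (only %in% c("all", "qpi")) {
    qpi <- run_stage("qpi", {
      sc <- as_sim_config(cfg)
      phantoms <- make_group_phantoms(sc, mass_means = config_mass_means(cfg),
                                      mass_sd = cfg$mass_sd %||% 20)
      cells <- simulate_qpi_arm(sc, phantoms)
      f_cells <- file.path(out_dir, "cells.csv")
      utils::write.csv(cells, f_cells, row.names = FALSE)
      summ <- summarize_groups(cells)
      f_summ <- file.path(out_dir, "qpi_group_summary.csv")
      utils::write.csv(summ, f_summ, row.names = FALSE)
      wm <- welch_vs_control(cells, "dry_mass_pg")
      wd <- welch_vs_control(cells, "matter_density_pg_per_um2")
      wm$quantity <- "dry_mass"; wd$quantity <- "matter_density"
      stats_tab <- rbind(wm, wd)
      f_stats <- file.path(out_dir, "qpi_welch.csv")
      utils::write.csv(stats_tab, f_stats, row.names = FALSE)
      f_png <- file.path(out_dir, "fig_biophysics.png")
      grDevices::png(f_png, width = 900, height = 450)
      old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
      bar_with_sd(summ$group, summ$dry_mass_mean, summ$dry_mass_sd,
                  "dry mass (pg)")
      bar_with_sd(summ$group, summ$density_mean, summ$density_sd,
                  "matter density (pg/um^2)")
      grDevices::dev.off()
      add_out("qpi", c(f_cells, f_summ, f_stats, f_png))
      list(summary = summ, stats = stats_tab)
    })
    report <- c(report, "## Biophysical parameters (QPI arm)", "",
                "![biophysics](fig_biophysics.png)", "",
                md_table(qpi$summary), "",
                "Welch tests vs control:", "", md_table(qpi$stats), "")
  } else {
    report <- c(report, "## Biophysical parameters (QPI arm)", "",
                "SKIPPED", "")
  }

  ## stage: raman ----------------------------------------------------------
  if (only %in% c("all", "raman")) {
    raman <- run_stage("raman", {
      specs <- default_group_specs(
        noise_sd = cfg$raman_noise_sd %||% 0.02,
        n_spectra = cfg$spectra_per_group %||% 15L)
      ds <- make_group_spectra(specs, seed = cfg$seed)
      f_raw <- file.path(out_dir, "spectra_raw.csv")
      write_spectra_csv(ds, f_raw)
      proc <- preprocess_spectra(ds)
      f_proc <- file.path(out_dir, "spectra_processed.csv")
      write_spectra_csv(proc, f_proc)
      bands <- rbind(cbind(band = 1000,
                           band_intensity_by_group(proc, 1000)),
                     cbind(band = 1584,
                           band_intensity_by_group(proc, 1584)))
      f_bands <- file.path(out_dir, "band_intensities.csv")
      utils::write.csv(bands, f_bands, row.names = FALSE)
      f_mean <- file.path(out_dir, "fig_mean_spectra.png")
      plot_mean_spectra(group_mean_spectra(proc), f_mean)
      f_bar <- file.path(out_dir, "fig_band_intensity.png")
      grDevices::png(f_bar, width = 900, height = 450)
      old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
      for (b in c(1000, 1584)) {
        sub <- bands[bands$band == b, ]
        bar_with_sd(sub$group, sub$mean, sub$sd,
                    sprintf("%d cm-1 band intensity (SNV units)", b))
      }
      grDevices::dev.off()
      add_out("raman", c(f_raw, f_proc, f_bands, f_mean, f_bar))
      list(proc = proc, bands = bands)
    })
    pca <- run_stage("pca", {
      res <- fit_pca(raman$proc, n_components = cfg$n_components %||% 3)
      f_load <- file.path(out_dir, "pca_loadings.csv")
      utils::write.csv(data.frame(wavenumber = res$axis,
                                  t(res$loadings)), f_load,
                       row.names = FALSE)
      f_sco <- file.path(out_dir, "pca_scores.csv")
      utils::write.csv(data.frame(cell_id = raman$proc$cell_ids,
                                  group = res$labels, res$scores),
                       f_sco, row.names = FALSE)
      f_png <- file.path(out_dir, "fig_pc_scatter.png")
      sep <- score_scatter_3d(res, file = f_png)
      f_cent <- file.path(out_dir, "pca_centroids.csv")
      utils::write.csv(sep$centroids, f_cent, row.names = FALSE)
      add_out("pca", c(f_load, f_sco, f_cent, f_png))
      list(res = res, sep = sep)
    })
    report <- c(report, "## Raman spectra", "",
                "![mean spectra](fig_mean_spectra.png)", "",
                "![band intensities](fig_band_intensity.png)", "",
                md_table(raman$bands), "",
                "## PCA discrimination", "",
                "![PC scatter](fig_pc_scatter.png)", "",
                sprintf("Explained variance: %s.",
                        paste(sprintf("%.1f%%",
                                      100 * pca$res$explained_variance_fraction),
                              collapse = ", ")),
                sprintf("Mean silhouette of the 3-PC configuration: %.3f.",
                        pca$sep$silhouette), "")
  } else {
    report <- c(report, "## Raman spectra", "", "SKIPPED", "",
                "## PCA discrimination", "", "SKIPPED", "")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  writeLines(report, file.path(out_dir, "report.md"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}

# grouped bar chart with +/- SD whiskers (base graphics)
bar_with_sd <- function(groups, means, sds, ylab) {
  ctr <- graphics::barplot(means, names.arg = as.character(groups),
                           ylab = ylab,
                           ylim = c(0, max(means + sds) * 1.15))
  graphics::arrows(ctr, means - sds, ctr, means + sds, angle = 90,
                   code = 3, length = 0.05)
}

# vertically offset group mean spectra with SD envelopes
plot_mean_spectra <- function(gm, file) {
  grDevices::png(file, width = 900, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  offsets <- (seq_along(gm) - 1) * 3
  ylim <- range(unlist(lapply(seq_along(gm), function(i)
    c(gm[[i]]$mean - gm[[i]]$sd, gm[[i]]$mean + gm[[i]]$sd) + offsets[i])))
  graphics::plot(NULL, xlim = range(gm[[1]]$axis), ylim = ylim,
                 xlab = "Raman shift (cm-1)",
                 ylab = "SNV intensity (offset)",
                 main = "Group mean spectra +/- SD")
  for (i in seq_along(gm)) {
    g <- gm[[i]]
    graphics::polygon(c(g$axis, rev(g$axis)),
                      c(g$mean + g$sd, rev(g$mean - g$sd)) + offsets[i],
                      col = grDevices::adjustcolor(i, alpha.f = 0.25),
                      border = NA)
    graphics::lines(g$axis, g$mean + offsets[i], col = i)
    graphics::text(max(g$axis), offsets[i] + g$mean[length(g$mean)] + 0.8,
                   names(gm)[i], pos = 2, col = i)
  }
}

# minimal data.frame -> markdown table
md_table <- function(df) {
  fmt <- function(v) if (is.numeric(v)) formatC(v, digits = 4, format = "g")
                     else as.character(v)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
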