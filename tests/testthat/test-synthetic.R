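test_that("phantom closed-form dry mass matches independent quadrature", {
  cases <- list(
    cell_phantom(radius = 5.6419, peak_phase = 1.0, profile = "uniform_disk"),
    cell_phantom(radius = 6, peak_phase = 1.4, profile = "smoothed_disk"),
    cell_phantom(radius = 6, peak_phase = 2.0, profile = "gaussian_cap")
  )
  for (ph in cases) {
    expect_equal(ph$true_dry_mass, quadrature_mass(ph),
                 tolerance = 2e-3, label = ph$profile)
  }
  # hand-evaluated closed form: lambda*phi*A / (4 pi alpha) for a disk of
  # area 100 um^2, phi = 1 rad, lambda = 0.8 um, alpha = 0.185 um^3/pg
  disk <- cell_phantom(radius = sqrt(100 / pi), peak_phase = 1.0)
  expect_equal(disk$true_dry_mass, 0.8 * 1.0 * 100 / (4 * pi * 0.185),
               tolerance = 1e-12)
  expect_equal(disk$true_dry_mass, 34.41, tolerance = 1e-4)
})

test_that("rasterized phase maps integrate to the analytic mass", {
  cfg <- mid_config()
  for (prof in c("uniform_disk", "smoothed_disk", "gaussian_cap")) {
    ph <- cell_phantom(radius = 4, peak_phase = 1.2, profile = prof)
    pm <- make_phase_map(ph, cfg)
    disc <- cfg$wavelength / (4 * pi * cfg$alpha) * sum(pm$phase) *
      cfg$pixel_size^2
    expect_lt(abs(disc - ph$true_dry_mass) / ph$true_dry_mass, 0.01,
              label = prof)
  }
})

test_that("gaussian-cap discrete mass converges to the quadrature oracle", {
  ph <- cell_phantom(radius = 4, peak_phase = 2, profile = "gaussian_cap")
  oracle <- quadrature_mass(ph, pixel = 0.01)  # 10x oversampled
  errs <- vapply(c(64L, 128L, 256L), function(n) {
    cfg <- sim_config(seed = 1, image_size = n,
                      pixel_size = 0.1 * 256 / n)
    pm <- make_phase_map(ph, cfg)
    disc <- cfg$wavelength / (4 * pi * cfg$alpha) * sum(pm$phase) *
      cfg$pixel_size^2
    abs(disc - oracle) / oracle
  }, numeric(1))
  expect_true(all(diff(errs) < 0))      # refining the grid shrinks the error
  expect_lt(errs[3], 0.01)
})

test_that("zero-amplitude phantom gives an all-zero map; misfits rejected", {
  cfg <- small_config()
  pm <- make_phase_map(cell_phantom(radius = 3, peak_phase = 0), cfg)
  expect_true(all(pm$phase == 0))
  expect_error(cell_phantom(radius = 3, peak_phase = 0.15), "0.2 rad")
  expect_error(
    make_phase_map(cell_phantom(center = c(5, 0), radius = 3,
                                peak_phase = 1), cfg),
    "field of view")
})

test_that("interferogram forward model produces carrier fringes", {
  cfg <- small_config()
  flat <- phase_map(matrix(0, 128, 128), cfg$pixel_size, cfg$wavelength)
  ig <- make_interferogram(flat, cfg)
  px <- 0:127
  expected <- cfg$fringe_background + cfg$fringe_amplitude *
    cos(2 * pi * outer(px * 0.25, px * 0, "+"))
  expect_equal(ig$intensity, expected, tolerance = 1e-12)
  # noiseless spectrum of any phase map has its energy in DC +/- carrier
  ph <- cell_phantom(radius = 3, peak_phase = 1, profile = "gaussian_cap")
  ig2 <- make_interferogram(make_phase_map(ph, cfg), cfg)
  mag <- Mod(stats::fft(ig2$intensity))
  top3 <- order(mag, decreasing = TRUE)[1:3]
  idx <- arrayInd(top3, dim(mag))
  fx <- sort(((idx[, 1] - 1) / 128 + 0.5) %% 1 - 0.5)
  expect_equal(fx, c(-0.25, 0, 0.25), tolerance = 1e-12)
})

test_that("synthetic outputs are deterministic under a fixed seed", {
  gs <- default_group_specs()$T100
  a <- make_spectra(gs, seed = 11)
  b <- make_spectra(gs, seed = 11)
  expect_identical(a, b)
  cfg <- small_config(pixel_size = 0.3)
  p1 <- make_group_phantoms(cfg)
  p2 <- make_group_phantoms(cfg)
  expect_identical(p1, p2)
  v1 <- make_viability_table(seed = 5)
  v2 <- make_viability_table(seed = 5)
  expect_identical(v1, v2)
})

test_that("simulated spectra follow the configured band structure", {
  # a single noiseless band peaks exactly at its centre
  spec <- spectral_group_spec(
    group = "control",
    band_amplitudes = c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0),  # 1004 only
    baseline_coeffs = rep(0, 5), noise_sd = 0, n_spectra = 1)
  ds <- make_spectra(spec, seed = 1)
  expect_equal(ds$axis[which.max(ds$matrix[1, ])], 1004)
  # configured monotone 1584 amplitudes are the oracle downstream
  amps <- vapply(default_group_specs(), function(s)
    s$band_amplitudes[s$band_centers == 1584], numeric(1))
  expect_true(all(diff(amps) > 0))
  # axis must cover every band
  expect_error(make_spectra(default_group_specs()$control,
                            axis = seq(1100, 1800), seed = 1),
               "band centre")
  # marker bands are mandatory
  expect_error(spectral_group_spec("control", band_centers = c(720, 1004),
                                   band_amplitudes = c(1, 1)),
               "marker bands")
})

test_that("viability table honours its configuration", {
  zero <- make_viability_table(noise_sd = 0, seed = 1)
  corr <- viability_correct(zero)
  expect_equal(corr$corrected_mean,
               c(0.85, 0.62, 0.45, 0.30), tolerance = 1e-12)
  expect_true(all(diff(corr$corrected_mean) < 0))
  expect_error(make_viability_table(mean_corrected = c(control = -0.1,
                                                       T50 = -0.2)),
               "non-negative")
  expect_error(make_viability_table(mean_corrected = c(control = 0.3,
                                                       T50 = 0.5)),
               "decrease")
})
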