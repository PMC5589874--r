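test_that("carrier estimation finds the configured frequency", {
  cfg <- small_config()
  flat <- phase_map(matrix(0, 128, 128), cfg$pixel_size, cfg$wavelength)
  ig <- make_interferogram(flat, cfg)
  ig$carrier_hint <- NULL
  expect_equal(estimate_carrier(ig), c(0.25, 0))
  # off-axis diagonal carrier with noise: within one frequency bin
  cfg2 <- small_config(carrier_frequency = c(0.2, 0.1), noise_sd = 0.01)
  set.seed(1)
  ig2 <- make_interferogram(flat, cfg2)
  ig2$carrier_hint <- NULL
  k <- estimate_carrier(ig2)
  expect_true(all(abs(k - c(0.2, 0.1)) <= 1 / 128 + 1e-12))
  # constant image has no carrier
  const <- interferogram(matrix(1, 128, 128), 0.1, 0.8)
  expect_error(estimate_carrier(const), "no carrier detected")
  expect_error(estimate_carrier(interferogram(matrix(1, 32, 32), 0.1, 0.8)),
               "64 x 64")
})

test_that("sideband demodulation recovers the wrapped phase", {
  cfg <- mid_config()
  ph <- cell_phantom(radius = 9, peak_phase = 2.5, profile = "gaussian_cap")
  pm <- make_phase_map(ph, cfg)
  ig <- make_interferogram(pm, cfg)
  rec <- reconstruct_phase(ig)
  expect_false(rec$background_corrected)
  expect_true(all(rec$phase > -pi & rec$phase <= pi + 1e-12))
  expect_lt(rmse_interior(rec$phase, pm$phase), 0.01)
  # zero-phase hologram demodulates to ~0
  flat <- phase_map(matrix(0, 256, 256), cfg$pixel_size, cfg$wavelength)
  rec0 <- reconstruct_phase(make_interferogram(flat, cfg))
  expect_lt(rmse_interior(rec0$phase, flat$phase), 1e-6)
  # phase exceeding 2 pi comes back wrapped: differs by exact 2 pi multiples
  ph8 <- cell_phantom(radius = 10, peak_phase = 8, profile = "gaussian_cap")
  pm8 <- make_phase_map(ph8, cfg)
  rec8 <- reconstruct_phase(make_interferogram(pm8, cfg))
  i <- 6:251
  resid <- (rec8$phase - pm8$phase)[i, i]
  k <- round(resid / (2 * pi))
  expect_true(any(k != 0))
  expect_lt(sqrt(mean((resid - 2 * pi * k)^2)), 0.01)
  # a sideband window reaching DC is refused
  expect_error(reconstruct_phase(ig, window_radius = 0.3), "overlap DC")
})

test_that("reconstruction is linear in the phase below the wrap limit", {
  cfg <- mid_config()
  ph <- cell_phantom(radius = 9, peak_phase = 2.0, profile = "gaussian_cap")
  pm1 <- make_phase_map(ph, cfg)
  pm2 <- phase_map(0.5 * pm1$phase, cfg$pixel_size, cfg$wavelength)
  r1 <- reconstruct_phase(make_interferogram(pm1, cfg))
  r2 <- reconstruct_phase(make_interferogram(pm2, cfg))
  expect_lt(rmse_interior(0.5 * r1$phase, r2$phase), 1e-3)
})

test_that("phase unwrapping recovers smooth surfaces", {
  # analytic 1-D case: vertical ramp 0 -> 6 pi
  n <- 64
  ramp <- matrix(rep(seq(0, 6 * pi, length.out = n), each = n), n, n)
  wrapped <- phase_map(opticyte:::wrap_to_pi(ramp), 0.1, 0.8)
  for (m in c("lsq", "itoh")) {
    un <- unwrap_phase(wrapped, method = m)
    off <- mean(un$phase - ramp)
    # offset is a whole multiple of 2 pi
    expect_lt(min(off %% (2 * pi), 2 * pi - off %% (2 * pi)), 1e-6,
              label = m)
    expect_lt(max(abs(un$phase - ramp - off)), 1e-6, label = m)
  }
  # smooth gaussian cap of peak 8 rad
  cfg <- mid_config()
  pm <- make_phase_map(cell_phantom(radius = 10, peak_phase = 8,
                                    profile = "gaussian_cap"), cfg)
  wr <- phase_map(opticyte:::wrap_to_pi(pm$phase), cfg$pixel_size,
                  cfg$wavelength)
  for (m in c("lsq", "itoh")) {
    un <- unwrap_phase(wr, method = m)
    off <- mean(un$phase - pm$phase)
    expect_lt(sqrt(mean((un$phase - pm$phase - off)^2)), 0.01, label = m)
  }
  # already-continuous input passes through unchanged
  cont <- phase_map(pm$phase, cfg$pixel_size, cfg$wavelength)
  expect_equal(unwrap_phase(cont)$phase, pm$phase, tolerance = 1e-9)
  expect_equal(unwrap_phase(cont, "itoh")$phase, pm$phase, tolerance = 1e-9)
})

test_that("background subtraction removes tilt and offset", {
  n <- 128
  X <- matrix(rep(seq_len(n), n), n, n)
  Y <- t(X)
  plane <- 0.002 * X - 0.001 * Y + 0.3
  pm <- phase_map(plane, 0.1, 0.8)
  out <- subtract_background(pm)
  expect_true(out$background_corrected)
  expect_lt(max(abs(out$phase)), 1e-8)
  # phantom on a tilted background
  cfg <- small_config()
  ph <- make_phase_map(cell_phantom(radius = 3, peak_phase = 1,
                                    profile = "gaussian_cap"), cfg)
  tilted <- phase_map(ph$phase + plane, cfg$pixel_size, cfg$wavelength)
  rec <- subtract_background(tilted)
  expect_lt(sqrt(mean((rec$phase - ph$phase)^2)), 0.02)
  bg <- ph$phase < 0.01
  expect_lt(abs(median(rec$phase[bg])), 0.02)
  # flat background: output is input minus its background median
  flat <- phase_map(ph$phase, cfg$pixel_size, cfg$wavelength)
  out2 <- subtract_background(flat)
  expect_lt(abs(median(out2$phase[bg])), 0.02)
  expect_error(subtract_background(pm, matrix(FALSE, n, n)), "empty")
})

test_that("full chain recovers ground truth at spec noise levels", {
  cfg0 <- mid_config(noise_sd = 0)
  ph <- cell_phantom(radius = 9, peak_phase = 2.5, profile = "gaussian_cap")
  pm <- make_phase_map(ph, cfg0)
  rec0 <- reconstruct_chain(make_interferogram(pm, cfg0))
  expect_lt(rmse_interior(rec0$phase, pm$phase), 0.01)
  cfg1 <- mid_config(noise_sd = 0.01)
  set.seed(7)
  rec1 <- reconstruct_chain(make_interferogram(pm, cfg1))
  expect_lt(rmse_interior(rec1$phase, pm$phase), 0.05)
  # dry mass through the chain: uniform disk, noiseless, within 2%
  disk <- cell_phantom(radius = 8, peak_phase = 1.2)
  pmd <- make_phase_map(disk, cfg0)
  recd <- reconstruct_chain(make_interferogram(pmd, cfg0))
  mk <- segment_cells(recd)
  expect_length(mk, 1)
  est <- dry_mass(recd, mk[[1]])
  expect_lt(abs(est - disk$true_dry_mass) / disk$true_dry_mass, 0.02)
  # and within 5% at 1% fringe noise
  set.seed(8)
  recn <- reconstruct_chain(make_interferogram(pmd, cfg1))
  mkn <- segment_cells(recn)
  estn <- dry_mass(recn, mkn[[1]])
  expect_lt(abs(estn - disk$true_dry_mass) / disk$true_dry_mass, 0.05)
})
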