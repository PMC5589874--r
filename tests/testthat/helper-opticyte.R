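# shared fixtures built in code

# small, fast acquisition geometry used by most tests
small_config <- function(pixel_size = 0.1, ...) {
  sim_config(seed = 42L, image_size = 128L, pixel_size = pixel_size, ...)
}

# mid-size geometry for recovery checks
mid_config <- function(...) {
  sim_config(seed = 42L, image_size = 256L, pixel_size = 0.1, ...)
}

# segment the dominant component and return its dry mass
dry_mass_of_first <- function(pm) {
  mk <- segment_cells(pm)
  dry_mass(pm, mk[[1]])
}

# RMSE between two matrices with a border excluded (windowing edge effects)
rmse_interior <- function(a, b, border = 5L) {
  i <- (border + 1):(nrow(a) - border)
  j <- (border + 1):(ncol(a) - border)
  sqrt(mean((a[i, j] - b[i, j])^2))
}

# independent numerical quadrature of a phantom's phase integral on an
# oversampled grid (the oracle for closed-form masses)
quadrature_mass <- function(phantom, pixel = 0.01) {
  half <- phantom$radius * 1.05
  ax <- seq(-half, half, by = pixel)
  r <- sqrt(outer(ax^2, ax^2, "+"))
  R <- phantom$radius
  vals <- matrix(0, length(ax), length(ax))
  inside <- r < R
  vals[inside] <- switch(phantom$profile,
    uniform_disk  = phantom$peak_phase,
    smoothed_disk = phantom$peak_phase * cos(pi * r[inside] / (2 * R))^2,
    gaussian_cap  = phantom$peak_phase * exp(-r[inside]^2 / (2 * (R / 3)^2)))
  phantom$wavelength / (4 * pi * phantom$alpha) * sum(vals) * pixel^2
}

# full QPI chain on one interferogram
reconstruct_chain <- function(ig, method = "lsq") {
  subtract_background(unwrap_phase(reconstruct_phase(ig), method = method))
}
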