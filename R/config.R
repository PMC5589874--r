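#' Simulation configuration
#'
#' Bundles the acquisition geometry and noise model used by the synthetic
#' generators and carried as metadata by every derived image.
#'
#' The defaults emulate a high-NA (60x / 1.0 NA) reflection phase microscope:
#' 512 x 512 pixels at 0.1 um/pixel, centre wavelength 0.8 um, and an off-axis
#' carrier of 0.25 cycles/pixel along x. The carrier magnitude must lie in
#' (0.1, 0.4) cycles/pixel so that the interference sidebands are separable
#' from the DC term without aliasing.
#'
#' @param seed integer seed; fully determines every synthetic output.
#' @param image_size side length of the (square) field of view, pixels.
#' @param pixel_size lateral sampling, um/pixel.
#' @param wavelength centre illumination wavelength, um.
#' @param carrier_frequency length-2 numeric, carrier in cycles/pixel.
#' @param fringe_background additive fringe offset A (arbitrary intensity).
#' @param fringe_amplitude fringe modulation B; visibility is B/A.
#' @param noise_model `"gaussian"` (additive, default) or `"shot"` (Poisson).
#' @param noise_sd standard deviation of additive noise, as a fraction of the
#'   fringe amplitude B (ignored for `"shot"`).
#' @param alpha specific refractive index increment, um^3/pg.
#' @param phantoms_per_group number of synthetic cells per exposure group.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, image_size = 256)
#' cfg$carrier_frequency
#' @export
sim_config <- function(seed = 1L,
                       image_size = 512L,
                       pixel_size = 0.1,
                       wavelength = 0.8,
                       carrier_frequency = c(0.25, 0),
                       fringe_background = 1,
                       fringe_amplitude = 0.8,
                       noise_model = c("gaussian", "shot"),
                       noise_sd = 0,
                       alpha = 0.185,
                       phantoms_per_group = 10L) {
  noise_model <- match.arg(noise_model)
  cfg <- structure(list(
    seed = as.integer(seed),
    image_size = as.integer(image_size),
    pixel_size = pixel_size,
    wavelength = wavelength,
    carrier_frequency = as.numeric(carrier_frequency),
    fringe_background = fringe_background,
    fringe_amplitude = fringe_amplitude,
    noise_model = noise_model,
    noise_sd = noise_sd,
    alpha = alpha,
    phantoms_per_group = as.integer(phantoms_per_group)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every declared invariant of [sim_config()] and returns the config
#' invisibly, or stops with all violations collected into one message.
#'
#' @param cfg a `sim_config` (or plain list with the same fields).
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  bad <- sim_config_violations(cfg)
  if (length(bad) > 0L)
    stop("invalid simulation config:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(cfg)
}

# collect invariant violations as character vector (empty if valid)
sim_config_violations <- function(cfg) {
  bad <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && is.finite(cfg$seed),
      "seed must be a single finite integer")
  chk(is.numeric(cfg$image_size) && cfg$image_size >= 64,
      "image_size must be >= 64 pixels")
  chk(is.numeric(cfg$pixel_size) && cfg$pixel_size > 0,
      "pixel_size must be > 0 um")
  chk(is.numeric(cfg$wavelength) && cfg$wavelength > 0,
      "wavelength must be > 0 um")
  kmag <- sqrt(sum(cfg$carrier_frequency^2))
  chk(length(cfg$carrier_frequency) == 2L && kmag > 0.1 && kmag < 0.4,
      "carrier_frequency magnitude must lie in (0.1, 0.4) cycles/pixel")
  chk(cfg$fringe_background > 0, "fringe_background must be > 0")
  chk(cfg$fringe_amplitude > 0, "fringe_amplitude must be > 0")
  chk(cfg$noise_model %in% c("gaussian", "shot"),
      "noise_model must be 'gaussian' or 'shot'")
  chk(is.numeric(cfg$noise_sd) && cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0,
      "alpha (specific refractive increment) must be > 0 um^3/pg")
  bad
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  field of view : %d x %d px @ %.3g um/px\n",
              x$image_size, x$image_size, x$pixel_size))
  cat(sprintf("  wavelength    : %.3g um\n", x$wavelength))
  cat(sprintf("  carrier       : (%.3g, %.3g) cycles/px\n",
              x$carrier_frequency[1], x$carrier_frequency[2]))
  cat(sprintf("  noise         : %s, sd = %.3g x B\n", x$noise_model, x$noise_sd))
  cat(sprintf("  alpha         : %.3g um^3/pg, seed = %d\n", x$alpha, x$seed))
  invisible(x)
}
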