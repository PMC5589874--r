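#' Estimate the off-axis carrier frequency
#'
#' Locates the strongest non-DC peak of the Fourier magnitude spectrum of the
#' interferogram. The sign ambiguity between the two conjugate sidebands is
#' resolved by always reporting the peak in the half-plane with positive
#' first component (positive second component when the first is zero).
#'
#' @param ig an [interferogram()] of at least 64 x 64 pixels.
#' @param dc_guard radius (bins) around DC excluded from the search.
#' @return Length-2 numeric carrier estimate, cycles/pixel (bin-quantized).
#' @examples
#' cfg <- sim_config(seed = 1, image_size = 128)
#' pm <- make_phase_map(cell_phantom(radius = 3, peak_phase = 1), cfg)
#' estimate_carrier(make_interferogram(pm, cfg))
#' @export
estimate_carrier <- function(ig, dc_guard = 3) {
  stopifnot(inherits(ig, "interferogram"))
  n <- nrow(ig$intensity); m <- ncol(ig$intensity)
  if (n < 64 || m < 64) stop("interferogram must be at least 64 x 64 pixels")
  F <- stats::fft(ig$intensity)
  mag <- Mod(F)
  fx <- signed_freq(n); fy <- signed_freq(m)
  dc <- outer(abs(fx) * n <= dc_guard, abs(fy) * m <= dc_guard, "&")
  mag_out <- mag[!dc]
  peak <- max(mag_out)
  if (peak <= 3 * stats::median(mag_out))
    stop("no carrier detected: no Fourier peak above 3x the median ",
         "spectral magnitude outside DC", call. = FALSE)
  idx <- which(mag == peak & !dc, arr.ind = TRUE)[1, ]
  k <- c(fx[idx[1]], fy[idx[2]])
  if (k[1] < 0 || (k[1] == 0 && k[2] < 0)) k <- -k
  k
}

# signed DFT frequencies in cycles/sample, bin order as returned by fft()
signed_freq <- function(n) {
  f <- (seq_len(n) - 1) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f
}

# wrap to the principal interval (-pi, pi]
wrap_to_pi <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Demodulate an off-axis interferogram to a wrapped phase map
#'
#' Standard Fourier sideband filtering: transform the fringe image, isolate
#' the +1-order sideband with a circular window centred on the carrier,
#' inverse-transform to the complex analytic signal, remove the carrier ramp,
#' and take the argument. The output phase is wrapped to (-pi, pi].
#'
#' @param ig an [interferogram()].
#' @param carrier `"auto"` (default: use the stored hint, else
#'   [estimate_carrier()]) or a length-2 numeric carrier in cycles/pixel.
#' @param window_radius sideband window radius, cycles/pixel; default half
#'   the carrier magnitude. Must be smaller than the carrier magnitude so the
#'   window cannot overlap DC.
#' @param window `"hard"` (circular top-hat, default) or `"hann"`
#'   (raised-cosine taper to the window edge).
#' @return A wrapped [phase_map()] (`background_corrected = FALSE`).
#' @export
reconstruct_phase <- function(ig, carrier = "auto", window_radius = NULL,
                              window = c("hard", "hann")) {
  stopifnot(inherits(ig, "interferogram"))
  window <- match.arg(window)
  if (identical(carrier, "auto"))
    carrier <- if (!is.null(ig$carrier_hint)) ig$carrier_hint
               else estimate_carrier(ig)
  stopifnot(is.numeric(carrier), length(carrier) == 2L)
  kmag <- sqrt(sum(carrier^2))
  if (kmag <= 0) stop("carrier must be non-zero")
  if (is.null(window_radius)) window_radius <- kmag / 2
  if (window_radius >= kmag)
    stop("sideband window (radius ", format(window_radius),
         " cycles/px) would overlap DC; use a larger carrier or a smaller ",
         "window", call. = FALSE)
  n <- nrow(ig$intensity); m <- ncol(ig$intensity)
  F <- stats::fft(ig$intensity)
  # torus distance from each Fourier bin to the carrier
  dfx <- wrap_unit(signed_freq(n) - carrier[1])
  dfy <- wrap_unit(signed_freq(m) - carrier[2])
  d2 <- outer(dfx^2, dfy^2, "+")
  w <- d2 <= window_radius^2
  Fs <- matrix(0 + 0i, n, m)
  if (window == "hard") {
    Fs[w] <- F[w]
  } else {
    taper <- 0.5 * (1 + cos(pi * sqrt(d2) / window_radius))
    taper[!w] <- 0
    Fs <- F * taper
  }
  analytic <- stats::fft(Fs, inverse = TRUE) / (n * m)
  px <- seq_len(n) - 1; py <- seq_len(m) - 1
  ramp <- 2 * pi * outer(px * carrier[1], py * carrier[2], "+")
  phase_map(wrap_to_pi(Arg(analytic) - ramp),
            pixel_size = ig$pixel_size, wavelength = ig$wavelength,
            background_corrected = FALSE)
}

# wrap frequency difference to [-0.5, 0.5)
wrap_unit <- function(f) {
  w <- (f + 0.5) %% 1 - 0.5
  w
}

#' Unwrap a wrapped phase map
#'
#' Recovers a continuous phase surface from values wrapped to (-pi, pi].
#' The default `"lsq"` method solves the unweighted least-squares (Poisson)
#' formulation via the discrete cosine transform, which is exact whenever the
#' wrapped pixel-to-pixel gradients are consistent (all true neighbouring
#' differences below pi) and degrades gracefully on noisy input. The `"itoh"`
#' method integrates wrapped differences along the first column and then
#' along rows; it is exact on noise-free input but propagates errors along
#' its path. Both results are re-anchored so that the output agrees with the
#' input modulo 2 pi and an already-continuous input is returned unchanged.
#'
#' @param wrapped a [phase_map()] with phase in (-pi, pi] (a continuous map
#'   is accepted and passed through).
#' @param method `"lsq"` (default) or `"itoh"`.
#' @return A [phase_map()] with continuous phase, equal to the true phase up
#'   to one global multiple of 2 pi.
#' @export
unwrap_phase <- function(wrapped, method = c("lsq", "itoh")) {
  stopifnot(inherits(wrapped, "phase_map"))
  method <- match.arg(method)
  psi <- wrapped$phase
  phi <- if (method == "lsq") unwrap_lsq(psi) else unwrap_itoh(psi)
  # re-anchor: global constant (circular mean, robust at the +/- pi
  # boundary), then the nearest global 2 pi multiple
  phi <- phi + Arg(mean(exp(1i * (psi - phi))))
  phi <- phi + 2 * pi * round(mean(psi - phi) / (2 * pi))
  phase_map(phi, wrapped$pixel_size, wrapped$wavelength,
            wrapped$background_corrected)
}

# Itoh path-following: integrate wrapped differences down column 1, then
# across each row
unwrap_itoh <- function(psi) {
  n <- nrow(psi); m <- ncol(psi)
  first <- cumsum(c(psi[1, 1], wrap_to_pi(diff(psi[, 1]))))
  dx <- wrap_to_pi(psi[, -1, drop = FALSE] - psi[, -m, drop = FALSE])
  cbind(first, first + t(apply(dx, 1, cumsum)), deparse.level = 0)
}

# unweighted least-squares unwrapping: solve the discrete Poisson equation
# with Neumann boundaries in the DCT basis (Ghiglia-Romero)
unwrap_lsq <- function(psi) {
  n <- nrow(psi); m <- ncol(psi)
  dx <- wrap_to_pi(psi[-1, , drop = FALSE] - psi[-n, , drop = FALSE])
  dy <- wrap_to_pi(psi[, -1, drop = FALSE] - psi[, -m, drop = FALSE])
  rho <- matrix(0, n, m)
  rho <- rho + rbind(dx, 0) - rbind(0, dx)
  rho <- rho + cbind(dy, 0) - cbind(0, dy)
  Tn <- dct_matrix(n); Tm <- dct_matrix(m)
  R <- Tn %*% rho %*% t(Tm)
  denom <- outer(2 * cos(pi * (seq_len(n) - 1) / n) - 2,
                 2 * cos(pi * (seq_len(m) - 1) / m) - 2, "+")
  denom[1, 1] <- 1
  R <- R / denom
  R[1, 1] <- 0
  t(Tn) %*% R %*% Tm
}

# orthonormal DCT-II matrix: (C %*% x) is the DCT of x, t(C) the inverse
dct_matrix <- function(n) {
  k <- seq_len(n) - 1
  C <- cos(pi * outer(k, k + 0.5) / n) * sqrt(2 / n)
  C[1, ] <- sqrt(1 / n)
  C
}

#' Subtract the instrumental background phase
#'
#' Fits a first-order plane (tilt + offset) to a cell-free region and
#' subtracts it from the whole map, then removes the residual median over
#' that region so the background sits at zero. In `"auto"` mode the
#' background region is taken as the pixels whose residual after a
#' whole-image plane fit lies below the 20th percentile.
#'
#' @param pm a [phase_map()] (typically unwrapped).
#' @param cell_free_region `"auto"` or a logical matrix marking background
#'   pixels; must select at least one pixel.
#' @return A [phase_map()] with `background_corrected = TRUE`; the median
#'   phase over the background region is zero to within 0.02 rad.
#' @export
subtract_background <- function(pm, cell_free_region = "auto") {
  stopifnot(inherits(pm, "phase_map"))
  n <- nrow(pm$phase); m <- ncol(pm$phase)
  X <- matrix(rep(seq_len(n), m), n, m)
  Y <- matrix(rep(seq_len(m), each = n), n, m)
  if (identical(cell_free_region, "auto")) {
    res <- fit_plane_residual(pm$phase, X, Y, NULL)
    bg <- res <= stats::quantile(res, 0.2)
  } else {
    bg <- cell_free_region
    stopifnot(is.logical(bg), all(dim(bg) == dim(pm$phase)))
  }
  if (!any(bg)) stop("background region is empty", call. = FALSE)
  corrected <- fit_plane_residual(pm$phase, X, Y, bg)
  corrected <- corrected - stats::median(corrected[bg])
  phase_map(corrected, pm$pixel_size, pm$wavelength,
            background_corrected = TRUE)
}

# residual of a least-squares plane fitted on `on` (NULL = all pixels),
# evaluated everywhere
fit_plane_residual <- function(z, X, Y, on) {
  if (is.null(on)) on <- rep(TRUE, length(z))
  A <- cbind(1, X[on], Y[on])
  coef <- stats::.lm.fit(A, z[on])$coefficients
  z - (coef[1] + coef[2] * X + coef[3] * Y)
}
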