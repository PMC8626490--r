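#' HARP filter specification
#'
#' A Gaussian bandpass in k-space centred at the positive harmonic peak of
#' the tag carrier. The full width at half maximum (FWHM) is given in
#' k-space pixels; the Gaussian sigma is `FWHM / (2 sqrt(2 log 2))`. The
#' classic filter widths studied range from 8 to 28 pixels.
#'
#' @param direction `"x"` (vertical tag lines, carrier along x) or `"y"`.
#' @param fwhm filter FWHM in k-space pixels.
#' @param tag_spacing tag spacing in mm.
#' @param pixel_spacing pixel spacing in mm.
#' @param n image matrix size (needed to place the carrier in k-space).
#' @return list of class `harp_filter_spec`.
#' @export
harp_filter_spec <- function(direction = c("x", "y"), fwhm = 16,
                             tag_spacing = 8, pixel_spacing = 1.1, n = 256) {
  direction <- match.arg(direction)
  if (fwhm <= 0) stopf("FWHM must be > 0")
  carrier_px <- n * pixel_spacing / tag_spacing  # cycles across the image
  if (carrier_px >= n / 2) stopf("tag carrier outside the Nyquist band")
  structure(list(direction = direction, fwhm = fwhm,
                 sigma = fwhm / (2 * sqrt(2 * log(2))),
                 omega_d = 2 * pi / tag_spacing,
                 carrier_px = carrier_px,
                 pixel_spacing = pixel_spacing, n = n),
            class = "harp_filter_spec")
}

#' Isolate the positive spectral harmonic of a tagged image
#'
#' FFT the image, multiply by an isotropic Gaussian bandpass centred at the
#' positive harmonic peak `+omega_d n_d`, and inverse FFT. The result is the
#' complex harmonic image whose wrapped phase is (up to filtering error) the
#' material tag phase `omega_d X . n_d`.
#'
#' @param img real or complex image matrix.
#' @param spec a [harp_filter_spec()].
#' @return list of class `harmonic_image`: `values` (complex matrix),
#'   `phase` (wrapped into (-pi, pi\]), `magnitude`.
#' @export
harmonic_filter <- function(img, spec) {
  n1 <- nrow(img); n2 <- ncol(img)
  # signed integer frequencies along rows (y) and columns (x)
  fr <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1)
  fc <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1)
  kc <- if (spec$direction == "x") spec$carrier_px * n2 / spec$n else 0
  kr <- if (spec$direction == "y") spec$carrier_px * n1 / spec$n else 0
  # distances in k-pixels of the *spec* grid (sigma is defined there)
  dr <- (fr - kr) * spec$n / n1
  dc <- (fc - kc) * spec$n / n2
  H <- exp(-(outer(dr^2, dc^2, `+`)) / (2 * spec$sigma^2))
  Fk <- stats::fft(img)
  vals <- stats::fft(Fk * H, inverse = TRUE) / (n1 * n2)
  structure(list(values = vals, phase = Arg(vals), magnitude = Mod(vals),
                 spec = spec),
            class = "harmonic_image")
}

#' Gradient of a wrapped phase map
#'
#' Finite differences taken modulo 2 pi: each raw difference is wrapped into
#' (-pi, pi\] before dividing by the pixel spacing, making the gradient
#' insensitive to 2 pi phase jumps. Central differences in the interior,
#' one-sided at borders. Slopes above pi per pixel alias (documented limit).
#'
#' @param phase matrix of wrapped phase values in (-pi, pi\].
#' @param spacing pixel spacing in mm.
#' @return list `d_dx`, `d_dy` in rad/mm.
#' @export
wrapped_phase_gradient <- function(phase, spacing) {
  list(d_dx = fd_axis(phase, spacing, "x", wrap = TRUE),
       d_dy = fd_axis(phase, spacing, "y", wrap = TRUE))
}

#' Inverse deformation gradient from two harmonic phases
#'
#' The harmonic phase is a material property, `phi_d = omega_d X . n_d`, so
#' its spatial gradient gives a row of the inverse deformation gradient:
#' `grad phi_d = omega_d (row d of F^-1)`. With two perpendicular tag
#' directions the full G = F^-1 is assembled: row 1 from the x-encoding
#' phase (vertical tag lines, image `I_v`), row 2 from the y-encoding phase
#' (horizontal lines, `I_h`).
#'
#' @param phase_x,phase_y wrapped phase maps encoding `X . x-hat` and
#'   `X . y-hat`.
#' @param omega tag carrier frequency in rad/mm.
#' @param spacing pixel spacing in mm.
#' @return list `f11`, `f12`, `f21`, `f22` holding G (inverse form).
#' @export
inverse_gradient_from_phases <- function(phase_x, phase_y, omega, spacing) {
  gx <- wrapped_phase_gradient(phase_x, spacing)
  gy <- wrapped_phase_gradient(phase_y, spacing)
  list(f11 = gx$d_dx / omega, f12 = gx$d_dy / omega,
       f21 = gy$d_dx / omega, f22 = gy$d_dy / omega)
}

#' HARP principal strain estimation from a tagged frame pair
#'
#' The full bandpass pipeline: harmonic filtering of each tag direction,
#' wrapped phase gradients, inverse deformation gradient, Eulerian strain
#' `e = (I - G'G)/2`, and principal decomposition. Strain is computed
#' frame-by-frame directly from phase gradients (Eulerian), with no
#' temporal tracking, and the output maps keep the input's native
#' resolution.
#'
#' @param pair a `tagged_pair` (fields `I_h`, `I_v`, `pixel_spacing`,
#'   `tag_spacing`).
#' @param fwhm bandpass FWHM in k-space pixels (8, 12, 16, 20, 24, 28 in
#'   the classic sweep); the FWHM is interpreted on a 256-cell k-space grid
#'   so a physical filter width carries across matrix sizes.
#' @return a `principal_strain`.
#' @export
harp_strain <- function(pair, fwhm = 16) {
  n <- nrow(pair$I_v)
  spec_x <- harp_filter_spec("x", fwhm, pair$tag_spacing, pair$pixel_spacing,
                             n = 256)
  spec_y <- harp_filter_spec("y", fwhm, pair$tag_spacing, pair$pixel_spacing,
                             n = 256)
  hx <- harmonic_filter(pair$I_v, spec_x)
  hy <- harmonic_filter(pair$I_h, spec_y)
  g <- inverse_gradient_from_phases(hx$phase, hy$phase,
                                    spec_x$omega_d, pair$pixel_spacing)
  principal_decomposition(strain_from_inverse_gradient(g))
}
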