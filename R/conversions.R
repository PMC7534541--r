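#' Angle, momentum-transfer and energy conversions
#'
#' Scalar conversions used throughout the pipeline. The momentum transfer is
#' defined as \eqn{s = 4\pi \sin(\theta)/\lambda} where \eqn{2\theta} is the
#' scattering angle and \eqn{\lambda} the X-ray wavelength, and real-space
#' spacings follow \eqn{d = 2\pi/s}. All functions are vectorised.
#'
#' @param energy Photon energy in keV.
#' @param two_theta Scattering angle \eqn{2\theta} in degrees, in `[0, 180)`.
#' @param s Momentum transfer in inverse Angstrom.
#' @param d Real-space spacing in Angstrom.
#' @param wavelength X-ray wavelength in Angstrom.
#' @return A numeric vector in the units named by the function.
#' @examples
#' wavelength_from_energy(10)        # 1.23984 A, the 10 keV beamline setting
#' s_from_two_theta(2, 1.24)         # ~0.1769 1/A
#' d_from_s(2 * pi)                  # 1 A
#' @name conversions
NULL

# hc in keV * Angstrom
.hc_keV_A <- 12.3984

#' @rdname conversions
#' @export
wavelength_from_energy <- function(energy) {
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    stop("photon energy must be positive and finite", call. = FALSE)
  }
  .hc_keV_A / energy
}

#' @rdname conversions
#' @export
energy_from_wavelength <- function(wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive", call. = FALSE)
  .hc_keV_A / wavelength
}

#' @rdname conversions
#' @export
s_from_two_theta <- function(two_theta, wavelength) {
  if (any(two_theta < 0) || any(two_theta >= 180)) {
    stop("two_theta must lie in [0, 180) degrees", call. = FALSE)
  }
  if (any(wavelength <= 0)) stop("wavelength must be positive", call. = FALSE)
  4 * pi * sin(two_theta * pi / 360) / wavelength
}

#' @rdname conversions
#' @export
two_theta_from_s <- function(s, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive", call. = FALSE)
  x <- s * wavelength / (4 * pi)
  if (any(s < 0) || any(x > 1)) {
    stop("s outside the representable range for this wavelength", call. = FALSE)
  }
  2 * asin(x) * 180 / pi
}

#' @rdname conversions
#' @export
d_from_s <- function(s) {
  if (any(s <= 0)) stop("s must be positive", call. = FALSE)
  2 * pi / s
}

#' @rdname conversions
#' @export
s_from_d <- function(d) {
  if (any(d <= 0)) stop("d must be positive", call. = FALSE)
  2 * pi / d
}

#' @rdname conversions
#' @export
two_theta_from_d <- function(d, wavelength) {
  # Bragg's law: lambda = 2 d sin(theta)
  x <- wavelength / (2 * d)
  if (any(d <= 0) || any(x > 1)) stop("d out of range for Bragg reflection", call. = FALSE)
  2 * asin(x) * 180 / pi
}

#' @rdname conversions
#' @export
d_from_two_theta <- function(two_theta, wavelength) {
  if (any(two_theta <= 0) || any(two_theta >= 180)) {
    stop("two_theta must lie in (0, 180)", call. = FALSE)
  }
  wavelength / (2 * sin(two_theta * pi / 360))
}
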