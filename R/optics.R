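#' Optical configuration of a static light-scattering instrument
#'
#' Bundles the illumination wavelength and the refractive index of the
#' suspending medium. The defaults describe a helium-neon laser
#' (632.8 nm) in water, the configuration of a typical laser
#' granulometer used for activated-sludge work.
#'
#' @param wavelength_um Illumination wavelength in micrometres. Must be
#'   positive. Default `0.6328` (He-Ne laser).
#' @param medium_refractive_index Refractive index of the suspending
#'   medium (dimensionless, >= 1). Default `1.33` (water).
#'
#' @return An object of class `optical_config`: a list with elements
#'   `wavelength_um` and `medium_refractive_index`.
#' @examples
#' optics <- optical_config()
#' q_from_angle(90, optics)
#' @export
optical_config <- function(wavelength_um = 0.6328,
                           medium_refractive_index = 1.33) {
  if (!is.numeric(wavelength_um) || length(wavelength_um) != 1L ||
      !is.finite(wavelength_um) || wavelength_um <= 0) {
    stop("`wavelength_um` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(medium_refractive_index) ||
      length(medium_refractive_index) != 1L ||
      !is.finite(medium_refractive_index) || medium_refractive_index < 1) {
    stop("`medium_refractive_index` must be a single number >= 1",
         call. = FALSE)
  }
  structure(
    list(wavelength_um = wavelength_um,
         medium_refractive_index = medium_refractive_index),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  wavelength: %.4f um\n", x$wavelength_um))
  cat(sprintf("  medium refractive index: %.3f\n", x$medium_refractive_index))
  invisible(x)
}

#' Scattering-vector magnitude from scattering angle
#'
#' Converts a scattering angle, measured from the forward optical axis,
#' into the magnitude of the scattering (momentum-transfer) vector
#' \eqn{q = 4 \pi n \sin(\theta/2) / \lambda}, the standard bridge
#' between angle-resolved detector readings and structural length
#' scales (\eqn{~1/q}).
#'
#' @param theta_deg Scattering angle(s) in degrees, in `[0, 180]`.
#' @param optics An [optical_config()] object.
#'
#' @return Scattering-vector magnitude(s) in inverse micrometres; `0`
#'   exactly at `theta_deg = 0`, strictly increasing in the angle.
#' @examples
#' q_from_angle(c(0, 90, 180), optical_config())
#' @export
q_from_angle <- function(theta_deg, optics = optical_config()) {
  stopifnot(inherits(optics, "optical_config"))
  if (!is.numeric(theta_deg) || any(!is.finite(theta_deg))) {
    stop("`theta_deg` must be finite numeric", call. = FALSE)
  }
  if (any(theta_deg < 0 | theta_deg > 180)) {
    stop("scattering angle must lie in [0, 180] degrees", call. = FALSE)
  }
  theta_rad <- theta_deg * pi / 180
  4 * pi * optics$medium_refractive_index * sin(theta_rad / 2) /
    optics$wavelength_um
}
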