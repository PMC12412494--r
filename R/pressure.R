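# Calibrated intracompartmental pressure from the raw barometer channel.
# The device's internal compensation is out of scope; the model here is an
# affine gain/offset with a linear residual temperature coefficient, plus a
# hydrostatic water-column fit for bench calibration.

STANDARD_GRAVITY <- 9.80665

#' Pressure channel calibration
#'
#' Affine calibration with linear residual temperature compensation:
#' `icp = gain * raw - offset - temp_coeff * (t_dev - t_ref)`.
#'
#' @param offset additive offset in mmHg.
#' @param gain dimensionless gain, > 0.
#' @param temp_coeff residual temperature coefficient in mmHg/K.
#' @param t_ref reference device temperature in Kelvin.
#' @return object of class `pressure_calibration`.
#' @export
pressure_calibration <- function(offset = 0, gain = 1, temp_coeff = 0,
                                 t_ref = 310.15) {
  if (!is.finite(gain) || gain <= 0)
    abort("gain must be finite and > 0", "acs_config_error")
  structure(list(offset = offset, gain = gain, temp_coeff = temp_coeff,
                 t_ref = t_ref),
            class = "pressure_calibration")
}

#' Calibrate a raw pressure stream
#'
#' @param raw raw readings in mmHg-equivalent counts (vectorised).
#' @param t_dev device temperature in Kelvin (scalar or vector).
#' @param cal a [pressure_calibration()].
#' @return intracompartmental pressure in mmHg.
#' @examples
#' calibrate_pressure(75, 310.15, pressure_calibration(offset = 5))
#' @export
calibrate_pressure <- function(raw, t_dev = 310.15,
                               cal = pressure_calibration()) {
  stopifnot(inherits(cal, "pressure_calibration"))
  cal$gain * raw - cal$offset - cal$temp_coeff * (t_dev - cal$t_ref)
}

#' Fit a calibration from a hydrostatic water column
#'
#' Regresses raw readings against the reference hydrostatic pressure
#' `P = rho * g * h` (converted to mmHg) and returns the gain/offset that
#' map readings back onto the reference: `gain = 1/slope`,
#' `offset = intercept/slope`.
#'
#' @param depths water depths in m (>= 2 distinct values).
#' @param readings raw sensor readings in mmHg-equivalent units.
#' @param fluid_density fluid density in kg/m^3 (default water, 1000).
#' @return a [pressure_calibration()] with the fit residuals (mmHg) and the
#'   reference pressures attached as attributes `residuals` and `p_ref`.
#' @examples
#' cal <- fit_hydrostatic(c(0, 0.1, 0.2), pa_to_mmhg(1000 * 9.80665 * c(0, 0.1, 0.2)))
#' c(cal$gain, cal$offset)
#' @export
fit_hydrostatic <- function(depths, readings, fluid_density = 1000) {
  if (length(depths) != length(readings) || length(depths) < 2 ||
      length(unique(depths)) < 2)
    abort("need >= 2 distinct depths", "acs_fit_error")
  p_ref <- pa_to_mmhg(fluid_density * STANDARD_GRAVITY * depths)
  fit <- stats::lm(readings ~ p_ref)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    abort("degenerate hydrostatic fit (nonpositive slope)", "acs_fit_error")
  cal <- pressure_calibration(offset = unname(stats::coef(fit)[1]) / slope,
                              gain = 1 / slope)
  attr(cal, "residuals") <- unname(stats::residuals(fit)) / slope
  attr(cal, "p_ref") <- p_ref
  cal
}
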