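# Thermal-anemometry flow sensing: four NTC thermistors downstream of a
# resistive heater. The heater raises local temperature; convective cooling
# by perfusing blood reduces the steady temperature excess DT at each
# thermistor, so DT decreases monotonically with flow velocity u:
#
#   DT(r) = (q R / lambda) * F(r/R) / (1 + 0.76 s u R / alpha_fluid)
#
# with F the Bessel shape factor (see shape_factor.R). At u = 0 this reduces
# to pure conduction. Absolute magnitudes depend on unpublished device
# constants, so outputs are interpreted as relative flow trends.

#' NTC thermistor calibration
#'
#' Beta-model (`T = 1 / (1/t0 + ln(R/r0)/beta)`) or affine resistance-to-
#' temperature calibration for the flow sensor's negative-temperature-
#' coefficient thermistors (nominal B = 3380 K, 10 kOhm at 25 C).
#'
#' @param beta beta constant in Kelvin (> 0).
#' @param r0 nominal resistance in Ohm at `t0` (> 0).
#' @param t0 reference temperature in Kelvin.
#' @param mode "beta_model" or "linear". The linear mode is an affine map
#'   `T = intercept + slope * R` fitted over the physiological range
#'   (30-40 C); its slope must be negative (NTC).
#' @param slope,intercept affine coefficients, required in linear mode.
#' @return an object of class `ntc_calibration`.
#' @export
ntc_calibration <- function(beta = 3380, r0 = 10000, t0 = 298.15,
                            mode = c("beta_model", "linear"),
                            slope = NULL, intercept = NULL) {
  mode <- match.arg(mode)
  stopifnot(beta > 0, r0 > 0, t0 > 0)
  if (mode == "linear") {
    if (is.null(slope) || is.null(intercept))
      abort("linear mode needs slope and intercept", "acs_config_error")
    if (slope >= 0)
      abort("NTC linear calibration must have negative slope",
            "acs_config_error")
  }
  structure(list(beta = beta, r0 = r0, t0 = t0, mode = mode,
                 slope = slope, intercept = intercept),
            class = "ntc_calibration")
}

#' Convert thermistor resistance to temperature
#'
#' Monotone decreasing in resistance. In beta mode the exact inverse is
#' [temperature_to_resistance()].
#'
#' @param resistance resistance in Ohm, > 0 (vectorised).
#' @param cal an [ntc_calibration()].
#' @return temperature in Kelvin.
#' @examples
#' ntc_to_temperature(10000, ntc_calibration())  # 298.15 K by construction
#' @export
ntc_to_temperature <- function(resistance, cal = ntc_calibration()) {
  stopifnot(inherits(cal, "ntc_calibration"))
  if (any(!is.finite(resistance)) || any(resistance <= 0))
    abort("resistance must be finite and > 0", "acs_input_error")
  if (cal$mode == "linear") return(cal$intercept + cal$slope * resistance)
  1 / (1 / cal$t0 + log(resistance / cal$r0) / cal$beta)
}

#' @rdname ntc_to_temperature
#' @param temperature temperature in Kelvin, > 0.
#' @export
temperature_to_resistance <- function(temperature, cal = ntc_calibration()) {
  stopifnot(inherits(cal, "ntc_calibration"))
  if (any(temperature <= 0))
    abort("temperature must be > 0", "acs_input_error")
  if (cal$mode == "linear") return((temperature - cal$intercept) / cal$slope)
  cal$r0 * exp(cal$beta * (1 / temperature - 1 / cal$t0))
}

#' Thermal transport model parameters
#'
#' Houses the constants of the flow-inversion model and the probe geometry.
#' None of the deployed device's values are published; the defaults are
#' representative soft-tissue/blood literature values and datasheet-scale
#' heater figures, and every entry is configurable. Distances default to
#' `r = (0.5, 6.5, 7.25, 8) mm`: the probe places the thermistors at 16,
#' 22.5, 23.25 and 24 mm from the oximeter with the heater just behind the
#' first one, and the first distance is floored at 0.5 mm to stay out of the
#' near field.
#'
#' @param q_heat heater heat flux in W/m^2.
#' @param big_r heat-spreader radius R in m.
#' @param k_tissue effective tissue thermal conductivity lambda in W/(m K).
#' @param alpha_fluid blood thermal diffusivity in m^2/s.
#' @param s_blood dimensionless blood content.
#' @param r_list per-thermistor distance from the heater in m, ascending.
#' @return an object of class `thermal_model_params`.
#' @export
thermal_model_params <- function(q_heat = 870, big_r = 2e-3, k_tissue = 0.5,
                                 alpha_fluid = 1.35e-7, s_blood = 0.05,
                                 r_list = c(0.5, 6.5, 7.25, 8) * 1e-3) {
  vals <- c(q_heat, big_r, k_tissue, alpha_fluid, s_blood, r_list)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all thermal parameters must be finite and > 0", "acs_config_error")
  if (is.unsorted(r_list, strictly = TRUE))
    abort("r_list must be strictly ascending", "acs_geometry_error")
  structure(list(q_heat = q_heat, big_r = big_r, k_tissue = k_tissue,
                 alpha_fluid = alpha_fluid, s_blood = s_blood,
                 r_list = r_list),
            class = "thermal_model_params")
}

# 0.76 s u R / alpha with u in mm/s and SI elsewhere.
flow_group <- function(u, tp) 0.76 * tp$s_blood * (u * 1e-3) * tp$big_r / tp$alpha_fluid

#' Forward thermal model: temperature excess at a thermistor
#'
#' Steady-state temperature rise above baseline at distance `r` from the
#' heater for flow velocity `u`; strictly decreasing in `u`, equal to
#' `(q R / lambda) F(r/R)` at `u = 0`.
#'
#' @param u flow velocity in mm/s, >= 0 (vectorised).
#' @param tp a [thermal_model_params()].
#' @param r thermistor distance in m (scalar).
#' @return temperature excess in Kelvin.
#' @export
forward_delta_t <- function(u, tp = thermal_model_params(), r) {
  stopifnot(inherits(tp, "thermal_model_params"))
  if (any(u < 0)) abort("u must be >= 0", "acs_input_error")
  if (r <= 0) abort("r must be > 0", "acs_geometry_error")
  amp <- tp$q_heat * tp$big_r / tp$k_tissue * shape_factor(r, tp$big_r)
  amp / (1 + flow_group(u, tp))
}

# Conduction amplitudes (q R / lambda) F(r_i/R) for all thermistors.
thermal_amplitudes <- function(tp) {
  tp$q_heat * tp$big_r / tp$k_tissue *
    shape_factor(tp$r_list, tp$big_r)
}

#' Invert the thermal model for flow velocity
#'
#' Least-squares fit of [forward_delta_t()] across the available thermistor
#' channels, over `u >= 0`. The residual sum of squares is linear in
#' `g = 1/(1 + 0.76 s u R / alpha)`, so the bounded scalar minimisation has
#' a closed-form optimum which is used to bracket `stats::optimize`; on
#' noiseless forward data the recovery is exact to optimiser tolerance.
#'
#' @param delta_t temperature excess per thermistor in Kelvin (length of
#'   `tp$r_list`); `NA` marks dropped channels.
#' @param tp a [thermal_model_params()].
#' @param u_max upper search bound in mm/s.
#' @return list with `u_hat` (mm/s), `residual` (RSS, K^2), `boundary`
#'   (TRUE when the optimum sits on a search bound) and `n_channels`.
#' @examples
#' tp <- thermal_model_params()
#' dt <- vapply(tp$r_list, function(r) forward_delta_t(2, tp, r), 1)
#' invert_flow(dt, tp)$u_hat
#' @export
invert_flow <- function(delta_t, tp = thermal_model_params(), u_max = 50) {
  stopifnot(inherits(tp, "thermal_model_params"))
  ok <- is.finite(delta_t)
  if (!any(ok)) abort("all thermistor channels missing", "acs_missing_data")
  A <- thermal_amplitudes(tp)[ok]
  d <- delta_t[ok]
  beta1 <- flow_group(1, tp)  # group factor per unit (mm/s)
  g_star <- sum(A * d) / sum(A^2)
  boundary <- FALSE
  if (g_star >= 1) {
    u0 <- 0
    boundary <- g_star > 1 + 1e-9
  } else if (g_star <= 1 / (1 + beta1 * u_max)) {
    u0 <- u_max
    boundary <- TRUE
  } else u0 <- (1 / g_star - 1) / beta1
  rss <- function(u) sum((A / (1 + beta1 * u) - d)^2)
  lo <- max(0, 0.5 * u0 - 1e-6)
  hi <- min(u_max, 2 * u0 + 1e-6)
  opt <- stats::optimize(rss, c(lo, hi), tol = 1e-12)
  u_hat <- if (opt$objective <= rss(u0)) opt$minimum else u0
  if (u_hat < 1e-10) u_hat <- if (rss(0) <= rss(u_hat)) 0 else u_hat
  list(u_hat = u_hat, residual = rss(u_hat), boundary = boundary,
       n_channels = sum(ok))
}

# Vectorised closed-form inversion for a matrix of per-sample temperature
# excesses (rows = samples, cols = thermistors); used on long traces.
invert_flow_series <- function(delta_t_mat, tp = thermal_model_params(),
                               u_max = 50) {
  stopifnot(inherits(tp, "thermal_model_params"))
  A <- thermal_amplitudes(tp)
  beta1 <- flow_group(1, tp)
  W <- is.finite(delta_t_mat)
  D <- delta_t_mat; D[!W] <- 0
  num <- as.numeric(D %*% A)
  den <- as.numeric(W %*% A^2)
  g <- ifelse(den > 0, num / den, NA_real_)
  u <- (1 / pmin(pmax(g, 1 / (1 + beta1 * u_max)), 1) - 1) / beta1
  u[!is.finite(g)] <- NA_real_
  u
}

#' Relative flow index from the outer thermistor pair
#'
#' `DT14 = T1 - T4`, the temperature difference between the thermistor
#' nearest the heater and the farthest one. Any common additive baseline
#' (local tissue temperature) cancels, and the index decreases as flow
#' increases.
#'
#' @param t1,t4 simultaneous temperature samples in Kelvin.
#' @return temperature difference in Kelvin.
#' @export
relative_flow_index <- function(t1, t4) {
  if (length(t1) != length(t4))
    abort("t1 and t4 must be simultaneous samples", "acs_input_error")
  t1 - t4
}
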