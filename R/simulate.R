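# Synthetic physiological-episode generator. Emulates the porcine
# balloon-inflation experiment: intracompartmental pressure (ICP) stepped
# 0 -> 50 -> 100 -> 150 mmHg with ~1 min ramps, inverse (clamped-linear)
# StO2 and flow responses with a delayed flow channel, cardiac pulsatility
# on the PPG, per-channel additive Gaussian sensor noise, and seeded
# determinism. Ground truth is carried alongside the raw streams so every
# inversion stage can be validated end to end.

#' Episode configuration
#'
#' The stated world of the synthetic experiment. Defaults reproduce one
#' stepped loading cycle (plateaus at 0/50/100/150 mmHg, 60 s ramps) at
#' 20 Hz with physiologically plausible couplings; all knobs are explicit.
#'
#' @param duration episode length in seconds.
#' @param sample_rate sampling rate in Hz (device default 20; low-power 1).
#' @param icp_profile data.frame with columns `start` (s), `target` (mmHg)
#'   and `ramp` (s): at `start` the pressure ramps linearly to `target`
#'   over `ramp` seconds and then holds. Times must be strictly increasing
#'   and ramps must not overlap the next segment.
#' @param dbp diastolic blood pressure in mmHg (scalar reference).
#' @param heart_rate heart rate in beats per minute.
#' @param flow_delay dead time of the flow response in seconds (thermal
#'   transport delay; drives the cross-correlation lag).
#' @param flow_lag_tau first-order lag time constant of the flow response
#'   in seconds (applied after the dead time).
#' @param sto2_baseline baseline saturation fraction in (0, 1].
#' @param flow_baseline baseline flow velocity in mm/s.
#' @param coupling_slopes named numeric `c(sto2 = , flow = )`: change of
#'   StO2 fraction / flow (mm/s) per mmHg of ICP; both must be <= 0.
#' @param noise_sd named numeric noise SDs:
#'   `pressure` (mmHg), `ppg` (intensity units), `thermistor` (K).
#' @param ac_amplitude fractional amplitude of the pulsatile PPG component
#'   (default 2% of DC).
#' @param i0 named numeric source intensities `c(red = , ir = )`, > 0.
#' @param heater_on_time time at which the flow-sensor heater switches on
#'   (s); before that all thermistors sit at tissue baseline.
#' @param tissue_temp baseline tissue temperature in Kelvin (cancels in
#'   temperature differences).
#' @param pressure_offset,pressure_temp_coeff,device_temp_drift raw
#'   pressure-channel artifact model: additive offset (mmHg), residual
#'   temperature coefficient (mmHg/K) and sinusoidal device-temperature
#'   drift amplitude (K).
#' @param seed integer RNG seed; identical configs give bit-identical
#'   output.
#' @return object of class `episode_config`.
#' @export
episode_config <- function(duration = 900,
                           sample_rate = 20,
                           icp_profile = data.frame(
                             start = c(0, 180, 420, 660),
                             target = c(0, 50, 100, 150),
                             ramp = c(0, 60, 60, 60)),
                           dbp = 70,
                           heart_rate = 80,
                           flow_delay = 15,
                           flow_lag_tau = 20,
                           sto2_baseline = 0.70,
                           flow_baseline = 5,
                           coupling_slopes = c(sto2 = -0.0015, flow = -0.03),
                           noise_sd = c(pressure = 0.3, ppg = 1e-3,
                                        thermistor = 0.01),
                           ac_amplitude = 0.02,
                           i0 = c(red = 1, ir = 1),
                           heater_on_time = 30,
                           tissue_temp = 310.15,
                           pressure_offset = 5,
                           pressure_temp_coeff = 0.2,
                           device_temp_drift = 0.5,
                           seed = 1L) {
  if (sample_rate <= 0) abort("sample_rate must be > 0", "acs_config_error")
  if (duration <= 0) abort("duration must be > 0", "acs_config_error")
  if (nrow(icp_profile)) {
    if (is.unsorted(icp_profile$start, strictly = TRUE))
      abort("icp_profile times must be strictly increasing",
            "acs_config_error")
    if (any(icp_profile$ramp < 0))
      abort("ramp durations must be >= 0", "acs_config_error")
    ends <- icp_profile$start + icp_profile$ramp
    if (nrow(icp_profile) > 1 &&
        any(ends[-nrow(icp_profile)] > icp_profile$start[-1]))
      abort("overlapping ramp segments in icp_profile", "acs_config_error")
  }
  if (sto2_baseline <= 0 || sto2_baseline > 1)
    abort("sto2_baseline must be in (0, 1]", "acs_config_error")
  if (any(coupling_slopes > 0))
    abort("coupling slopes must be <= 0", "acs_config_error")
  if (flow_delay < 0 || flow_lag_tau < 0)
    abort("flow_delay and flow_lag_tau must be >= 0", "acs_config_error")
  if (any(i0 <= 0)) abort("source intensities must be > 0", "acs_config_error")
  structure(list(duration = duration, sample_rate = sample_rate,
                 icp_profile = icp_profile, dbp = dbp,
                 heart_rate = heart_rate, flow_delay = flow_delay,
                 flow_lag_tau = flow_lag_tau,
                 sto2_baseline = sto2_baseline,
                 flow_baseline = flow_baseline,
                 coupling_slopes = coupling_slopes, noise_sd = noise_sd,
                 ac_amplitude = ac_amplitude, i0 = i0,
                 heater_on_time = heater_on_time, tissue_temp = tissue_temp,
                 pressure_offset = pressure_offset,
                 pressure_temp_coeff = pressure_temp_coeff,
                 device_temp_drift = device_temp_drift,
                 seed = as.integer(seed)),
            class = "episode_config")
}

episode_time <- function(config) {
  seq(0, config$duration, by = 1 / config$sample_rate)
}

#' Generate the ground-truth ICP trace of an episode
#'
#' Piecewise-linear ramps between exact plateau values: at each profile row
#' the pressure ramps from the previous target to the new one over the ramp
#' duration, then holds.
#'
#' @param config an [episode_config()].
#' @return an [mc_trace()] with channel `icp` in mmHg (noise-free ground
#'   truth).
#' @examples
#' cfg <- episode_config(duration = 240, icp_profile = data.frame(
#'   start = c(0, 60, 120, 180), target = c(0, 50, 100, 150),
#'   ramp = c(0, 30, 30, 30)))
#' max(trace_channel(generate_icp_trace(cfg), "icp"))
#' @export
generate_icp_trace <- function(config) {
  stopifnot(inherits(config, "episode_config"))
  t <- episode_time(config)
  prof <- config$icp_profile
  icp <- numeric(length(t))
  if (nrow(prof)) {
    prev <- prof$target[1]
    icp[] <- prev
    for (i in seq_len(nrow(prof))) {
      s <- prof$start[i]; tg <- prof$target[i]; rd <- prof$ramp[i]
      seg <- t >= s
      if (rd > 0) {
        frac <- clamp((t[seg] - s) / rd, 0, 1)
        icp[seg] <- prev + frac * (tg - prev)
      } else icp[seg] <- tg
      prev <- tg
    }
  }
  mc_trace(t, list(icp = icp), c(icp = "mmHg"),
           sample_rate = config$sample_rate,
           metadata = list(stage = "ground_truth", seed = config$seed))
}

#' Derive ground-truth physiology from an ICP trace
#'
#' Clamped-linear inverse couplings: `sto2 = clamp(s0 + m_s * icp, 0, 1)`
#' and `u = max(0, u0 + m_u * icp)` with the flow channel passed through a
#' pure dead time (`flow_delay`) and a first-order lag (`flow_lag_tau`).
#' Concentration changes redistribute oxygenation at fixed total
#' hemoglobin: `d_hbo2 = (sto2 - s0) * total`, `d_hb = -d_hbo2`.
#'
#' @param icp an [mc_trace()] with channel `icp`, or a numeric vector on
#'   the episode time base.
#' @param config an [episode_config()].
#' @param hs a [hemo_state()]; defaults to the config's baseline.
#' @return list of class `ground_truth` with `time`, `icp`, `u`, `sto2`,
#'   `d_hbo2`, `d_hb`.
#' @export
derive_physiology <- function(icp, config, hs = NULL) {
  stopifnot(inherits(config, "episode_config"))
  if (inherits(icp, "mc_trace")) {
    t <- icp$time
    icp <- trace_channel(icp, "icp")
  } else t <- episode_time(config)[seq_along(icp)]
  if (any(!is.finite(icp))) abort("icp must be finite", "acs_input_error")
  if (is.null(hs)) hs <- hemo_state(sto2_baseline = config$sto2_baseline)
  dt <- 1 / config$sample_rate
  sto2 <- clamp(config$sto2_baseline +
                  config$coupling_slopes[["sto2"]] * icp, 0, 1)
  u_drive <- pmax(0, config$flow_baseline +
                    config$coupling_slopes[["flow"]] * icp)
  shift <- round(config$flow_delay / dt)
  u_del <- if (shift > 0)
    c(rep(u_drive[1], min(shift, length(u_drive))),
      u_drive[seq_len(max(0, length(u_drive) - shift))])
  else u_drive
  u <- first_order_lag(u_del, dt, config$flow_lag_tau)
  total <- hs$hbo2_0 + hs$hb_0
  d_hbo2 <- (sto2 - hs$sto2_baseline) * total
  structure(list(time = t, icp = icp, u = u, sto2 = sto2,
                 d_hbo2 = d_hbo2, d_hb = -d_hbo2, hs = hs),
            class = "ground_truth")
}

#' Synthesise raw dual-wavelength PPG intensities
#'
#' Forward model of the Beer-Lambert chain:
#' `I(l, t) = I0(l) exp(-q DPF(l) [eps_HbO2(l) dHbO2 + eps_Hb(l) dHb])`
#' modulated by a pulsatile sinusoid at the heart rate and additive
#' Gaussian noise. Log-linear in the concentration changes, so a noiseless
#' zero-AC trace inverts exactly.
#'
#' @param gt a `ground_truth` from [derive_physiology()].
#' @param oc an [optical_constants()].
#' @param config an [episode_config()].
#' @return an [mc_trace()] with channels `ppg_red`, `ppg_ir`.
#' @export
forward_ppg <- function(gt, oc = optical_constants(), config) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "episode_config"))
  if (any(config$i0 <= 0))
    abort("source intensities must be > 0", "acs_config_error")
  t <- gt$time
  puls <- 1 + config$ac_amplitude * sin(2 * pi * config$heart_rate / 60 * t)
  chans <- with_seed(config$seed + 1L, {
    lapply(c(red = 1L, ir = 2L), function(k) {
      od <- oc$d_led_pd * oc$dpf[k] *
        (oc$eps_hbo2[k] * gt$d_hbo2 + oc$eps_hb[k] * gt$d_hb)
      config$i0[k] * exp(-od) * puls +
        stats::rnorm(length(t), 0, config$noise_sd[["ppg"]])
    })
  })
  mc_trace(t, list(ppg_red = chans$red, ppg_ir = chans$ir),
           c(ppg_red = "a.u.", ppg_ir = "a.u."),
           sample_rate = config$sample_rate,
           metadata = list(stage = "raw_ppg", seed = config$seed))
}

#' Synthesise the four thermistor channels and heater schedule
#'
#' While the heater is on, each thermistor reads the tissue baseline plus
#' the forward thermal-model excess for the instantaneous ground-truth
#' flow; while off it reads the baseline alone. The common baseline cancels
#' in temperature differences. Additive Gaussian noise per channel.
#'
#' @param gt a `ground_truth`.
#' @param tp a [thermal_model_params()].
#' @param config an [episode_config()].
#' @return an [mc_trace()] with channels `t1`..`t4` (K) and `heater` (0/1).
#' @export
forward_thermistors <- function(gt, tp = thermal_model_params(), config) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "episode_config"))
  t <- gt$time
  heater <- as.numeric(t >= config$heater_on_time)
  amps <- thermal_amplitudes(tp)
  gain <- 1 / (1 + flow_group(gt$u, tp))
  chans <- with_seed(config$seed + 2L, {
    lapply(seq_along(tp$r_list), function(i) {
      config$tissue_temp + heater * amps[i] * gain +
        stats::rnorm(length(t), 0, config$noise_sd[["thermistor"]])
    })
  })
  names(chans) <- paste0("t", seq_along(chans))
  units <- stats::setNames(rep("K", length(chans)), names(chans))
  chans$heater <- heater
  mc_trace(t, chans, c(units, heater = "on/off"),
           sample_rate = config$sample_rate,
           metadata = list(stage = "raw_thermistors", seed = config$seed,
                           heater_on_time = config$heater_on_time))
}

#' Synthesise the raw pressure and device-temperature channels
#'
#' `raw = icp + offset + temp_coeff * (T_dev - t_ref) + noise`, with a slow
#' sinusoidal device-temperature drift, emulating the uncompensated
#' residual behaviour of the barometer channel.
#'
#' @param gt a `ground_truth`.
#' @param config an [episode_config()].
#' @param t_ref reference temperature of the calibration (K).
#' @return an [mc_trace()] with channels `pressure_raw` (mmHg),
#'   `temp_device` (K).
#' @export
forward_pressure <- function(gt, config, t_ref = 310.15) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "episode_config"))
  t <- gt$time
  t_dev <- t_ref + config$device_temp_drift * sin(2 * pi * t / 600)
  raw <- with_seed(config$seed + 3L,
    gt$icp + config$pressure_offset +
      config$pressure_temp_coeff * (t_dev - t_ref) +
      stats::rnorm(length(t), 0, config$noise_sd[["pressure"]]))
  mc_trace(t, list(pressure_raw = raw, temp_device = t_dev),
           c(pressure_raw = "mmHg", temp_device = "K"),
           sample_rate = config$sample_rate,
           metadata = list(stage = "raw_pressure", seed = config$seed,
                           t_ref = t_ref))
}

#' Simulate a full multimodal episode
#'
#' Runs the ground-truth and all three forward sensor models under one
#' seed.
#'
#' @param config an [episode_config()].
#' @param oc,tp,hs sensor constants; defaults as in the component
#'   constructors (the hemoglobin baseline follows the config).
#' @return list with `config`, `ground_truth` and the raw traces
#'   `pressure`, `ppg`, `thermistors`.
#' @export
simulate_episode <- function(config = episode_config(),
                             oc = optical_constants(),
                             tp = thermal_model_params(),
                             hs = NULL) {
  gt_icp <- generate_icp_trace(config)
  gt <- derive_physiology(gt_icp, config, hs = hs)
  list(config = config,
       ground_truth = gt,
       pressure = forward_pressure(gt, config),
       ppg = forward_ppg(gt, oc, config),
       thermistors = forward_thermistors(gt, tp, config))
}
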