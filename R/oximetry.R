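# Reflection-mode tissue oximetry from dual-wavelength (660/880 nm) PPG:
# optical densities OD = -ln(I_t/I0), AC/DC separation at 0.1 Hz, modified
# Beer-Lambert inversion of the 2x2 extinction system for concentration
# changes of oxy- and deoxyhemoglobin, and StO2 relative to a baseline
# hemoglobin state. DPF defaults to 1 per wavelength, which scales the
# concentration changes but not the sign or trend of StO2.

#' Optical constants for dual-wavelength oximetry
#'
#' Wavelengths, molar extinction coefficients, differential pathlength
#' factors and emitter-detector separation of the reflection-mode probe.
#' Extinction defaults are the standard tabulated hemoglobin compilation
#' (Prahl/OMLC) at 660 and 880 nm in L mol^-1 cm^-1; the LED-photodiode
#' distance defaults to the integrated oximeter module's datasheet-scale
#' geometry (0.25 cm) and is configurable, as the deployed value is
#' unpublished.
#'
#' @param wavelengths two wavelengths in nm (red, infrared).
#' @param eps_hbo2,eps_hb molar extinction of HbO2 / Hb per wavelength,
#'   L mol^-1 cm^-1.
#' @param dpf differential pathlength factor per wavelength, > 0.
#' @param d_led_pd LED-to-photodetector distance in cm, > 0.
#' @return an object of class `optical_constants`.
#' @export
optical_constants <- function(wavelengths = c(red = 660, ir = 880),
                              eps_hbo2 = c(red = 319.6, ir = 1214.0),
                              eps_hb = c(red = 3226.56, ir = 726.44),
                              dpf = c(red = 1, ir = 1),
                              d_led_pd = 0.25) {
  stopifnot(length(wavelengths) == 2, length(eps_hbo2) == 2,
            length(eps_hb) == 2, length(dpf) == 2)
  if (d_led_pd <= 0 || any(dpf <= 0))
    abort("d_led_pd and dpf must be > 0", "acs_config_error")
  M <- extinction_matrix(eps_hbo2, eps_hb, dpf)
  if (!is.finite(det(M)) || abs(det(M)) < 1e-8 * prod(sqrt(rowSums(M^2))))
    abort(sprintf("extinction matrix is near-singular (det = %.3g)", det(M)),
          "acs_config_error")
  structure(list(wavelengths = wavelengths, eps_hbo2 = eps_hbo2,
                 eps_hb = eps_hb, dpf = dpf, d_led_pd = d_led_pd),
            class = "optical_constants")
}

extinction_matrix <- function(eps_hbo2, eps_hb, dpf) {
  matrix(c(eps_hbo2[1] * dpf[1], eps_hb[1] * dpf[1],
           eps_hbo2[2] * dpf[2], eps_hb[2] * dpf[2]),
         nrow = 2, byrow = TRUE)
}

#' Baseline hemoglobin state
#'
#' Total hemoglobin is split into oxygenated and deoxygenated pools by the
#' baseline saturation; the molar total is concentration / molar mass. StO2
#' computed against a nominal baseline is a relative, not absolute, measure.
#'
#' @param total_hb_conc total hemoglobin concentration in g/L (default 150).
#' @param molar_mass_hb hemoglobin molar mass in g/mol (default 64500).
#' @param sto2_baseline baseline saturation fraction in (0, 1].
#' @return object of class `hemo_state` with fields `hbo2_0`, `hb_0` (mol/L).
#' @export
hemo_state <- function(total_hb_conc = 150, molar_mass_hb = 64500,
                       sto2_baseline = 0.70) {
  stopifnot(total_hb_conc > 0, molar_mass_hb > 0)
  if (sto2_baseline <= 0 || sto2_baseline > 1)
    abort("sto2_baseline must be in (0, 1]", "acs_config_error")
  total <- total_hb_conc / molar_mass_hb
  structure(list(total_hb_conc = total_hb_conc,
                 molar_mass_hb = molar_mass_hb,
                 sto2_baseline = sto2_baseline,
                 hbo2_0 = sto2_baseline * total,
                 hb_0 = (1 - sto2_baseline) * total),
            class = "hemo_state")
}

#' Optical density of a detected intensity
#'
#' `OD = -ln(i_t / i_0)`; zero when the intensity equals its reference,
#' negative when the tissue brightens. Nonpositive intensities are masked
#' (`NA`) rather than raising an error, matching the missing-sample
#' semantics of the trace container.
#'
#' @param i_t detected intensity (vectorised).
#' @param i_0 reference intensity (scalar or vector).
#' @return dimensionless optical density.
#' @export
optical_density <- function(i_t, i_0) {
  od <- rep(NA_real_, length(i_t))
  ok <- is.finite(i_t) & is.finite(i_0) & i_t > 0 & i_0 > 0
  od[ok] <- -log(i_t[ok] / (if (length(i_0) == 1) i_0 else i_0[ok]))
  od
}

#' Invert the modified Beer-Lambert system
#'
#' Solves the 2x2 linear system
#' `(dHbO2, dHb)' = (1/q) M^-1 (OD(l1), OD(l2))'` with
#' `M = [eps_HbO2(l) * DPF(l), eps_Hb(l) * DPF(l)]` per wavelength row, for
#' the concentration changes relative to the reference window. Exactly
#' linear in the optical densities.
#'
#' @param od numeric length-2 vector `(OD_red, OD_ir)` or an n x 2 matrix.
#' @param oc an [optical_constants()].
#' @return matrix with columns `d_hbo2`, `d_hb` in mol/L.
#' @export
invert_beer_lambert <- function(od, oc = optical_constants()) {
  stopifnot(inherits(oc, "optical_constants"))
  M <- extinction_matrix(oc$eps_hbo2, oc$eps_hb, oc$dpf)
  od <- if (is.matrix(od)) od else matrix(od, ncol = 2)
  out <- t(solve(M, t(od))) / oc$d_led_pd
  colnames(out) <- c("d_hbo2", "d_hb")
  out
}

#' Tissue oxygen saturation from concentration changes
#'
#' `StO2 = (HbO2_0 + dHbO2) / (HbO2_0 + dHbO2 + Hb_0 + dHb)`, clamped to
#' `[0, 1]`; equal to the baseline saturation at zero change, and reported
#' as a relative quantity when the baseline split is nominal. Samples with a
#' nonpositive denominator are masked.
#'
#' @param d_hbo2,d_hb concentration changes in mol/L (vectorised).
#' @param hs a [hemo_state()].
#' @return saturation fraction in `[0, 1]` (NA where masked).
#' @export
compute_sto2 <- function(d_hbo2, d_hb, hs = hemo_state()) {
  stopifnot(inherits(hs, "hemo_state"))
  num <- hs$hbo2_0 + d_hbo2
  den <- num + hs$hb_0 + d_hb
  out <- ifelse(is.finite(den) & den > 0, clamp(num / den, 0, 1), NA_real_)
  as.numeric(out)
}

#' Pulse rate and variability from the AC band
#'
#' Rate is the dominant spectral peak of the pulsatile component in the
#' 0.5-4 Hz band (zero-padded periodogram with parabolic peak
#' interpolation); variability is the standard deviation of successive
#' peak-to-peak intervals, with peak times refined by quadratic
#' interpolation. Raises an `acs_no_pulse` condition when no peak stands
#' above the band's noise floor.
#'
#' @param ac pulsatile (AC) component, at least 10 s long.
#' @param sample_rate sampling rate in Hz (>= 4x the expected pulse rate).
#' @return list with `rate_bpm`, `variability_ms` and `n_beats`.
#' @export
pulse_metrics <- function(ac, sample_rate) {
  n <- length(ac)
  if (n < 10 * sample_rate)
    abort("need at least 10 s of data", "acs_input_error")
  x <- ac - mean(ac)
  if (stats::sd(x) == 0) abort("no oscillation above noise floor", "acs_no_pulse")
  nfft <- 2^ceiling(log2(n * 8))
  P <- Mod(stats::fft(c(x, rep(0, nfft - n))))^2
  f <- (seq_len(nfft) - 1) * sample_rate / nfft
  band <- which(f >= 0.5 & f <= min(4, sample_rate / 2 * 0.99))
  if (!length(band)) abort("band empty at this sample rate", "acs_input_error")
  pk <- band[which.max(P[band])]
  if (P[pk] < 20 * stats::median(P[band]))
    abort("no oscillation above noise floor", "acs_no_pulse")
  # parabolic refinement on log power
  i <- c(pk - 1, pk, pk + 1)
  lp <- log(P[i] + .Machine$double.xmin)
  denom <- lp[1] - 2 * lp[2] + lp[3]
  shift <- if (abs(denom) > 0) 0.5 * (lp[1] - lp[3]) / denom else 0
  f_hat <- (pk - 1 + shift) * sample_rate / nfft
  rate <- 60 * f_hat
  # time-domain peak-to-peak intervals
  min_gap <- max(1L, floor(0.5 / f_hat * sample_rate))
  thr <- 0.4 * max(x)
  is_pk <- which(x > thr &
                   x >= c(-Inf, x[-n]) & x > c(x[-1], -Inf))
  keep <- logical(0)
  last <- -Inf
  for (j in is_pk) {
    if (j - last >= min_gap) { keep <- c(keep, j); last <- j }
  }
  tpk <- vapply(keep, function(j) {
    if (j <= 1 || j >= n) return(j / sample_rate)
    y <- x[(j - 1):(j + 1)]
    d <- y[1] - 2 * y[2] + y[3]
    s <- if (abs(d) > 0) 0.5 * (y[1] - y[3]) / d else 0
    (j + s) / sample_rate
  }, numeric(1))
  iv <- diff(tpk)
  list(rate_bpm = rate,
       variability_ms = if (length(iv) >= 2) stats::sd(iv) * 1000 else NA_real_,
       n_beats = length(tpk))
}

#' Run the full oximetry chain on a PPG trace
#'
#' From raw dual-wavelength PPG intensities to StO2: reference intensities
#' as the per-channel mean over the initial baseline window, optical
#' densities, zero-phase 0.1 Hz AC/DC separation (the DC branch feeds the
#' Beer-Lambert inversion), concentration changes, and saturation. Pulse
#' metrics are computed from the AC branch of the infrared channel when
#' possible.
#'
#' @param trace an [mc_trace()] with channels `ppg_red` and `ppg_ir`.
#' @param oc an [optical_constants()].
#' @param hs a [hemo_state()].
#' @param baseline_window length of the reference window in seconds.
#' @param cutoff AC/DC separation cutoff in Hz.
#' @return an [mc_trace()] with channels `od_red`, `od_ir`, `d_hbo2`,
#'   `d_hb`, `sto2`; pulse metrics, when defined, are in `$metadata$pulse`.
#' @export
oximetry_pipeline <- function(trace, oc = optical_constants(),
                              hs = hemo_state(), baseline_window = 30,
                              cutoff = 0.1) {
  stopifnot(inherits(trace, "mc_trace"))
  red <- trace_channel(trace, "ppg_red")
  ir <- trace_channel(trace, "ppg_ir")
  t <- trace$time
  sr <- trace$sample_rate
  win <- t <= t[1] + baseline_window
  i0 <- c(mean(red[win], na.rm = TRUE), mean(ir[win], na.rm = TRUE))
  if (any(!is.finite(i0)) || any(i0 <= 0))
    abort("nonpositive reference intensity", "acs_config_error")
  od_red <- optical_density(red, i0[1])
  od_ir <- optical_density(ir, i0[2])
  dc_red <- separate_dc(od_red, sr, cutoff = cutoff)
  dc_ir <- separate_dc(od_ir, sr, cutoff = cutoff)
  conc <- invert_beer_lambert(cbind(dc_red$dc, dc_ir$dc), oc)
  sto2 <- compute_sto2(conc[, "d_hbo2"], conc[, "d_hb"], hs)
  pulse <- tryCatch(pulse_metrics(separate_dc(ir, sr, cutoff = cutoff)$ac, sr),
                    acs_no_pulse = function(e) NULL,
                    acs_input_error = function(e) NULL)
  mc_trace(t,
           channels = list(od_red = od_red, od_ir = od_ir,
                           d_hbo2 = conc[, "d_hbo2"], d_hb = conc[, "d_hb"],
                           sto2 = sto2),
           units = c(od_red = "1", od_ir = "1", d_hbo2 = "mol/L",
                     d_hb = "mol/L", sto2 = "fraction"),
           sample_rate = sr,
           metadata = c(trace$metadata,
                        list(stage = "oximetry", i0 = i0, pulse = pulse)))
}
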