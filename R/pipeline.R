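# End-to-end composition: simulate (optional) -> calibrate pressure ->
# oximetry chain -> thermal flow inversion -> diagnostic fusion.

# Estimate per-channel thermistor baselines from heater-off samples and
# return the temperature-excess matrix for heater-on samples, excluding the
# equilibration window after switch-on.
thermistor_excess <- function(trace, warmup = 60) {
  heater <- trace_channel(trace, "heater")
  tch <- grep("^t[0-9]+$", names(trace$channels), value = TRUE)
  if (!length(tch)) abort("no thermistor channels", "acs_format_error")
  off <- heater == 0
  if (!any(off)) abort("no heater-off baseline samples", "acs_missing_data")
  on_t <- trace$time[heater == 1]
  t_on0 <- if (length(on_t)) min(on_t) else Inf
  usable <- heater == 1 & trace$time >= t_on0 + warmup
  baselines <- vapply(tch, function(nm)
    mean(trace$channels[[nm]][off], na.rm = TRUE), 1)
  mat <- sapply(tch, function(nm) trace$channels[[nm]] - baselines[[nm]])
  list(excess = mat, usable = usable, baselines = baselines)
}

#' Estimate a flow-velocity trace from raw thermistor channels
#'
#' Subtracts per-channel baselines estimated from heater-off samples,
#' excludes the post-switch-on equilibration window, and inverts the
#' thermal model jointly across thermistors. Long traces are inverted at a
#' decimated rate (default ~1 Hz) with the closed-form least-squares
#' solution and interpolated back.
#'
#' @param trace thermistor [mc_trace()] (channels `t1..t4`, `heater`).
#' @param tp a [thermal_model_params()].
#' @param warmup equilibration window after heater-on, in seconds,
#'   excluded from inversion (default 60).
#' @param decimate_hz inversion rate in Hz.
#' @return an [mc_trace()] with channels `u_hat` (mm/s, NA outside usable
#'   samples) and `delta_t14` (K).
#' @export
flow_pipeline <- function(trace, tp = thermal_model_params(), warmup = 60,
                          decimate_hz = 1) {
  stopifnot(inherits(trace, "mc_trace"))
  ex <- thermistor_excess(trace, warmup = warmup)
  n <- length(trace$time)
  step <- max(1L, round(trace$sample_rate / decimate_hz))
  idx <- seq(1L, n, by = step)
  u <- rep(NA_real_, n)
  use <- idx[ex$usable[idx]]
  if (length(use)) {
    u_dec <- invert_flow_series(ex$excess[use, , drop = FALSE], tp)
    interp_at <- which(ex$usable)
    if (length(use) >= 2) {
      u[interp_at] <- stats::approx(trace$time[use], u_dec,
                                    xout = trace$time[interp_at],
                                    rule = 2)$y
    } else u[use] <- u_dec
  }
  tch <- grep("^t[0-9]+$", names(trace$channels), value = TRUE)
  dt14 <- trace$channels[[tch[1]]] - trace$channels[[tch[length(tch)]]]
  mc_trace(trace$time,
           list(u_hat = u, delta_t14 = dt14),
           c(u_hat = "mm/s", delta_t14 = "K"),
           sample_rate = trace$sample_rate,
           metadata = c(trace$metadata,
                        list(stage = "flow", warmup = warmup)))
}

#' Run the full monitoring pipeline
#'
#' Simulates an episode (unless raw traces are supplied), calibrates the
#' pressure channel, runs the oximetry chain and the flow inversion, and
#' fuses the calibrated channels into the diagnostic outputs: the
#' perfusion-pressure differential, the fasciotomy alert report and the
#' plateau-wise modality summaries against the reference pressure.
#'
#' @param config an [episode_config()].
#' @param oc,tp,hs,rule component parameter objects.
#' @param cal pressure calibration; defaults to the bench calibration
#'   implied by the config's artifact model (offset and temperature
#'   coefficient known from bench tests).
#' @param raw optional list with elements `pressure`, `ppg`, `thermistors`
#'   ([mc_trace()] objects) to process instead of simulating.
#' @param out_dir optional directory; when given, all processed traces and
#'   the alert report (JSON) are written there.
#' @param verbose print stage-by-stage progress.
#' @return list of class `acs_pipeline_result` with `icp`, `oximetry`,
#'   `flow`, `delta_p`, `alert`, `summaries`, and `ground_truth`/`raw` when
#'   simulated.
#' @export
run_pipeline <- function(config = episode_config(),
                         oc = optical_constants(),
                         tp = thermal_model_params(),
                         hs = NULL,
                         rule = diagnostic_rule(),
                         cal = NULL,
                         raw = NULL,
                         out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  simulated <- is.null(raw)
  if (simulated) {
    say("[simulate] seed %d, %g s at %g Hz", config$seed, config$duration,
        config$sample_rate)
    raw <- simulate_episode(config, oc = oc, tp = tp, hs = hs)
  }
  if (is.null(cal))
    cal <- pressure_calibration(offset = config$pressure_offset,
                                temp_coeff = config$pressure_temp_coeff,
                                t_ref = raw$pressure$metadata$t_ref %||% 310.15)
  stage <- "pressure_calibration"
  res <- tryCatch({
    icp_v <- calibrate_pressure(trace_channel(raw$pressure, "pressure_raw"),
                                trace_channel(raw$pressure, "temp_device"),
                                cal)
    icp <- mc_trace(raw$pressure$time, list(icp = icp_v), c(icp = "mmHg"),
                    sample_rate = raw$pressure$sample_rate,
                    metadata = c(raw$pressure$metadata,
                                 list(stage = "calibrated_pressure")))
    say("[pressure] %d samples calibrated", length(icp_v))
    stage <- "oximetry"
    oxi <- oximetry_pipeline(raw$ppg, oc = oc,
                             hs = hs %||%
                               hemo_state(sto2_baseline = config$sto2_baseline))
    say("[oximetry] StO2 range %.3f-%.3f",
        min(oxi$channels$sto2, na.rm = TRUE),
        max(oxi$channels$sto2, na.rm = TRUE))
    stage <- "flow"
    flow <- flow_pipeline(raw$thermistors, tp = tp)
    say("[flow] %d usable flow samples", sum(is.finite(flow$channels$u_hat)))
    stage <- "diagnostics"
    dp <- delta_p(config$dbp, icp)
    alert <- fasciotomy_flag(dp, rule)
    summaries <- tryCatch(
      correlate_modalities(icp, list(
        pressure = trace_channel(icp, "icp"),
        sto2 = oxi$channels$sto2,
        flow = flow$channels$u_hat)),
      acs_insufficient_data = function(e) NULL)
    say("[diagnostics] %s",
        if (nrow(alert$alert_intervals)) "fasciotomy indicated"
        else "no indication")
    list(icp = icp, oximetry = oxi, flow = flow, delta_p = dp,
         alert = alert, summaries = summaries)
  }, error = function(e) {
    if (inherits(e, "acs_error"))
      abort(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)), "acs_stage_error")
    stop(e)
  })
  res$config <- config
  if (simulated) {
    res$ground_truth <- raw$ground_truth
    res$raw <- raw[c("pressure", "ppg", "thermistors")]
  }
  class(res) <- "acs_pipeline_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trace(res$icp, file.path(out_dir, "icp.csv"))
    write_trace(res$oximetry, file.path(out_dir, "oximetry.csv"))
    write_trace(res$flow, file.path(out_dir, "flow.csv"))
    write_trace(res$delta_p, file.path(out_dir, "delta_p.csv"))
    report <- list(
      rule = unclass(res$alert$rule),
      alert_intervals = res$alert$alert_intervals,
      earliest_flag_time = res$alert$earliest_flag_time,
      summaries = res$summaries,
      seed = config$seed)
    jsonlite::write_json(report, file.path(out_dir, "alert_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  }
  say("[done] %.2f s elapsed", as.numeric(Sys.time() - t0, units = "secs"))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.acs_pipeline_result <- function(x, ...) {
  cat("<acs_pipeline_result>\n")
  cat(sprintf("  samples: %d at %g Hz\n", length(x$icp$time),
              x$icp$sample_rate))
  if (!is.null(x$summaries)) {
    cat("  modality summaries (plateau means vs reference pressure):\n")
    print(x$summaries, row.names = FALSE)
  }
  print(x$alert)
  invisible(x)
}
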