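# Clinical fusion layer: the perfusion-pressure differential
# dP = DBP - ICP, the fasciotomy decision rule (sustained dP below
# 30 mmHg for at least 2 h), plateau-wise cross-modality linearity
# summaries, and the battery endurance utility.

#' Fasciotomy decision rule
#'
#' @param delta_p_threshold threshold in mmHg (default 30).
#' @param min_duration minimum sustained duration in seconds (default
#'   7200 s = 2 h).
#' @return object of class `diagnostic_rule`.
#' @export
diagnostic_rule <- function(delta_p_threshold = 30, min_duration = 7200) {
  if (delta_p_threshold <= 0 || min_duration <= 0)
    abort("threshold and min_duration must be > 0", "acs_config_error")
  structure(list(delta_p_threshold = delta_p_threshold,
                 min_duration = min_duration),
            class = "diagnostic_rule")
}

#' Perfusion pressure differential
#'
#' `dP(t) = DBP(t) - ICP(t)` on the ICP time base. A scalar DBP represents
#' a single clinical measurement; a DBP trace is linearly interpolated onto
#' the ICP time base (the time supports must overlap).
#'
#' @param dbp diastolic blood pressure: scalar mmHg or an [mc_trace()]
#'   with channel `dbp`.
#' @param icp an [mc_trace()] with channel `icp` (mmHg).
#' @return an [mc_trace()] with channel `delta_p` in mmHg.
#' @examples
#' icp <- mc_trace(0:10, list(icp = rep(40, 11)), c(icp = "mmHg"))
#' trace_channel(delta_p(70, icp), "delta_p")[1]
#' @export
delta_p <- function(dbp, icp) {
  stopifnot(inherits(icp, "mc_trace"))
  p <- trace_channel(icp, "icp")
  t <- icp$time
  if (inherits(dbp, "mc_trace")) {
    if (max(dbp$time) < min(t) || min(dbp$time) > max(t))
      abort("DBP and ICP time ranges do not overlap", "acs_alignment_error")
    dbp_v <- stats::approx(dbp$time, trace_channel(dbp, "dbp"), xout = t,
                           rule = 2)$y
  } else dbp_v <- rep(as.numeric(dbp), length(t))
  mc_trace(t, list(delta_p = dbp_v - p), c(delta_p = "mmHg"),
           sample_rate = icp$sample_rate,
           metadata = c(icp$metadata, list(stage = "delta_p")))
}

# Maximal below-threshold runs, broken at sampling gaps > gap_factor times
# the median interval. Returns a data.frame of run start/end times.
below_runs <- function(t, x, threshold, gap_factor = 2) {
  below <- x < threshold
  below[is.na(below)] <- FALSE
  gap_break <- c(FALSE, diff(t) > gap_factor * stats::median(diff(t)))
  run_id <- cumsum((below & !c(FALSE, below[-length(below)])) |
                     (below & gap_break))
  keep <- below
  if (!any(keep)) return(data.frame(start = numeric(0), end = numeric(0)))
  spans <- split(t[keep], run_id[keep])
  data.frame(start = vapply(spans, min, 1), end = vapply(spans, max, 1),
             row.names = NULL)
}

#' Apply the fasciotomy decision rule to a perfusion-pressure trace
#'
#' Flags every maximal run of samples with `delta_p < threshold` lasting at
#' least `min_duration`. Runs are strict: a single at-or-above-threshold
#' sample resets the clock, and sampling gaps longer than twice the median
#' interval break a run (dropout semantics). The earliest flag time is the
#' start of the first qualifying run plus `min_duration`.
#'
#' @param dp an [mc_trace()] with channel `delta_p`, or with channel order
#'   such that the first channel is the differential.
#' @param rule a [diagnostic_rule()].
#' @return object of class `alert_report`: `alert_intervals` (data.frame of
#'   start/end s), `earliest_flag_time` (s or NA), `rule`, and the input
#'   trace.
#' @export
fasciotomy_flag <- function(dp, rule = diagnostic_rule()) {
  stopifnot(inherits(dp, "mc_trace"), inherits(rule, "diagnostic_rule"))
  if (!length(dp$time)) abort("empty delta_p series", "acs_input_error")
  x <- if ("delta_p" %in% names(dp$channels)) dp$channels$delta_p
       else dp$channels[[1]]
  runs <- below_runs(dp$time, x, rule$delta_p_threshold)
  qual <- runs[runs$end - runs$start >= rule$min_duration, , drop = FALSE]
  structure(list(alert_intervals = qual,
                 earliest_flag_time = if (nrow(qual))
                   qual$start[1] + rule$min_duration else NA_real_,
                 all_below_runs = runs,
                 rule = rule,
                 delta_p = dp),
            class = "alert_report")
}

#' @export
print.alert_report <- function(x, ...) {
  cat(sprintf("<alert_report> rule: delta_p < %g mmHg for >= %g s\n",
              x$rule$delta_p_threshold, x$rule$min_duration))
  if (nrow(x$alert_intervals)) {
    cat(sprintf("  %d qualifying interval(s); earliest flag at t = %g s\n",
                nrow(x$alert_intervals), x$earliest_flag_time))
    for (i in seq_len(nrow(x$alert_intervals)))
      cat(sprintf("    [%g, %g] s\n", x$alert_intervals$start[i],
                  x$alert_intervals$end[i]))
  } else cat("  no fasciotomy indication\n")
  invisible(x)
}

# Plateau windows of a reference series: maximal runs where the smoothed
# derivative stays small. Returns index windows after trimming the leading
# settle fraction.
find_plateaus <- function(t, x, slope_tol = 0.05, min_len = 30,
                          settle_frac = 0.5) {
  dt <- stats::median(diff(t))
  k <- max(1L, round(5 / dt))  # ~5 s smoothing window
  xs <- as.numeric(stats::filter(x, rep(1 / (2 * k + 1), 2 * k + 1),
                                 sides = 2))
  n <- length(xs)
  # central slope over +-5 s of the smoothed series: robust to sample noise
  slope <- rep(NA_real_, n)
  i <- seq(k + 1L, n - k)
  slope[i] <- (xs[i + k] - xs[i - k]) / (2 * k * dt)
  flat <- abs(slope) < slope_tol
  flat[is.na(flat)] <- FALSE
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values & r$lengths * dt >= min_len)
  lapply(idx, function(i) {
    s <- starts[i]; e <- ends[i]
    s2 <- s + floor((e - s) * settle_frac)
    seq(s2, e)
  })
}

#' Cross-modality linearity summaries against a reference pressure
#'
#' For each measured modality, ordinary-least-squares slope, intercept and
#' Pearson correlation against the reference pressure. The default
#' `"plateau"` method averages reference and modality over detected
#' reference plateaus (trimming the first half of each window so lagged
#' channels settle) and regresses the plateau means, which suppresses lag
#' artifacts; `"sample"` regresses per sample.
#'
#' @param reference_p reference pressure: an [mc_trace()] (first channel)
#'   or numeric vector.
#' @param measured named list of numeric vectors on the same time base.
#' @param time time base in seconds (taken from the trace when omitted).
#' @param method "plateau" or "sample".
#' @param slope_tol,min_len,settle_frac plateau-detection tuning: maximum
#'   absolute reference slope (mmHg/s), minimum plateau length (s), and
#'   fraction of each plateau discarded before averaging.
#' @return data.frame with one row per modality: `modality`, `slope`,
#'   `intercept`, `pearson_r`, `n`.
#' @export
correlate_modalities <- function(reference_p, measured, time = NULL,
                                 method = c("plateau", "sample"),
                                 slope_tol = 0.05, min_len = 30,
                                 settle_frac = 0.5) {
  method <- match.arg(method)
  if (inherits(reference_p, "mc_trace")) {
    time <- reference_p$time
    reference_p <- reference_p$channels[[1]]
  }
  if (is.null(time)) time <- seq_along(reference_p)
  stopifnot(is.list(measured), !is.null(names(measured)))
  if (method == "plateau") {
    wins <- find_plateaus(time, reference_p, slope_tol, min_len, settle_frac)
    if (length(wins) < 3)
      abort(sprintf("only %d plateau(s) found; need >= 3", length(wins)),
            "acs_insufficient_data")
    ref <- vapply(wins, function(w) mean(reference_p[w], na.rm = TRUE), 1)
    vals <- lapply(measured, function(v)
      vapply(wins, function(w) mean(v[w], na.rm = TRUE), 1))
  } else {
    ref <- reference_p
    vals <- measured
  }
  out <- lapply(names(vals), function(nm) {
    y <- vals[[nm]]
    ok <- is.finite(ref) & is.finite(y)
    fit <- stats::lm(y[ok] ~ ref[ok])
    degenerate <- stats::sd(ref[ok]) == 0 || stats::sd(y[ok]) == 0
    data.frame(modality = nm,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               pearson_r = if (degenerate) NA_real_
                           else stats::cor(ref[ok], y[ok]),
               n = sum(ok))
  })
  do.call(rbind, out)
}

#' Battery endurance
#'
#' `hours = capacity / current`, optionally floored to whole hours. The
#' probe draws ~14 mA in full 20 Hz operation and ~4.2 mA in the 1 Hz
#' low-power mode from a 370 mAh cell.
#'
#' @param capacity battery capacity in mAh, > 0.
#' @param current draw in mA, > 0.
#' @param floor_to_int floor the result to whole hours.
#' @return endurance in hours.
#' @examples
#' endurance_hours(370, 4.2, floor_to_int = TRUE)  # 88
#' @export
endurance_hours <- function(capacity, current, floor_to_int = FALSE) {
  if (!is.finite(capacity) || !is.finite(current) ||
      capacity <= 0 || current <= 0)
    abort("capacity and current must be > 0", "acs_input_error")
  h <- capacity / current
  if (floor_to_int) floor(h) else h
}
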