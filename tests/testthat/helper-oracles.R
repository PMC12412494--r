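# Independent oracles used by the unit and acceptance suites. These share
# no code path with the package internals: the shape-factor oracle is a
# plain fine-grid trapezoid cumulative integral with partial-sum averaging
# at approximate Bessel-zero abscissae, and the decision-rule oracle is a
# per-sample run-length scan.

# Brute-force shape factor: cumulative trapezoid of J0(rho x) J1(x)/x on a
# uniform grid to X, then repeated pairwise averaging of the cumulative
# values sampled at the J1 oscillation zeros to resolve the alternating
# tail. Accuracy ~ 5e-7 relative over the geometry grid used in tests.
brute_shape_factor <- function(rho, X = 3000, h = 0.004) {
  x <- seq(h, X, by = h)
  fx <- besselJ(rho * x, 0) * besselJ(x, 1) / x
  cum <- c(0, cumsum(0.5 * (fx[-1] + fx[-length(fx)]) * h))
  # head 0..h: integrand -> J0(0)*J1(x)/x -> 1/2 at x = 0
  cum <- cum + 0.5 * (0.5 + fx[1]) * h
  # approximate J1 zeros (McMahon, 2 terms) as alternation markers
  k <- seq_len(floor((X - 10) / pi))
  beta <- (k + 0.25) * pi
  zs <- beta - 3 / (8 * beta)
  ps <- cum[pmin(length(cum), round(zs / h))]
  ps <- ps[max(1, length(ps) - 499):length(ps)]
  while (length(ps) > 1) ps <- 0.5 * (ps[-1] + ps[-length(ps)])
  ps
}

# Brute-force decision rule: per-sample scan with explicit run state.
oracle_alert_intervals <- function(t, dp, threshold, min_duration,
                                   gap_factor = 2) {
  med <- stats::median(diff(t))
  runs <- list()
  start <- NA
  prev_t <- NA
  for (i in seq_along(dp)) {
    below <- !is.na(dp[i]) && dp[i] < threshold
    gap <- !is.na(prev_t) && (t[i] - prev_t) > gap_factor * med
    if (below) {
      if (is.na(start) || gap) {
        if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, prev_t)
        start <- t[i]
      }
    } else if (!is.na(start)) {
      runs[[length(runs) + 1]] <- c(start, prev_t)
      start <- NA
    }
    prev_t <- t[i]
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, prev_t)
  if (!length(runs))
    return(data.frame(start = numeric(0), end = numeric(0)))
  m <- do.call(rbind, runs)
  out <- data.frame(start = m[, 1], end = m[, 2])
  out[out$end - out$start >= min_duration, , drop = FALSE]
}

# Noise-free, pulsation-free configuration used by round-trip closures.
noiseless_config <- function(...) {
  episode_config(noise_sd = c(pressure = 0, ppg = 0, thermistor = 0),
                 ac_amplitude = 0, ...)
}

# Samples at least `margin` seconds away from every ICP ramp segment (the
# zero-phase DC filter needs ~60 s to settle on either side of a step).
interior_mask <- function(time, config, margin = 60) {
  prof <- config$icp_profile
  edges <- c(rbind(prof$start, prof$start + prof$ramp))
  dist <- vapply(time, function(tt) min(abs(tt - edges)), 1)
  ramping <- vapply(time, function(tt)
    any(tt >= prof$start & tt <= prof$start + prof$ramp), TRUE)
  dist >= margin & !ramping & time >= margin & time <= max(time) - margin
}
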