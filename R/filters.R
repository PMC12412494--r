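# Zero-phase Butterworth low-pass filtering.
#
# Implemented from first principles (bilinear transform, cascaded biquads,
# forward-backward pass with reflective padding and DC-consistent initial
# conditions) because no DSP package is assumed; only low-pass separation at
# very low normalised cutoffs (0.1 Hz at 20 Hz sampling) is required, where
# second-order sections are numerically safe.

# Butterworth low-pass as second-order sections.
# order: even filter order; wn: cutoff / Nyquist in (0, 1).
# Returns a list of biquads, each list(b = c(b0,b1,b2), a = c(1,a1,a2)).
butter_lowpass_sos <- function(order = 4L, wn) {
  stopifnot(order %% 2 == 0, order >= 2, wn > 0, wn < 1)
  wa <- tan(pi * wn / 2)  # prewarped analog cutoff, fs = 1/2 convention
  k <- seq_len(order / 2)
  # analog prototype pole pairs on the unit circle, Re < 0
  re <- cos(pi * (2 * k + order - 1) / (2 * order))
  lapply(re, function(rp) {
    a0 <- 1 - 2 * rp * wa + wa^2
    list(b = c(wa^2, 2 * wa^2, wa^2) / a0,
         a = c(1, (2 * wa^2 - 2) / a0, (1 + 2 * rp * wa + wa^2) / a0))
  })
}

# Single causal pass of one biquad with steady-state (DC) initial conditions
# matched to x[1], so a constant input passes through exactly.
biquad_pass <- function(x, bq) {
  b <- bq$b; a <- bq$a
  x0 <- x[1]
  xb <- b[1] * x + b[2] * c(x0, x[-length(x)]) +
    b[3] * c(x0, x0, x[-c(length(x) - 1, length(x))])
  as.numeric(stats::filter(xb, -a[2:3], method = "recursive", init = c(x0, x0)))
}

# Zero-phase (forward-backward) application of cascaded biquads with odd
# reflection padding at both ends; padlen scales with the filter's settling
# length at low cutoffs.
sos_filtfilt <- function(x, sos, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- n - 1L
  padlen <- min(padlen, n - 1L)
  if (padlen < 3L) abort("trace shorter than filter warm-up", "acs_length_error")
  head_pad <- 2 * x[1] - x[seq(padlen + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  y <- c(head_pad, x, tail_pad)
  for (bq in sos) y <- biquad_pass(y, bq)
  y <- rev(y)
  for (bq in sos) y <- biquad_pass(y, bq)
  y <- rev(y)
  y[seq(padlen + 1, padlen + n)]
}

#' Separate the DC and AC components of a physiological signal
#'
#' Splits a sampled signal into a slowly varying (DC) component and a
#' pulsatile (AC) residual using a zero-phase 4th-order Butterworth low-pass
#' filter. With the default 0.1 Hz cutoff the DC branch retains baseline
#' drifts while the cardiac pulsation (typically around 1-2 Hz) is removed
#' from it; `ac = signal - dc`.
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate in Hz; must exceed `2 * cutoff`.
#' @param cutoff low-pass cutoff in Hz (default 0.1).
#' @param order Butterworth order (even, default 4).
#' @return list with numeric components `dc` and `ac`.
#' @examples
#' t <- seq(0, 60, by = 0.05)
#' s <- 2 + 0.02 * sin(2 * pi * 1.2 * t)
#' parts <- separate_dc(s, sample_rate = 20)
#' max(abs(parts$dc - 2)) < 1e-3
#' @export
separate_dc <- function(x, sample_rate, cutoff = 0.1, order = 4L) {
  stopifnot(is.numeric(x), sample_rate > 2 * cutoff, cutoff > 0)
  wn <- cutoff / (sample_rate / 2)
  # settling length of the slowest pole ~ 1/(wa * cos(pi/8)) samples
  wa <- tan(pi * wn / 2)
  padlen <- ceiling(12 / wa)
  if (length(x) <= max(3 * order, padlen %/% 4))
    abort("trace shorter than filter warm-up", "acs_length_error")
  sos <- butter_lowpass_sos(order, wn)
  dc <- sos_filtfilt(x, sos, padlen = padlen)
  list(dc = dc, ac = x - dc)
}
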