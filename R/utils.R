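#' @keywords internal
"_PACKAGE"

PA_PER_MMHG <- 133.322387415

#' Pressure unit conversions
#'
#' Exact double-precision conversions between mmHg, kPa and Pa
#' (1 mmHg = 133.322387415 Pa).
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' kpa_to_mmhg(mmhg_to_kpa(70))
#' @export
mmhg_to_pa <- function(x) x * PA_PER_MMHG

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / PA_PER_MMHG

#' @rdname mmhg_to_pa
#' @export
mmhg_to_kpa <- function(x) x * (PA_PER_MMHG / 1000)

#' @rdname mmhg_to_pa
#' @export
kpa_to_mmhg <- function(x) x / (PA_PER_MMHG / 1000)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

abort <- function(msg, class, ...) {
  stop(structure(class = c(class, "acs_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Evaluate an expression with a fixed RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so simulator calls are reproducible without disturbing
#' the session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' First-order lag (exponential smoothing) of a sampled signal
#'
#' Discretised first-order low-pass response `tau * dy/dt + y = x`, exact for
#' inputs that are piecewise constant between samples: a step input reaches
#' 63.2% of its asymptotic change at `t = tau` after the step.
#'
#' @param x numeric input series.
#' @param dt sample interval in seconds.
#' @param tau time constant in seconds; `tau = 0` returns `x` unchanged.
#' @param init initial state; defaults to `x[1]`.
#' @return numeric series of the lagged response.
#' @export
first_order_lag <- function(x, dt, tau, init = x[1]) {
  stopifnot(dt > 0, tau >= 0)
  if (tau == 0 || length(x) == 0) return(x)
  a <- exp(-dt / tau)
  # y[n] = a y[n-1] + (1-a) x[n]
  y <- stats::filter((1 - a) * x, a, method = "recursive", init = init)
  as.numeric(y)
}
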