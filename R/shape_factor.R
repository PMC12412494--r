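# Geometric shape factor for the heated-spreader thermal model:
#   F(r/R) = \int_0^Inf J0(g r) J1(g R) dg / g
# a Hankel-type oscillatory integral. The primary evaluation path integrates
# between consecutive Bessel zeros with fixed-order Gauss-Legendre panels and
# sums the strictly alternating segment series with repeated-averaging
# (Euler-type) acceleration; for r/R near 1 a slow beat frequency |1 - r/R|
# appears and the tail beyond the quadrature window is added analytically
# from the leading large-argument asymptotics of the Bessel product. A
# closed form in complete elliptic integrals is provided as a second,
# independent method.

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

.gl12 <- gauss_legendre(12L)

# Vectorised Gauss-Legendre integration of f over consecutive panels given by
# `breaks`; returns one integral per panel.
panel_integrals <- function(f, breaks, gl = .gl12) {
  a <- breaks[-length(breaks)]
  b <- breaks[-1]
  half <- 0.5 * (b - a)
  mid <- 0.5 * (a + b)
  x <- outer(half, gl$x) + mid        # n_panel x n_node
  fx <- matrix(f(as.numeric(x)), nrow = length(half))
  as.numeric((fx %*% gl$w) * half)
}

# Limit of the partial sums of an alternating series by repeated pairwise
# averaging of the cumulative sums.
alt_series_limit <- function(terms) {
  s <- cumsum(terms)
  while (length(s) > 1) s <- 0.5 * (s[-1] + s[-length(s)])
  s
}

# First `k` positive zeros of J0 or J1: McMahon expansion + vectorised Newton.
bessel_zeros <- function(nu, k) {
  stopifnot(nu %in% c(0, 1))
  beta <- (seq_len(k) + nu / 2 - 1 / 4) * pi
  mu <- 4 * nu^2
  x <- beta - (mu - 1) / (8 * beta) -
    4 * (mu - 1) * (7 * mu - 31) / (3 * (8 * beta)^3)
  for (it in 1:3) {
    j <- besselJ(x, nu)
    dj <- if (nu == 0) -besselJ(x, 1) else besselJ(x, 0) - besselJ(x, 1) / x
    x <- x - j / dj
  }
  x
}

# \int_X^Inf sin(a x)/x^2 dx ("s") or \int_X^Inf cos(a x)/x^2 dx ("c"), a > 0.
# Substituting t = a x reduces to a single-frequency alternating series.
osc_tail_integral <- function(a, X, kind = c("s", "c")) {
  kind <- match.arg(kind)
  if (a <= 0) return(0)
  y <- a * X
  f <- if (kind == "s") function(t) sin(t) / t^2 else function(t) cos(t) / t^2
  off <- if (kind == "c") 0.5 else 0
  k0 <- ceiling(y / pi + off)
  zs <- (seq(k0, k0 + 200) - off) * pi
  zs <- zs[zs > y]
  head <- panel_integrals(f, c(y, zs[1]))
  terms <- panel_integrals(f, zs[1:161])
  a * (head + alt_series_limit(terms))
}

# Complete elliptic integrals K(m), E(m) (parameter m = k^2) via the
# arithmetic-geometric mean.
ellipke_agm <- function(m) {
  stopifnot(m >= 0, m <= 1)
  if (m > 1 - 1e-14) return(list(K = Inf, E = 1))
  a <- 1; b <- sqrt(1 - m); c <- sqrt(m)
  csum <- 0.5 * c^2
  p <- 1
  for (it in 1:60) {
    an <- (a + b) / 2
    c <- (a - b) / 2
    b <- sqrt(a * b)
    a <- an
    p <- 2 * p
    csum <- csum + 0.5 * p * c^2
    if (abs(c) < 1e-17) break
  }
  K <- pi / (2 * a)
  list(K = K, E = K * (1 - csum))
}

shape_factor_elliptic <- function(rho) {
  if (rho <= 1) return((2 / pi) * ellipke_agm(rho^2)$E)
  m <- 1 / rho^2
  ke <- ellipke_agm(m)
  (2 * rho / pi) * (ke$E - (1 - m) * ke$K)
}

shape_factor_quadrature <- function(rho) {
  f <- function(x) besselJ(rho * x, 0) * besselJ(x, 1) / x
  if (rho <= 0.5) {
    # J1 zeros pace the oscillation; J0(rho x) is a smooth slow modulation
    zs <- bessel_zeros(1, 140)
    segs <- panel_integrals(f, c(1e-300, zs))
    return(sum(segs[1:60]) + alt_series_limit(segs[61:140]))
  }
  if (rho >= 2) {
    zs <- bessel_zeros(0, 140) / rho
    segs <- panel_integrals(f, c(1e-300, zs))
    return(sum(segs[1:60]) + alt_series_limit(segs[61:140]))
  }
  # comparable frequencies: exact panel sum on [0, X], then analytic tail from
  # J0(rho x) J1(x)/x ~ [sin((1-rho)x) - cos((1+rho)x)] / (pi sqrt(rho) x^2)
  a <- abs(1 - rho)
  X <- min(max(1500, 40 / max(a, 1e-12)), 4e4)
  z1 <- bessel_zeros(1, ceiling(X / pi) + 3)
  z0 <- bessel_zeros(0, ceiling(X * rho / pi) + 3) / rho
  zs <- sort(c(z1, z0))
  zs <- zs[zs < X]
  head <- sum(panel_integrals(f, c(1e-300, zs, X)))
  S <- osc_tail_integral(a, X, "s")
  C <- osc_tail_integral(1 + rho, X, "c")
  head + (sign(1 - rho) * S - C) / (pi * sqrt(rho))
}

.shape_factor_cache <- new.env(parent = emptyenv())

#' Thermal shape factor of the heater/spreader geometry
#'
#' Evaluates the dimensionless geometric factor
#' \deqn{F(r/R) = \int_0^\infty J_0(\gamma r)\, J_1(\gamma R)\, d\gamma/\gamma}
#' relating the heat-spreader radius `R` and the thermistor distance `r` to
#' the steady temperature field of the flow sensor. `F(0) = 1`, `F` is
#' nonincreasing in `r`, and `F(r, R) = F(cr, cR)` (only the ratio r/R
#' matters).
#'
#' The default method integrates between consecutive zeros of the Bessel
#' factors (12-point Gauss-Legendre per panel) and accelerates the
#' alternating segment series; near `r = R` an analytic asymptotic tail
#' handles the slow beat frequency. `method = "elliptic"` uses the exact
#' closed form in complete elliptic integrals and serves as an independent
#' cross-check.
#'
#' @param r distance from the heater (same length unit as `big_r`).
#' @param big_r heat-spreader radius, > 0.
#' @param method "quadrature" (default) or "elliptic".
#' @return dimensionless factor in `[0, 1]`, vectorised over `r`.
#' @examples
#' shape_factor(0, 1)                       # exactly 1 in the limit
#' shape_factor(1e-3, 2e-3)                 # typical probe geometry
#' shape_factor(1, 2) - shape_factor(500, 1000, method = "elliptic")
#' @export
shape_factor <- function(r, big_r, method = c("quadrature", "elliptic")) {
  method <- match.arg(method)
  if (any(r < 0) || any(big_r <= 0))
    abort("r must be >= 0 and big_r > 0", "acs_geometry_error")
  rho <- r / big_r
  vapply(rho, function(p) {
    if (p == 0) p_key <- "0" else p_key <- sprintf("%s:%.17g", method, p)
    if (!is.null(.shape_factor_cache[[p_key]]))
      return(.shape_factor_cache[[p_key]])
    val <- if (method == "elliptic") shape_factor_elliptic(p)
           else shape_factor_quadrature(p)
    if (!is.finite(val))
      abort("shape-factor quadrature failed to converge", "acs_numerical_error")
    .shape_factor_cache[[p_key]] <- val
    val
  }, numeric(1))
}
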