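test_that("NTC beta-model calibration matches the closed form and inverts", {
  cal <- ntc_calibration()
  expect_equal(ntc_to_temperature(10000, cal), 298.15)
  # independently computed: 10 kOhm * exp(3380 * (1/310.15 - 1/298.15))
  expect_equal(ntc_to_temperature(6449, cal), 310.15, tolerance = 1e-5)
  # forward then inverted resistance recovered to < 0.01%
  r37 <- temperature_to_resistance(310.15, cal)
  expect_equal(ntc_to_temperature(r37, cal), 310.15, tolerance = 1e-10)
  expect_lt(abs(r37 - 6449.239) / 6449.239, 1e-4)
  # monotone decreasing in resistance
  rr <- seq(2000, 30000, length.out = 50)
  expect_true(all(diff(ntc_to_temperature(rr, cal)) < 0))
  expect_error(ntc_to_temperature(-1, cal), class = "acs_input_error")
})

test_that("linear NTC mode is affine and must have negative slope", {
  cal <- ntc_calibration(mode = "linear", slope = -0.002, intercept = 323)
  expect_equal(ntc_to_temperature(6500, cal), 323 - 0.002 * 6500)
  expect_error(ntc_calibration(mode = "linear", slope = 0.01, intercept = 0),
               class = "acs_config_error")
})

test_that("shape factor limits, scale invariance and monotonicity", {
  for (R in c(0.5e-3, 1e-3, 2e-3))
    expect_equal(shape_factor(0, R), 1, tolerance = 1e-9)
  # scale invariance F(r, R) = F(cr, cR)
  for (c_ in c(0.1, 7)) {
    expect_equal(shape_factor(1.3, 2), shape_factor(1.3 * c_, 2 * c_),
                 tolerance = 1e-9)
  }
  # nonincreasing in r at fixed R
  r <- seq(0, 8e-3, length.out = 25)
  F <- shape_factor(r, 2e-3)
  expect_true(all(diff(F) <= 1e-12))
  expect_true(all(F >= 0 & F <= 1))
  expect_error(shape_factor(-1, 1), class = "acs_geometry_error")
})

test_that("quadrature and elliptic closed form agree, and match the brute oracle", {
  rhos <- c(0.05, 0.3, 0.75, 0.95, 1, 1.05, 1.4, 2.5, 6)
  for (rho in rhos) {
    q <- shape_factor(rho, 1)
    e <- shape_factor(rho, 1, method = "elliptic")
    expect_equal(q, e, tolerance = 1e-8)
  }
  for (rho in c(0.3, 1.143, 4)) {
    expect_equal(shape_factor(rho, 1), brute_shape_factor(rho),
                 tolerance = 1e-6)
  }
})

test_that("forward thermal model: zero-flow limit, monotone decay in u", {
  tp <- thermal_model_params()
  for (r in tp$r_list) {
    dt0 <- forward_delta_t(0, tp, r)
    expect_equal(dt0, tp$q_heat * tp$big_r / tp$k_tissue *
                   shape_factor(r, tp$big_r))
    u <- seq(0, 20, length.out = 40)
    dts <- forward_delta_t(u, tp, r)
    expect_true(all(diff(dts) < 0))
    expect_lt(forward_delta_t(1e4, tp, r), 1e-2 * dt0)
  }
  # direct formula evaluation oracle on a grid
  u <- c(0.3, 1, 2, 5, 12)
  direct <- tp$q_heat * tp$big_r / tp$k_tissue *
    shape_factor(tp$r_list[2], tp$big_r, method = "elliptic") /
    (1 + 0.76 * tp$s_blood * (u * 1e-3) * tp$big_r / tp$alpha_fluid)
  expect_equal(forward_delta_t(u, tp, tp$r_list[2]), direct,
               tolerance = 1e-8)
})

test_that("forward model is monotone in u across random parameter draws", {
  set.seed(11)
  for (i in 1:20) {
    tp <- thermal_model_params(
      q_heat = runif(1, 100, 5000), big_r = runif(1, 0.5e-3, 4e-3),
      k_tissue = runif(1, 0.2, 1), alpha_fluid = runif(1, 0.8e-7, 2e-7),
      s_blood = runif(1, 0.01, 0.5))
    r <- runif(1, 0.3e-3, 9e-3)
    dts <- forward_delta_t(seq(0, 20, length.out = 15), tp, r)
    expect_true(all(diff(dts) < 0))
  }
})

test_that("flow inversion recovers noiseless forward data and flags dropout", {
  tp <- thermal_model_params()
  for (u_true in c(0, 0.5, 1, 2, 5, 10, 20)) {
    dts <- vapply(tp$r_list, function(r) forward_delta_t(u_true, tp, r), 1)
    fit <- invert_flow(dts, tp)
    if (u_true == 0) expect_equal(fit$u_hat, 0, tolerance = 1e-6)
    else expect_lt(abs(fit$u_hat - u_true) / u_true, 0.01)
    expect_false(fit$boundary)
  }
  # partial dropout still inverts; total dropout raises
  dts <- vapply(tp$r_list, function(r) forward_delta_t(3, tp, r), 1)
  dts[c(2, 4)] <- NA
  expect_lt(abs(invert_flow(dts, tp)$u_hat - 3) / 3, 0.01)
  expect_error(invert_flow(rep(NA_real_, 4), tp),
               class = "acs_missing_data")
  # vectorised closed form agrees with the scalar path
  um <- c(0.5, 2, 8)
  mat <- t(vapply(um, function(u)
    vapply(tp$r_list, function(r) forward_delta_t(u, tp, r), 1),
    numeric(4)))
  expect_equal(acsprobe:::invert_flow_series(mat, tp), um,
               tolerance = 1e-8)
})

test_that("relative flow index cancels common baselines and tracks flow", {
  expect_equal(relative_flow_index(3, 3), 0)
  t1 <- c(311.2, 311.3); t4 <- c(310.4, 310.5)
  expect_equal(relative_flow_index(t1 + 0.5, t4 + 0.5),
               relative_flow_index(t1, t4))
  tp <- thermal_model_params()
  d14 <- function(u) forward_delta_t(u, tp, tp$r_list[1]) -
    forward_delta_t(u, tp, tp$r_list[4])
  expect_lt(d14(5), d14(1))
  expect_error(relative_flow_index(1:3, 1:2), class = "acs_input_error")
})
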