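test_that("ICP trace: plateaus exact, ramps linear, degenerate profiles", {
  cfg <- episode_config(duration = 240, icp_profile = data.frame(
    start = c(0, 60, 120, 180), target = c(0, 50, 100, 150),
    ramp = c(0, 30, 30, 30)))
  icp <- trace_channel(generate_icp_trace(cfg), "icp")
  t <- acsprobe:::episode_time(cfg)
  expect_equal(unique(icp[t < 60]), 0)
  expect_equal(unique(icp[t >= 90 & t < 120]), 50)
  expect_equal(unique(icp[t >= 150 & t < 180]), 100)
  expect_equal(unique(icp[t >= 210]), 150)
  # mid-ramp value is the linear interpolant
  expect_equal(icp[t == 75], 25)
  # empty profile -> constant zero
  cfg0 <- episode_config(duration = 10,
                         icp_profile = data.frame(start = numeric(0),
                                                  target = numeric(0),
                                                  ramp = numeric(0)))
  expect_equal(unique(trace_channel(generate_icp_trace(cfg0), "icp")), 0)
  # single step, no noise -> max equals the plateau
  cfg1 <- episode_config(duration = 120, icp_profile = data.frame(
    start = c(0, 30), target = c(0, 70), ramp = c(0, 10)))
  expect_equal(max(trace_channel(generate_icp_trace(cfg1), "icp")), 70)
  # overlapping ramp segments rejected
  expect_error(episode_config(icp_profile = data.frame(
    start = c(0, 50, 100), target = c(0, 50, 100), ramp = c(0, 100, 0))),
    class = "acs_config_error")
  expect_error(episode_config(icp_profile = data.frame(
    start = c(10, 5), target = c(0, 50), ramp = c(0, 0))),
    class = "acs_config_error")
})

test_that("physiology: zero drive, inverse signs, first-order lag at tau", {
  cfg <- episode_config()
  gt0 <- derive_physiology(rep(0, 200), cfg)
  expect_equal(unique(gt0$sto2), cfg$sto2_baseline)
  expect_equal(unique(gt0$u), cfg$flow_baseline)
  expect_equal(unique(gt0$d_hbo2), 0)
  # step response reaches 63.2% of the change at t = flow_lag_tau
  cfg2 <- episode_config(sample_rate = 20, flow_delay = 0, flow_lag_tau = 20)
  icp_step <- c(rep(0, 100), rep(100, 2000))
  gt <- derive_physiology(icp_step, cfg2)
  u0 <- cfg2$flow_baseline
  u_inf <- u0 + cfg2$coupling_slopes[["flow"]] * 100
  # step held from sample 101; input convention dates the step at sample 100
  at_tau <- gt$u[100 + 20 * cfg2$sample_rate]
  expect_equal((at_tau - u0) / (u_inf - u0), 1 - exp(-1), tolerance = 1e-3)
  # inverse responses to a pressure step
  expect_lt(gt$sto2[2000] - gt$sto2[1], 0)
  expect_lt(gt$u[2000] - gt$u[1], 0)
  # ground truth consistent with the saturation model at fixed total Hb
  hs <- gt0$hs
  expect_equal(compute_sto2(gt$d_hbo2, gt$d_hb, hs), gt$sto2,
               tolerance = 1e-12)
})

test_that("episode-level sign structure: negative pressure couplings", {
  ep <- simulate_episode(episode_config(seed = 21))
  gt <- ep$ground_truth
  expect_lt(cor(gt$icp, gt$sto2), 0)
  expect_lt(cor(gt$icp, gt$u), 0)
})

test_that("PPG forward model: identity, determinism, round trip", {
  cfg <- noiseless_config()
  gt <- derive_physiology(rep(0, 400), cfg)
  ppg <- forward_ppg(gt, optical_constants(), cfg)
  expect_equal(unique(trace_channel(ppg, "ppg_red")), cfg$i0[["red"]])
  expect_equal(unique(trace_channel(ppg, "ppg_ir")), cfg$i0[["ir"]])
  # same seed -> bit-identical; different seed differs
  cfgn <- episode_config(seed = 5)
  gtn <- derive_physiology(rep(10, 400), cfgn)
  p1 <- forward_ppg(gtn, optical_constants(), cfgn)
  p2 <- forward_ppg(gtn, optical_constants(), cfgn)
  expect_identical(p1$channels, p2$channels)
  cfgm <- episode_config(seed = 6)
  expect_false(identical(
    forward_ppg(gtn, optical_constants(), cfgm)$channels, p1$channels))
  # noiseless intensities invert to the ground-truth concentration changes
  oc <- optical_constants()
  cfg2 <- noiseless_config()
  icp <- seq(0, 150, length.out = 300)
  gt2 <- derive_physiology(icp, cfg2)
  ppg2 <- forward_ppg(gt2, oc, cfg2)
  od <- cbind(optical_density(trace_channel(ppg2, "ppg_red"), cfg2$i0[["red"]]),
              optical_density(trace_channel(ppg2, "ppg_ir"), cfg2$i0[["ir"]]))
  conc <- invert_beer_lambert(od, oc)
  expect_equal(conc[, "d_hbo2"], gt2$d_hbo2, tolerance = 1e-9)
  expect_equal(conc[, "d_hb"], gt2$d_hb, tolerance = 1e-9)
  expect_error(forward_ppg(gt2, oc, episode_config(i0 = c(red = -1, ir = 1))),
               class = "acs_config_error")
})

test_that("thermistor forward model: heater off, monotone cooling, geometry", {
  tp <- thermal_model_params()
  cfg <- noiseless_config(heater_on_time = 10, duration = 30)
  gt <- derive_physiology(rep(0, length(acsprobe:::episode_time(cfg))), cfg)
  th <- forward_thermistors(gt, tp, cfg)
  off <- trace_channel(th, "heater") == 0
  for (nm in paste0("t", 1:4))
    expect_equal(unique(trace_channel(th, nm)[off]), cfg$tissue_temp)
  # u doubled: every channel's excess strictly decreases
  on <- !off
  gt2 <- gt; gt2$u <- gt$u * 2
  th2 <- forward_thermistors(gt2, tp, cfg)
  for (nm in paste0("t", 1:4))
    expect_true(all(trace_channel(th2, nm)[on] <
                      trace_channel(th, nm)[on]))
  # the thermistor nearest the heater shows the largest excess
  exc <- vapply(paste0("t", 1:4),
                function(nm) mean(trace_channel(th, nm)[on]) - cfg$tissue_temp,
                1)
  expect_true(all(exc[1] > exc[-1]))
  expect_true(all(diff(exc) < 0))
  expect_error(thermal_model_params(r_list = c(-1e-3, 2e-3, 3e-3, 4e-3)),
               class = "acs_config_error")
})

test_that("raw pressure channel: identity, additive offset, compensation round trip", {
  gt <- derive_physiology(seq(0, 150, length.out = 500), episode_config())
  cfg_id <- noiseless_config(pressure_offset = 0, pressure_temp_coeff = 0)
  raw <- forward_pressure(gt, cfg_id)
  expect_equal(trace_channel(raw, "pressure_raw"), gt$icp)
  cfg_off <- noiseless_config(pressure_offset = 5, pressure_temp_coeff = 0)
  raw5 <- forward_pressure(gt, cfg_off)
  expect_equal(trace_channel(raw5, "pressure_raw") - gt$icp,
               rep(5, length(gt$icp)))
  # full drift model compensated by the matching calibration
  cfg_full <- noiseless_config()
  rawf <- forward_pressure(gt, cfg_full)
  icp_hat <- calibrate_pressure(
    trace_channel(rawf, "pressure_raw"),
    trace_channel(rawf, "temp_device"),
    pressure_calibration(offset = cfg_full$pressure_offset,
                         temp_coeff = cfg_full$pressure_temp_coeff,
                         t_ref = rawf$metadata$t_ref))
  expect_equal(icp_hat, gt$icp, tolerance = 1e-10)
})

test_that("whole-episode determinism under a fixed seed", {
  cfg <- episode_config(duration = 60, seed = 33L)
  e1 <- simulate_episode(cfg)
  e2 <- simulate_episode(cfg)
  expect_identical(e1$pressure$channels, e2$pressure$channels)
  expect_identical(e1$ppg$channels, e2$ppg$channels)
  expect_identical(e1$thermistors$channels, e2$thermistors$channels)
})
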