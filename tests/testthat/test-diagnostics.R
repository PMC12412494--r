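test_that("delta_p: subtraction, sign convention, alignment", {
  icp <- mc_trace(0:10, list(icp = rep(40, 11)), c(icp = "mmHg"))
  expect_equal(unique(trace_channel(delta_p(70, icp), "delta_p")), 30)
  icp0 <- mc_trace(0:10, list(icp = rep(0, 11)), c(icp = "mmHg"))
  expect_equal(unique(trace_channel(delta_p(70, icp0), "delta_p")), 70)
  icp100 <- mc_trace(0:10, list(icp = rep(100, 11)), c(icp = "mmHg"))
  expect_equal(unique(trace_channel(delta_p(60, icp100), "delta_p")), -40)
  # DBP trace resampled onto the ICP base; disjoint supports refused
  dbp <- mc_trace(c(0, 10), list(dbp = c(60, 80)), c(dbp = "mmHg"))
  dp <- delta_p(dbp, icp)
  expect_equal(trace_channel(dp, "delta_p"), seq(60, 80, by = 2) - 40)
  dbp_far <- mc_trace(c(100, 110), list(dbp = c(60, 80)), c(dbp = "mmHg"))
  expect_error(delta_p(dbp_far, icp), class = "acs_alignment_error")
})

test_that("decision rule worked cases: sustained, never-below, broken runs", {
  t <- seq(0, 9000, by = 1)
  flag25 <- fasciotomy_flag(mc_trace(t, list(delta_p = rep(25, length(t))),
                                     c(delta_p = "mmHg")))
  expect_equal(nrow(flag25$alert_intervals), 1)
  expect_equal(flag25$earliest_flag_time, 7200)
  flag35 <- fasciotomy_flag(mc_trace(t, list(delta_p = rep(35, length(t))),
                                     c(delta_p = "mmHg")))
  expect_equal(nrow(flag35$alert_intervals), 0)
  expect_true(is.na(flag35$earliest_flag_time))
  # 1 h below, 10 min at/above, 1 h below: runs broken, no flag
  x <- c(rep(25, 3600), rep(35, 600), rep(25, 3600))
  broken <- fasciotomy_flag(mc_trace(seq_along(x) - 1,
                                     list(delta_p = x), c(delta_p = "mmHg")))
  expect_equal(nrow(broken$alert_intervals), 0)
  expect_equal(nrow(broken$all_below_runs), 2)
  expect_error(fasciotomy_flag(mc_trace(numeric(0), list(), character(0))),
               class = "acs_input_error")
})

test_that("decision rule agrees with the brute-force run-length oracle", {
  set.seed(99)
  rule <- diagnostic_rule(delta_p_threshold = 30, min_duration = 120)
  for (i in 1:200) {
    n <- sample(30:300, 1)
    dt <- sample(c(1, 2, 5), 1)
    t <- cumsum(c(0, rep(dt, n - 1)))
    if (runif(1) < 0.3) t <- t + cumsum(c(0, rbinom(n - 1, 1, 0.02) * 10 * dt))
    dp <- 30 + cumsum(rnorm(n, 0, 4))
    tr <- mc_trace(t, list(delta_p = dp), c(delta_p = "mmHg"))
    got <- fasciotomy_flag(tr, rule)$alert_intervals
    want <- oracle_alert_intervals(t, dp, rule$delta_p_threshold,
                                   rule$min_duration)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("rule monotonicity in threshold and duration", {
  set.seed(17)
  for (i in 1:30) {
    n <- 400
    t <- seq_len(n) - 1
    dp <- 30 + cumsum(rnorm(n, 0, 3))
    tr <- mc_trace(t, list(delta_p = dp), c(delta_p = "mmHg"))
    base <- fasciotomy_flag(tr, diagnostic_rule(30, 60))
    lower_thr <- fasciotomy_flag(tr, diagnostic_rule(25, 60))
    shorter <- fasciotomy_flag(tr, diagnostic_rule(30, 30))
    alert_time <- function(r) if (nrow(r$alert_intervals))
      sum(r$alert_intervals$end - r$alert_intervals$start) else 0
    expect_lte(alert_time(lower_thr), alert_time(base))
    expect_gte(nrow(shorter$alert_intervals), nrow(base$alert_intervals))
  }
})

test_that("modality summaries: identity, slope recovery, data requirements", {
  cfg <- episode_config(seed = 12)
  icp_tr <- generate_icp_trace(cfg)
  ref <- trace_channel(icp_tr, "icp")
  s <- correlate_modalities(icp_tr, list(pressure = ref))
  expect_equal(s$slope, 1, tolerance = 1e-9)
  expect_equal(s$pearson_r, 1, tolerance = 1e-9)
  # StO2 constructed with a known slope of -0.001/mmHg is recovered to 5%
  sto2 <- 0.7 - 0.001 * ref + rnorm(length(ref), 0, 0.002)
  s2 <- correlate_modalities(icp_tr, list(sto2 = sto2))
  expect_equal(s2$slope, -0.001, tolerance = 0.05)
  expect_lt(s2$pearson_r, 0)
  # fewer than three plateaus is an error
  short <- mc_trace(seq(0, 100, by = 0.05),
                    list(icp = rep(10, 2001)), c(icp = "mmHg"))
  expect_error(correlate_modalities(short, list(x = rep(1, 2001))),
               class = "acs_insufficient_data")
  # per-sample mode works without plateaus
  s3 <- correlate_modalities(short, list(x = rnorm(2001)), method = "sample")
  expect_equal(nrow(s3), 1)
})

test_that("battery endurance arithmetic and guards", {
  expect_equal(endurance_hours(370, 4.2, floor_to_int = TRUE), 88)
  expect_equal(endurance_hours(370, 14), 26.43, tolerance = 1e-3)
  expect_gte(endurance_hours(370, 14), 24)
  expect_error(endurance_hours(0, 14), class = "acs_input_error")
  expect_error(endurance_hours(370, -2), class = "acs_input_error")
})
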