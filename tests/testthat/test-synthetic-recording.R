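# Small sessions keep the forward model cheap to exercise; the full study
# protocol sizes are used in the acceptance tests.

test_that("stimulus trains are evenly spaced with the protocol geometry", {
  ev <- make_stimulus_train("electrical", 30, 3, start_s = 5)
  expect_equal(nrow(ev), 30)
  expect_equal(ev$ttl_time_s[1], 5)
  expect_equal(ev$ttl_time_s[30], 92)
  expect_true(all(diff(ev$ttl_time_s) == 3))

  ev1 <- make_stimulus_train("optical", 1, 5, start_s = 0,
                             pulse_duration_ms = 6, power_W = 0.5)
  expect_equal(nrow(ev1), 1)
  ev3 <- make_stimulus_train("optical", 3, 5, start_s = 1,
                             pulse_duration_ms = 10, power_W = 0.5)
  expect_equal(ev3$ttl_time_s, c(1, 6, 11))
  expect_error(make_stimulus_train("optical", 0, 5), "n_stimuli")
  expect_error(make_stimulus_train("optical", 3, 0), "interval_s")
})

test_that("same seed and config give bit-identical traces and truth", {
  lay <- default_layout()
  cfg <- sim_config(duration_s = 4, seed = 7, evoked_prob_per_channel = 0.5)
  ev <- make_stimulus_train("optical", 3, 1, start_s = 0.5)
  a <- simulate_session(lay, cfg, ev)
  b <- simulate_session(lay, cfg, ev)
  expect_identical(a$session$traces, b$session$traces)
  expect_identical(a$truth, b$truth)
})

test_that("TTX suppresses every spike but keeps both artifacts per pulse", {
  lay <- default_layout()
  cfg <- sim_config(duration_s = 12, seed = 2, ttx_applied = TRUE)
  ev <- make_stimulus_train("optical", 10, 1, start_s = 0.5,
                            pulse_duration_ms = 6)
  sim <- simulate_session(lay, cfg, ev)
  expect_equal(nrow(sim$truth$spikes), 0)
  # 2 artifact impulses per optical stimulus
  at <- sim$truth$artifact_times
  expect_equal(nrow(at) * 2, 20)
  expect_equal(at$offset_s - at$onset_s, rep(0.006, 10))
  # artifacts really are on the traces: large transients at the impulses
  j <- 1
  i0 <- round(at$onset_s[1] * cfg$sampling_rate_hz)
  expect_lt(min(sim$session$traces[i0:(i0 + 20), j]), -100)
})

test_that("synaptic blockers remove exactly the synaptic spikes", {
  lay <- default_layout()
  ev <- make_stimulus_train("electrical", 5, 1, start_s = 0.5)
  mk <- function(blk) sim_config(duration_s = 6, seed = 31, synaptic_prob = 0.7,
                                 evoked_prob_per_channel = 0.5,
                                 blockers_applied = blk)
  ctl <- simulate_session(lay, mk(FALSE), ev)
  blk <- simulate_session(lay, mk(TRUE), ev)
  expect_gt(sum(ctl$truth$spikes$label == "synaptic"), 0)
  expect_equal(sum(blk$truth$spikes$label == "synaptic"), 0)
  # sub-streams are independent: all non-synaptic spikes are shared exactly
  non_syn <- ctl$truth$spikes[ctl$truth$spikes$label != "synaptic", ]
  rownames(non_syn) <- NULL
  expect_equal(non_syn, blk$truth$spikes)
})

test_that("direct volleys span the channel with pitch/velocity delays", {
  lay <- default_layout()
  cfg <- sim_config(duration_s = 3, seed = 5, evoked_prob_per_channel = 1,
                    latency_jitter_ms = 0, synaptic_prob = 0,
                    conduction_velocity_mm_s = 360)
  ev <- make_stimulus_train("optical", 1, 1, start_s = 1,
                            pulse_duration_ms = 6)
  sim <- simulate_session(lay, cfg, ev)
  dir <- sim$truth$spikes[sim$truth$spikes$label == "direct", ]
  # every channel responded on all 3 electrodes (p = 1, no dropout)
  expect_equal(nrow(dir), 24)
  expect_equal(sum(sim$truth$outcomes$responded), 8)
  for (c_idx in 0:7) {
    ts <- sort(dir$time_s[dir$channel_index == c_idx])
    expect_equal(diff(ts), rep(200 / 360 / 1000, 2), tolerance = 1e-9)
  }
  # latency at the first electrode: TTL + delay + base + pitch/velocity
  t1 <- min(dir$time_s)
  expect_equal(t1, 1 + 0.010 + 0.012 + 200 / 360 / 1000, tolerance = 1e-9)
})

test_that("direct latencies stay below 15 ms and synaptic at or above it", {
  lay <- default_layout()
  cfg <- sim_config(duration_s = 8, seed = 13, evoked_prob_per_channel = 0.8,
                    synaptic_prob = 0.8)
  ev <- make_stimulus_train("optical", 6, 1.2, start_s = 0.5,
                            pulse_duration_ms = 6)
  sim <- simulate_session(lay, cfg, ev)
  sp <- sim$truth$spikes
  onset <- ev$ttl_time_s + 0.010
  lat_ms <- (sp$time_s - onset[sp$stimulus_index]) * 1000
  expect_true(all(lat_ms[sp$label == "direct"] < 15))
  expect_true(all(lat_ms[sp$label == "direct"] > 5))
  expect_true(all(lat_ms[sp$label == "synaptic"] >= 15 - 0.5))
})

test_that("direct spike conservation: 3 spikes per successful outcome", {
  lay <- default_layout()
  cfg <- sim_config(duration_s = 10, seed = 17, evoked_prob_per_channel = 0.4,
                    latency_jitter_ms = 0, synaptic_prob = 0)
  ev <- make_stimulus_train("optical", 8, 1, start_s = 0.6)
  sim <- simulate_session(lay, cfg, ev)
  for (c_idx in 0:7) {
    n_dir <- sum(sim$truth$spikes$label == "direct" &
                   sim$truth$spikes$channel_index == c_idx)
    n_ok <- sum(sim$truth$outcomes$responded[
      sim$truth$outcomes$channel_index == c_idx])
    expect_equal(n_dir, 3 * n_ok)
  }
  # every direct spike maps to exactly one stimulus
  dir <- sim$truth$spikes[sim$truth$spikes$label == "direct", ]
  expect_false(any(is.na(dir$stimulus_index)))
})

test_that("empirical outcome rate converges to the configured probability", {
  lay <- default_layout()
  p <- 0.33
  cfg <- sim_config(duration_s = 65, seed = 23, evoked_prob_per_channel = p,
                    noise_sigma_uV = 0, synaptic_prob = 0,
                    channel_propagation_prob = 0)
  ev <- make_stimulus_train("optical", 60, 1, start_s = 0.5)
  sim <- simulate_session(lay, cfg, ev)
  n <- 60 * 8
  rate <- mean(sim$truth$outcomes$responded)
  expect_lt(abs(rate - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("invalid configurations and events are rejected", {
  lay <- default_layout()
  expect_error(sim_config(duration_s = 5, conduction_velocity_mm_s = 0),
               "velocity")
  expect_error(sim_config(duration_s = 5, evoked_prob_per_channel = 1.2),
               "probabilities")
  expect_error(sim_config(duration_s = -1), "duration_s")
  cfg <- sim_config(duration_s = 2, seed = 1)
  ev <- make_stimulus_train("optical", 3, 1, start_s = 0.5)
  expect_error(simulate_session(lay, cfg, ev), "outside session duration")
})
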