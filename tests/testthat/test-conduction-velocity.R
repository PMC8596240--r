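lay <- default_layout()

test_that("spikes chained across a channel form one propagation event", {
  # electrode positions 200/400/600 um, 0.55 ms inter-electrode delays
  ce <- channel_electrodes(lay, 0)
  tr <- data.frame(electrode_id = ce$id,
                   time_s = c(1.0000, 1.00055, 1.00110))
  evs <- match_propagating_spikes(tr, lay, 0)
  expect_length(evs, 1)
  expect_equal(evs[[1]]$electrode_ids, ce$id)
  expect_equal(evs[[1]]$positions_um, c(200, 400, 600))
  expect_equal(evs[[1]]$times_s, tr$time_s)

  # empty trains: no events
  expect_length(match_propagating_spikes(tr[0, ], lay, 0), 0)
  expect_error(match_propagating_spikes(tr, lay, 0, max_lag_ms = 0),
               "max_lag_ms")
})

test_that("simultaneous spikes are not chained (strictly positive lag)", {
  ce <- channel_electrodes(lay, 0)
  tr <- data.frame(electrode_id = ce$id[1:2], time_s = c(1, 1))
  expect_length(match_propagating_spikes(tr, lay, 0, min_span = 2), 0)
})

test_that("reverse propagation is not matched and each spike joins one event", {
  ce <- channel_electrodes(lay, 0)
  # two forward volleys plus one reversed (times decreasing with position)
  tr <- data.frame(
    electrode_id = rep(ce$id, 3),
    time_s = c(1.0, 1.0006, 1.0012,
               2.0, 2.0006, 2.0012,
               3.0012, 3.0006, 3.0))
  tr <- tr[order(tr$electrode_id, tr$time_s), ]
  evs <- match_propagating_spikes(tr, lay, 0)
  expect_length(evs, 2)
  used <- unlist(lapply(evs, function(e) paste(e$electrode_ids, e$times_s)))
  expect_false(anyDuplicated(used) > 0)
})

test_that("event velocity is the least-squares slope of position on time", {
  # 0/200/400 um at 0/0.5263/1.0526 ms: the hippocampal literature velocity
  ev1 <- manual_event(0, c(0, 200, 400), c(0, 0.5263, 1.0526) / 1000)
  est1 <- estimate_velocity(list(ev1, ev1, ev1), min_events = 3)
  expect_equal(est1$mean_mm_s, oracle_slope_mm_s(c(0, 200, 400),
                                                 c(0, 0.5263, 1.0526) / 1000))
  expect_equal(est1$mean_mm_s, 380.0, tolerance = 0.1)

  # 0.554 ms per 200 um pitch: the study's measured velocity scale
  ev2 <- manual_event(1, c(200, 400, 600),
                      1 + c(0, 0.554, 1.108) / 1000)
  est2 <- estimate_velocity(list(ev2, ev2, ev2), min_events = 3)
  expect_equal(est2$mean_mm_s, 0.2 / 0.000554, tolerance = 1e-6)
  expect_equal(est2$mean_mm_s, 361.0, tolerance = 0.1)
})

test_that("degenerate and backward events are discarded", {
  ok <- manual_event(0, c(200, 400, 600), 1 + c(0, 0.5, 1.0) / 1000)
  flat <- manual_event(0, c(200, 400), c(2, 2))
  expect_warning(est <- estimate_velocity(list(ok, ok, ok, flat),
                                          min_events = 3),
                 "zero time spread")
  expect_equal(est$per_channel$n_events, 3L)
  back <- manual_event(0, c(200, 400, 600), 1 + c(1.0, 0.5, 0) / 1000)
  expect_error(suppressWarnings(estimate_velocity(list(back, flat))),
               "no usable propagation events")
  expect_error(estimate_velocity(list(ok), min_events = 5), "at least")
})

test_that("velocity is invariant under time translation of all spikes", {
  set.seed(31)
  cfg <- sim_config(duration_s = 12, seed = 19, noise_sigma_uV = 0,
                    synaptic_prob = 0)
  sim <- simulate_session(lay, cfg, NULL)
  sp <- detect_session(sim$session)
  v1 <- velocity_from_trains(sp, lay, min_events = 1)
  sp2 <- sp
  sp2$time_s <- sp2$time_s + 123.456
  v2 <- velocity_from_trains(sp2, lay, min_events = 1)
  expect_equal(v2$per_channel$velocity_mm_s, v1$per_channel$velocity_mm_s,
               tolerance = 1e-9)
})

test_that("channels with one electrode cannot be analysed", {
  tiny <- default_layout(n_channels = 2, electrodes_per_channel = 1,
                         n_electrodes = 10)
  expect_error(match_propagating_spikes(
    data.frame(electrode_id = 1L, time_s = 1), tiny, 0), "fewer than 2")
})
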