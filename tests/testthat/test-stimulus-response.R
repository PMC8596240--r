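lay60 <- default_layout()

test_that("PSTH pools latencies into half-open 1 ms bins", {
  # pulse onset at 1.0 s (TTL 0.99 + 10 ms delay); spike 10 ms later
  ev <- make_stimulus_train("optical", 1, 5, start_s = 0.99,
                            pulse_duration_ms = 6)
  tr <- data.frame(electrode_id = 1L, time_s = 1.010)
  ps <- compute_psth(tr, ev, lay60)
  expect_equal(sum(ps$counts), 1)
  expect_equal(unname(ps$counts["1", 11]), 1L)  # bin [10, 11)
  expect_equal(ps$n_stimuli, 1)

  # no spikes at all: all-zero counts
  ps0 <- compute_psth(tr[0, ], ev, lay60)
  expect_true(all(ps0$counts == 0))

  expect_error(compute_psth(tr, ev[0, ], lay60), "no stimuli")
})

test_that("induced-window counting covers 5-50 ms only", {
  ev <- make_stimulus_train("electrical", 1, 5, start_s = 1)
  tr <- data.frame(electrode_id = rep(1L, 3),
                   time_s = 1 + c(3, 7, 20) / 1000)
  ps <- compute_psth(tr, ev, lay60)
  starts <- ps$bin_edges_ms[-length(ps$bin_edges_ms)]
  induced <- sum(ps$counts[, starts >= 5 & starts < 50])
  expect_equal(induced, 2)
  expect_equal(sum(ps$counts), 3)
})

test_that("PSTH total equals the brute-force pooled in-window count", {
  set.seed(21)
  for (rep_i in 1:20) {
    n_ev <- sample(2:6, 1)
    ev <- make_stimulus_train("optical", n_ev, runif(1, 0.3, 1), start_s = 0.2)
    ids <- sample(microchannel_electrodes(lay60), 6)
    tr <- data.frame(
      electrode_id = sample(ids, 80, replace = TRUE),
      time_s = runif(80, 0, 0.2 + n_ev))
    tr <- tr[order(tr$electrode_id, tr$time_s), ]
    ps <- compute_psth(tr, ev, lay60)
    refs <- ev$ttl_time_s + 0.010
    expect_equal(sum(ps$counts), oracle_psth_total(tr, refs, c(0, 50)))
  }
})

test_that("response probability is the per-electrode hit fraction", {
  ev <- make_stimulus_train("optical", 30, 1, start_s = 0.5)
  onsets <- ev$ttl_time_s + 0.010
  # electrode 1 responds to every stimulus; electrode 4 to exactly 3
  tr <- data.frame(
    electrode_id = c(rep(1L, 30), rep(4L, 3)),
    time_s = c(onsets + 0.012, onsets[c(2, 9, 17)] + 0.030))
  tr <- tr[order(tr$electrode_id, tr$time_s), ]
  pr <- response_probability(tr, ev, lay60)
  expect_equal(pr$table$prob[pr$table$electrode_id == 1], 1.0)
  expect_equal(pr$table$prob[pr$table$electrode_id == 4], 0.1)
  expect_equal(pr$n_stimuli, 30)
  # electrodes 1 (channel 0) and 4 (channel 1) are responsive
  expect_equal(pr$responsive_channels, 2)
  expect_equal(pr$mean, (1 + 0.1) / 24)
  expect_error(response_probability(tr, ev[0, ], lay60), "no stimuli")
})

test_that("adding spikes never decreases any per-electrode probability", {
  set.seed(8)
  ev <- make_stimulus_train("optical", 10, 0.5, start_s = 0.3)
  for (rep_i in 1:10) {
    base <- data.frame(
      electrode_id = sample(1:24, 50, replace = TRUE),
      time_s = runif(50, 0, 5.5))
    extra <- data.frame(
      electrode_id = sample(1:24, 10, replace = TRUE),
      time_s = runif(10, 0, 5.5))
    p1 <- response_probability(base, ev, lay60)$table$prob
    p2 <- response_probability(rbind(base, extra), ev, lay60)$table$prob
    expect_true(all(p2 >= p1))
  }
})

test_that("direct/synaptic classification splits at the 15 ms cutoff", {
  ev <- make_stimulus_train("electrical", 1, 5, start_s = 1)
  mk <- function(lat_ms) {
    tr <- data.frame(electrode_id = rep(1L, length(lat_ms)),
                     time_s = 1 + lat_ms / 1000)
    compute_psth(tr, ev, lay60)
  }
  # control: direct at 8 ms + synaptic at 25 ms; blocked: direct only
  cl <- classify_components(mk(c(8, 25)), mk(8))
  expect_equal(cl$direct_count, 1)
  expect_equal(cl$synaptic_count, 1)
  expect_true(cl$direct_persists)

  # identical PSTHs entirely below the cutoff: nothing synaptic
  cl2 <- classify_components(mk(c(8, 9)), mk(c(8, 9)))
  expect_equal(cl2$synaptic_count, 0)
  expect_true(cl2$direct_persists)

  # both empty: zero counts, persistence holds by the floor rule
  cl3 <- classify_components(mk(numeric()), mk(numeric()))
  expect_equal(cl3$direct_count, 0)
  expect_equal(cl3$synaptic_count, 0)
  expect_true(cl3$direct_persists)

  # mismatched binning is refused
  ps_a <- mk(8)
  ps_b <- compute_psth(data.frame(electrode_id = 1L, time_s = 1.008), ev,
                       lay60, window_config(bin_ms = 2))
  expect_error(classify_components(ps_a, ps_b), "binning")
})

test_that("latencies reference the TTL for electrical stimuli", {
  # same spike time, 10 ms after the TTL marker
  tr <- data.frame(electrode_id = 1L, time_s = 1.010)
  eve <- make_stimulus_train("electrical", 1, 5, start_s = 1)
  evo <- make_stimulus_train("optical", 1, 5, start_s = 1,
                             pulse_duration_ms = 6)
  ps_e <- compute_psth(tr, eve, lay60)
  ps_o <- compute_psth(tr, evo, lay60)
  expect_equal(unname(ps_e$counts["1", 11]), 1L)  # 10 ms after TTL
  expect_equal(unname(ps_o$counts["1", 1]), 1L)   # 0 ms after pulse onset
})
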