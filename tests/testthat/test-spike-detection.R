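test_that("robust noise sigma follows the MAD definition", {
  expect_equal(estimate_noise_sigma(rep(0, 100)), 0)
  expect_equal(estimate_noise_sigma(rep(5, 100)), 0)
  # alternating +/-0.6745 uV: MAD = 0.6745, scaled sigma = 1.0 exactly
  expect_equal(estimate_noise_sigma(rep(c(0.6745, -0.6745), 50)), 1.0)
  expect_error(estimate_noise_sigma(numeric()), "empty")
  # consistency on Gaussian noise
  set.seed(1)
  expect_equal(estimate_noise_sigma(rnorm(50000, sd = 4)), 4, tolerance = 0.1)
})

test_that("a flat trace yields no spikes and bad sampling rates error", {
  expect_equal(detect_spikes(rep(0, 1000), 20000), numeric())
  expect_error(detect_spikes(rep(0, 1000), 0), "sampling rate")
  expect_error(detect_spikes(numeric(), 20000), "empty")
})

test_that("an isolated deflection is found at its trough time", {
  fs <- 20000
  tr <- rep(0, 2000)
  t_spike <- 0.05
  idx <- which(abs((seq_along(tr) - 1) / fs - t_spike) < 0.0006)
  u <- ((idx - 1) / fs - (t_spike - 0.0002)) * 1000
  tr[idx] <- -10 * sin(pi * pmin(pmax(u / 0.4, 0), 1))
  got <- detect_spikes(tr, fs)
  ref <- oracle_detect(tr, fs)
  expect_length(got, 1)
  expect_length(ref, 1)
  expect_equal(got, t_spike, tolerance = 2e-4)
  expect_equal(got, ref, tolerance = 1 / fs)
})

test_that("the dead time suppresses a second deflection 0.5 ms later", {
  fs <- 20000
  tr <- rep(0, 4000)
  for (t0 in c(0.05, 0.0505)) {
    i0 <- round(t0 * fs) + 1
    tr[i0 + 0:3] <- -10
  }
  got <- detect_spikes(tr, fs)
  expect_length(got, 1)
  expect_length(oracle_detect(tr, fs), 1)
  # spacing beyond the dead time keeps both
  tr2 <- rep(0, 4000)
  for (t0 in c(0.05, 0.052)) {
    i0 <- round(t0 * fs) + 1
    tr2[i0 + 0:3] <- -10
  }
  expect_length(detect_spikes(tr2, fs), 2)
})

test_that("detection is invariant to a constant voltage offset", {
  set.seed(4)
  fs <- 20000
  tr <- rnorm(20000, sd = 5)
  for (t0 in c(0.1, 0.3, 0.72)) {
    i0 <- round(t0 * fs) + 1
    tr[i0 + 0:4] <- tr[i0 + 0:4] - 40
  }
  expect_equal(detect_spikes(tr + 137.5, fs), detect_spikes(tr, fs))
})

test_that("artifact windows blank detections at onset and offset delays", {
  # one pulse: TTL 1.0 s, 10 ms TTL-to-pulse delay, 6 ms pulse
  ev <- make_stimulus_train("optical", 1, 5, start_s = 1,
                            pulse_duration_ms = 6)
  tr <- data.frame(electrode_id = rep(1L, 4),
                   time_s = c(0.5, 1.010, 1.0165, 1.030))
  out <- blank_artifacts(tr, ev, blank_ms = 2)
  expect_equal(out$time_s, c(0.5, 1.030))
  expect_equal(attr(out, "n_removed"), 2)
  iv <- attr(out, "blanked_intervals_s")
  expect_equal(iv$start_s, c(1.008, 1.014))
  expect_equal(iv$end_s, c(1.012, 1.018))

  # trains away from any artifact pass through unchanged
  far <- data.frame(electrode_id = 1L, time_s = c(0.2, 3.0))
  out2 <- blank_artifacts(far, ev)
  expect_equal(out2$time_s, far$time_s)
  expect_equal(attr(out2, "n_removed"), 0)

  # electrical stimuli generate no artifact windows
  eve <- make_stimulus_train("electrical", 3, 1, start_s = 0.5)
  out3 <- blank_artifacts(tr, eve)
  expect_equal(nrow(out3), 4)
})

test_that("detector matches the per-sample scan oracle on random traces", {
  # spot check here; the full 100-trace sweep lives in the acceptance suite
  set.seed(11)
  fs <- 20000
  for (rep_i in 1:10) {
    tr <- rnorm(8000, sd = 5)
    # gaps either inside or clearly outside the 1 ms dead time (never at
    # its boundary, where sample- and sub-sample timing could disagree)
    short <- runif(12) < 0.4
    gaps <- ifelse(short, runif(12, 0.0004, 0.00085), runif(12, 0.0012, 0.02))
    times <- 0.02 + cumsum(gaps)
    for (t0 in times) {
      i0 <- round(t0 * fs) + 1
      if (i0 + 4 <= length(tr)) tr[i0 + 0:4] <- tr[i0 + 0:4] - runif(1, 20, 60)
    }
    got <- detect_spikes(tr, fs)
    ref <- oracle_detect(tr, fs)
    expect_equal(length(got), length(ref))
    if (length(got)) expect_lt(max(abs(got - ref)), 1 / fs + 1e-12)
  }
})
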