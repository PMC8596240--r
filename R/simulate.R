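#' Simulation configuration for synthetic chip recordings
#'
#' Collects every tunable of the forward model. Defaults emulate the
#' statistical structure of recordings from hippocampal cultures on a
#' microfluidic chip/MEA: spontaneous bursts separated by 2-10 s that
#' propagate into the microchannels, stimulus-evoked direct axonal responses
#' travelling at ~360 mm/s, synaptic responses at latencies above 15 ms that
#' disappear under AMPA/NMDA blockade, large optical stimulation artifacts at
#' pulse onset and offset, and additive Gaussian electrode noise, all sampled
#' at 20 kHz.
#'
#' @param duration_s session length in seconds.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param noise_sigma_uV standard deviation of the additive Gaussian noise
#'   (uV); 0 gives noise-free traces.
#' @param spike_amplitude_uV trough depth of the extracellular spike template
#'   (uV). The template is a negative-leading biphasic wave of total width
#'   `spike_width_ms`.
#' @param spike_width_ms total spike template width (ms).
#' @param burst_interval_range_s range of intervals between successive
#'   spontaneous bursts (s).
#' @param spikes_per_burst_range integer range of spikes per burst.
#' @param intraburst_isi_range_s range of inter-spike intervals inside a
#'   burst (s).
#' @param channel_propagation_prob probability that a burst spike propagates
#'   as an axonal volley through a given microchannel.
#' @param conduction_velocity_mm_s axonal conduction velocity (mm/s).
#' @param velocity_jitter_frac fractional per-channel spread of the true
#'   velocity (0 = all channels identical).
#' @param evoked_prob_per_channel Bernoulli probability that a stimulus evokes
#'   a direct axonal response in a channel; scalar (recycled) or one value per
#'   channel. The mapping from radiation power to this probability is an
#'   empirical finding, not part of the model, so callers set it per
#'   condition.
#' @param direct_latency_base_ms latency from pulse onset to the channel
#'   entrance for direct responses (ms). The default of 12 keeps all
#'   in-channel direct latencies inside the sub-15 ms direct window while
#'   staying clear of the blanked artifact intervals at pulse onset and
#'   offset for 6 and 10 ms pulses.
#' @param latency_jitter_ms Gaussian jitter applied independently to each
#'   spike time (ms).
#' @param synaptic_prob probability that a stimulus additionally evokes a
#'   synaptically mediated volley in a channel (suppressed when
#'   `blockers_applied`).
#' @param synaptic_latency_range_ms latency range of synaptic responses after
#'   pulse onset (ms); at and above the 15 ms direct/synaptic boundary.
#' @param blockers_applied if `TRUE`, CNQX/CPP-style synaptic blockade: no
#'   synaptic responses are generated.
#' @param ttx_applied if `TRUE`, TTX-style sodium-channel blockade: no spikes
#'   of any kind are generated; stimulation artifacts remain.
#' @param artifact_amplitude_uV peak amplitude of the optical stimulation
#'   artifact (uV); default 10x the spike amplitude, so artifact blanking is
#'   a necessity rather than a nicety.
#' @param artifact_tau_ms time constant of the critically damped artifact
#'   transient (ms); the transient has decayed into the noise ~2 ms after
#'   each optical impulse.
#' @param seed integer seed governing all randomness; sub-streams for bursts,
#'   evoked outcomes, synaptic responses and per-electrode noise are derived
#'   deterministically from it, so flipping `blockers_applied` changes
#'   nothing but the synaptic spikes.
#' @param label free-text condition label (e.g. `"0.5 W, 6 ms"`).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration_s,
                       sampling_rate_hz = 20000,
                       noise_sigma_uV = 5,
                       spike_amplitude_uV = 40,
                       spike_width_ms = 1,
                       burst_interval_range_s = c(2, 10),
                       spikes_per_burst_range = c(3L, 8L),
                       intraburst_isi_range_s = c(0.03, 0.1),
                       channel_propagation_prob = 1,
                       conduction_velocity_mm_s = 360,
                       velocity_jitter_frac = 0,
                       evoked_prob_per_channel = 0.5,
                       direct_latency_base_ms = 12,
                       latency_jitter_ms = 0.1,
                       synaptic_prob = 0.5,
                       synaptic_latency_range_ms = c(15, 40),
                       blockers_applied = FALSE,
                       ttx_applied = FALSE,
                       artifact_amplitude_uV = 400,
                       artifact_tau_ms = 0.3,
                       seed = 1L,
                       label = "") {
  cfg <- as.list(environment())
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (conduction_velocity_mm_s <= 0)
    stop("conduction_velocity_mm_s must be positive")
  probs <- c(evoked_prob_per_channel, synaptic_prob, channel_propagation_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (noise_sigma_uV < 0) stop("noise_sigma_uV must be non-negative")
  if (synaptic_latency_range_ms[1] < 0 ||
      diff(synaptic_latency_range_ms) < 0)
    stop("synaptic_latency_range_ms must be an increasing non-negative range")
  structure(cfg, class = "sim_config")
}

#' Build an evenly spaced stimulus train
#'
#' Events follow the stimulation protocols of the study: electrical trains of
#' biphasic impulses (e.g. 30 impulses at 3 s intervals, 800 mV) marked by
#' their delivery time, and optical trains of laser pulses (6 or 10 ms at 5 s
#' intervals) marked by a TTL signal that precedes the pulse by a fixed delay
#' (~10 ms).
#'
#' @param kind `"electrical"` or `"optical"`.
#' @param n_stimuli number of stimuli (>= 1).
#' @param interval_s inter-stimulus interval (s, > 0).
#' @param start_s TTL time of the first stimulus (s).
#' @param pulse_duration_ms optical pulse duration (ms); ignored for
#'   electrical stimuli.
#' @param power_W optical radiation power (W), metadata carried through to
#'   result tables.
#' @param amplitude_mV electrical stimulus amplitude (mV), metadata.
#' @param ttl_to_pulse_delay_ms delay between TTL marker and the optical
#'   pulse (ms).
#' @param target where the stimulus is aimed: `"chamber"` (cell somas) or
#'   `"channels"` (the axons themselves), metadata.
#' @return Data frame of stimulus events with one row per stimulus, columns
#'   `kind`, `ttl_time_s`, `pulse_duration_ms`, `ttl_to_pulse_delay_ms`,
#'   `power_W`, `amplitude_mV`, `target`, sorted by `ttl_time_s`.
#' @examples
#' ev <- make_stimulus_train("electrical", 30, 3, start_s = 5)
#' range(ev$ttl_time_s)  # 5 .. 92
#' @export
make_stimulus_train <- function(kind = c("electrical", "optical"),
                                n_stimuli,
                                interval_s,
                                start_s = 0,
                                pulse_duration_ms = 6,
                                power_W = NA_real_,
                                amplitude_mV = 800,
                                ttl_to_pulse_delay_ms = 10,
                                target = c("chamber", "channels")) {
  kind <- match.arg(kind)
  target <- match.arg(target)
  if (n_stimuli < 1) stop("n_stimuli must be >= 1")
  if (interval_s <= 0) stop("interval_s must be positive")
  if (kind == "optical" && pulse_duration_ms <= 0)
    stop("pulse_duration_ms must be positive for optical stimuli")
  data.frame(
    kind = kind,
    ttl_time_s = start_s + (seq_len(n_stimuli) - 1) * interval_s,
    pulse_duration_ms = if (kind == "optical") pulse_duration_ms else NA_real_,
    ttl_to_pulse_delay_ms = if (kind == "optical") ttl_to_pulse_delay_ms else 0,
    power_W = power_W,
    amplitude_mV = if (kind == "electrical") amplitude_mV else NA_real_,
    target = target,
    stringsAsFactors = FALSE
  )
}

# internal: biphasic extracellular spike template, unit trough depth.
# u_ms is time since waveform start; negative lobe over the first 40% of the
# width (trough at 0.2 * width), smaller positive rebound over the rest.
spike_waveform <- function(u_ms, width_ms = 1) {
  a <- 0.4 * width_ms
  w <- numeric(length(u_ms))
  i1 <- u_ms >= 0 & u_ms < a
  w[i1] <- -sin(pi * u_ms[i1] / a)
  i2 <- u_ms >= a & u_ms <= width_ms
  w[i2] <- 0.3 * sin(pi * (u_ms[i2] - a) / (width_ms - a))
  w
}

# internal: sample indices and values of one template placed at time t_s
# (t_s = trough time), evaluated on the continuous waveform so sub-sample
# placement is preserved.
template_samples <- function(t_s, fs, amp, width_ms, n_samples) {
  t0 <- t_s - 0.2 * width_ms / 1000
  i0 <- floor(t0 * fs) + 1
  idx <- i0:(i0 + ceiling(width_ms / 1000 * fs) + 1L)
  idx <- idx[idx >= 1L & idx <= n_samples]
  if (!length(idx)) return(NULL)
  u <- ((idx - 1) / fs - t0) * 1000
  list(idx = idx, val = amp * spike_waveform(u, width_ms))
}

# internal: critically damped artifact transient starting at t_s, peak
# depth -amp at t_s + tau.
artifact_samples <- function(t_s, fs, amp, tau_ms, n_samples) {
  tau_s <- tau_ms / 1000
  i0 <- floor(t_s * fs) + 1
  idx <- i0:(i0 + ceiling(10 * tau_s * fs))
  idx <- idx[idx >= 1L & idx <= n_samples]
  if (!length(idx)) return(NULL)
  u <- (idx - 1) / fs - t_s
  u[u < 0] <- 0
  list(idx = idx, val = -amp * (u / tau_s) * exp(1 - u / tau_s))
}

#' Simulate a chip recording session with ground truth
#'
#' Forward model of a multichannel extracellular recording. Spontaneous
#' bursts are generated in the chambers and propagate as axonal volleys
#' through the microchannels; each stimulus evokes, independently per
#' channel, a direct axonal volley with the configured probability (latency
#' `direct_latency_base_ms` after pulse onset at the channel entrance, spikes
#' on the channel's electrodes delayed by position/velocity) and, unless
#' blockers are applied, a synaptic volley at a latency above 15 ms. Optical
#' stimuli additionally inject large artifact transients on every electrode
#' at pulse onset and pulse offset. TTX suppresses all spikes but not the
#' artifacts. Gaussian noise is added throughout. The same seed and
#' configuration always reproduce bit-identical traces and truth.
#'
#' @param layout a `chip_layout`.
#' @param config a `sim_config`.
#' @param events stimulus event data frame from [make_stimulus_train()] (or
#'   `NULL` for a stimulus-free session); TTL times must be strictly
#'   increasing and lie inside the session.
#' @return A list with elements:
#' \describe{
#'   \item{session}{`recording_session`: `traces` (samples x electrodes
#'     matrix, uV, column names = electrode ids), `sampling_rate_hz`,
#'     `duration_s`, `electrode_ids`, `events`, `condition`.}
#'   \item{truth}{`ground_truth`: `spikes` (electrode_id, time_s, label in
#'     spontaneous/direct/synaptic, stimulus_index, channel_index),
#'     `outcomes` (stimulus_index, channel_index, responded),
#'     `true_velocity_mm_s` (per channel), `artifact_times` (stimulus_index,
#'     onset_s, offset_s).}
#' }
#' @export
simulate_session <- function(layout, config, events = NULL) {
  validate_layout(layout)
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (is.null(events)) events <- make_stimulus_train("optical", 1, 1)[0, ]
  if (nrow(events) > 1 && any(diff(events$ttl_time_s) <= 0))
    stop("stimulus events must be strictly increasing in time")
  if (nrow(events) && (min(events$ttl_time_s) < 0 ||
                       max(events$ttl_time_s) >= config$duration_s))
    stop(sprintf("stimulus event at %.3f s lies outside session duration %.3f s",
                 events$ttl_time_s[which.max(events$ttl_time_s)],
                 config$duration_s))

  fs <- config$sampling_rate_hz
  n_samples <- round(config$duration_s * fs)
  el <- layout$electrodes
  n_el <- nrow(el)
  n_ch <- layout$n_channels
  chamber_ids <- el$id[el$compartment != "microchannel"]
  ch_info <- lapply(seq_len(n_ch) - 1L, function(c_idx)
    channel_electrodes(layout, c_idx))

  p_evoked <- rep(config$evoked_prob_per_channel, length.out = n_ch)
  jit_s <- config$latency_jitter_ms / 1000

  # per-channel true velocity (sub-stream 5)
  set.seed(sub_seed(config$seed, 5))
  v_ch <- config$conduction_velocity_mm_s *
    (1 + config$velocity_jitter_frac * rnorm(n_ch))
  if (any(v_ch <= 0)) stop("per-channel velocity became non-positive")

  # accumulate true spikes as parallel vectors
  acc <- list(id = integer(), t = numeric(), lab = character(),
              stim = integer(), chan = integer())
  push <- function(ids, ts, lab, stim, chan) {
    acc$id <<- c(acc$id, as.integer(ids))
    acc$t <<- c(acc$t, ts)
    acc$lab <<- c(acc$lab, rep(lab, length(ts)))
    acc$stim <<- c(acc$stim, rep(as.integer(stim), length.out = length(ts)))
    acc$chan <<- c(acc$chan, rep(as.integer(chan), length.out = length(ts)))
  }
  channel_volley <- function(entry_s, c_idx, lab, stim) {
    info <- ch_info[[c_idx + 1L]]
    ts <- entry_s + (info$position_um / 1000) / v_ch[c_idx + 1L] +
      rnorm(nrow(info), 0, jit_s)
    push(info$id, ts, lab, stim, c_idx)
  }

  # --- spontaneous bursts (sub-stream 1) ---
  if (!config$ttx_applied) {
    set.seed(sub_seed(config$seed, 1))
    t_burst <- runif(1, 0.3, 1.5)
    while (t_burst < config$duration_s - 0.5) {
      nsp <- sample(config$spikes_per_burst_range[1]:config$spikes_per_burst_range[2], 1)
      sp_times <- t_burst + cumsum(runif(nsp, config$intraburst_isi_range_s[1],
                                         config$intraburst_isi_range_s[2]))
      for (sp in sp_times) {
        if (length(chamber_ids))
          push(chamber_ids, sp + rnorm(length(chamber_ids), 0, 0.002),
               "spontaneous", NA_integer_, NA_integer_)
        for (c_idx in seq_len(n_ch) - 1L) {
          if (runif(1) < config$channel_propagation_prob)
            channel_volley(sp + runif(1, 0.001, 0.003), c_idx,
                           "spontaneous", NA_integer_)
        }
      }
      t_burst <- t_burst + runif(1, config$burst_interval_range_s[1],
                                 config$burst_interval_range_s[2])
    }
  }

  # pulse onset per stimulus (TTL + TTL-to-pulse delay for optical)
  onset_s <- if (nrow(events))
    events$ttl_time_s + ifelse(events$kind == "optical",
                               events$ttl_to_pulse_delay_ms / 1000, 0)
  else numeric()

  # --- evoked direct responses (sub-stream 2) ---
  outcomes <- data.frame(stimulus_index = integer(), channel_index = integer(),
                         responded = logical())
  if (nrow(events)) {
    outcomes <- data.frame(
      stimulus_index = rep(seq_len(nrow(events)), each = n_ch),
      channel_index = rep(seq_len(n_ch) - 1L, times = nrow(events)),
      responded = FALSE
    )
    if (!config$ttx_applied) {
      set.seed(sub_seed(config$seed, 2))
      for (i in seq_len(nrow(events))) {
        hit <- runif(n_ch) < p_evoked
        outcomes$responded[outcomes$stimulus_index == i] <- hit
        for (c_idx in which(hit) - 1L)
          channel_volley(onset_s[i] + config$direct_latency_base_ms / 1000,
                         c_idx, "direct", i)
      }
    }
  }

  # --- synaptic responses (sub-stream 3) ---
  if (nrow(events) && !config$ttx_applied && !config$blockers_applied &&
      config$synaptic_prob > 0) {
    set.seed(sub_seed(config$seed, 3))
    for (i in seq_len(nrow(events))) {
      for (c_idx in seq_len(n_ch) - 1L) {
        if (runif(1) < config$synaptic_prob) {
          lat <- runif(1, config$synaptic_latency_range_ms[1],
                       config$synaptic_latency_range_ms[2]) / 1000
          channel_volley(onset_s[i] + lat, c_idx, "synaptic", i)
        }
      }
    }
  }

  # drop spikes whose template would straddle the session edge
  margin <- 1.5 * config$spike_width_ms / 1000
  keep <- acc$t > margin & acc$t < config$duration_s - margin
  spikes <- data.frame(electrode_id = acc$id[keep], time_s = acc$t[keep],
                       label = acc$lab[keep], stimulus_index = acc$stim[keep],
                       channel_index = acc$chan[keep],
                       stringsAsFactors = FALSE)
  spikes <- spikes[order(spikes$electrode_id, spikes$time_s), , drop = FALSE]
  rownames(spikes) <- NULL

  # --- synthesize traces ---
  traces <- matrix(0, nrow = n_samples, ncol = n_el,
                   dimnames = list(NULL, as.character(el$id)))
  col_of <- match(spikes$electrode_id, el$id)
  for (r in seq_len(nrow(spikes))) {
    tp <- template_samples(spikes$time_s[r], fs, config$spike_amplitude_uV,
                           config$spike_width_ms, n_samples)
    if (!is.null(tp))
      traces[tp$idx, col_of[r]] <- traces[tp$idx, col_of[r]] + tp$val
  }

  # optical artifacts at pulse onset and offset, on every electrode
  is_opt <- nrow(events) > 0 & events$kind == "optical"
  artifact_times <- data.frame(stimulus_index = integer(), onset_s = numeric(),
                               offset_s = numeric())
  if (any(is_opt)) {
    artifact_times <- data.frame(
      stimulus_index = which(is_opt),
      onset_s = onset_s[is_opt],
      offset_s = onset_s[is_opt] + events$pulse_duration_ms[is_opt] / 1000
    )
    for (r in seq_len(nrow(artifact_times))) {
      for (t_a in c(artifact_times$onset_s[r], artifact_times$offset_s[r])) {
        ar <- artifact_samples(t_a, fs, config$artifact_amplitude_uV,
                               config$artifact_tau_ms, n_samples)
        if (!is.null(ar)) traces[ar$idx, ] <- traces[ar$idx, ] + ar$val
      }
    }
  }

  # per-electrode noise (sub-streams 1000 + column)
  if (config$noise_sigma_uV > 0) {
    for (j in seq_len(n_el)) {
      set.seed(sub_seed(config$seed, 1000 + j))
      traces[, j] <- traces[, j] + rnorm(n_samples, 0, config$noise_sigma_uV)
    }
  }

  session <- structure(
    list(
      sampling_rate_hz = fs,
      duration_s = config$duration_s,
      traces = traces,
      electrode_ids = el$id,
      events = events,
      condition = list(blockers_applied = config$blockers_applied,
                       ttx_applied = config$ttx_applied,
                       label = config$label)
    ),
    class = "recording_session"
  )
  truth <- structure(
    list(
      spikes = spikes,
      outcomes = outcomes,
      true_velocity_mm_s = setNames(v_ch, paste0("channel_", seq_len(n_ch) - 1L)),
      artifact_times = artifact_times
    ),
    class = "ground_truth"
  )
  list(session = session, truth = truth)
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "recording_session: %d electrodes, %.1f s at %g Hz, %d stimuli%s%s\n",
    ncol(x$traces), x$duration_s, x$sampling_rate_hz, nrow(x$events),
    if (isTRUE(x$condition$blockers_applied)) ", blockers" else "",
    if (isTRUE(x$condition$ttx_applied)) ", TTX" else ""))
  invisible(x)
}
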