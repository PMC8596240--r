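#!/usr/bin/env Rscript
# Step 4 — conduction velocity along the microchannels.
#
# Chains spontaneous spikes across each channel's electrodes (200 um pitch)
# and regresses position on time; the per-channel median slope is the
# channel's velocity.

suppressMessages(library(axonmea))

res_dir <- "results/velocity"
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
lay <- read_layout("results/simulated/layout.json")

spikes <- read_spike_table("results/spikes/spontaneous_spikes.csv")
vel <- velocity_from_trains(spikes, lay, max_lag_ms = 5, min_events = 5)

out <- rbind(
  data.frame(channel_index = as.character(vel$per_channel$channel_index),
             velocity_mm_s = vel$per_channel$velocity_mm_s,
             n_events = vel$per_channel$n_events),
  data.frame(channel_index = "mean", velocity_mm_s = vel$mean_mm_s,
             n_events = sum(vel$per_channel$n_events)))
write.csv(out, file.path(res_dir, "velocity.csv"), row.names = FALSE)
message(sprintf("Velocity: %.0f +/- %.0f mm/s over %d channels (configured 360).",
                vel$mean_mm_s, vel$sd_mm_s, vel$n_channels))
message("Per-channel table written to ", res_dir, "/velocity.csv.")
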