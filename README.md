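# axonmea

Analysis of stimulus-evoked axonal activity recorded on microelectrode
arrays (MEAs) aligned with PDMS microfluidic chips.

In this preparation, hippocampal neurons cultured in two chambers send
their axons into eight 800 µm microchannels that exclude somata and
dendrites. The 60-electrode array (200 µm pitch) puts three electrodes
under each channel, so isolated multi-unit axonal signals are recorded at
known positions along every channel at 20 kHz. Neurons are stimulated
either electrically (trains of biphasic impulses) or with short infrared
laser pulses gated by a shutter whose TTL marker precedes the pulse by
~10 ms. The analysis questions are: did a stimulus evoke a propagating
axonal response, with what probability per electrode, is the response
direct (axonal) or synaptically mediated, how fast does it travel, and do
response rates differ between stimulation conditions?

`axonmea` is for electrophysiologists and methods developers working with
such chip recordings. It provides the full analysis chain and — since raw
vendor recordings of this kind are not publicly deposited — a forward
model that generates synthetic sessions with complete ground truth, so
every stage of the chain is validated quantitatively.

## The model and statistics at the core

* **Spike detection.** Noise is estimated per electrode as
  σ = median(|x − median(x)|)/0.6745; a spike is reported at every
  negative-going crossing of −5σ, timed at the trace trough (parabolic
  sub-sample interpolation) with a 1 ms refractory dead time. Detections
  within ±2 ms of an optical artifact impulse — at pulse onset and again
  at pulse offset — are blanked.
* **Evoked responses.** Spike latencies relative to the laser pulse onset
  (TTL + 10 ms) are pooled over stimuli into a 0–50 ms PSTH (1 ms bins).
  The per-electrode response probability is
  P_e = (# stimuli with ≥ 1 spike in 5–50 ms)/N, summarised as M ± SD
  over the 24 microchannel electrodes. Responses below 15 ms are direct
  axonal responses (they persist under CNQX/CPP synaptic blockade);
  responses at ≥ 15 ms that disappear under blockade are synaptic.
* **Conduction velocity.** Spikes are chained across a channel's
  electrodes (strictly positive lags ≤ 5 ms); per chain, velocity is the
  least-squares slope of position (mm) on time (s), per-channel the
  median over chains, summarised as M ± SD across channels.
* **Condition comparison.** Paired Wilcoxon signed-rank test (the
  classical T test) over the 24 electrodes, exact over all 2^n sign
  assignments up to n = 25, normal approximation with continuity
  correction above.

## Worked example

Simulate the optical protocol — 30 pulses of 6 ms at 5 s intervals under
synaptic blockade, with each channel responding to a stimulus with
probability 0.33 — then run the chain:

```r
library(axonmea)

lay <- default_layout()
cfg <- sim_config(duration_s = 155, seed = 1,
                  evoked_prob_per_channel = 0.33, blockers_applied = TRUE)
ev  <- make_stimulus_train("optical", 30, 5, start_s = 2,
                           pulse_duration_ms = 6, power_W = 0.33)
sim    <- simulate_session(lay, cfg, ev)
spikes <- blank_artifacts(detect_session(sim$session), ev)

sim$session
#> recording_session: 60 electrodes, 155.0 s at 20000 Hz, 30 stimuli, blockers
nrow(spikes); attr(spikes, "n_removed")
#> [1] 7987
#> [1] 5112
response_probability(spikes, ev, lay)
#> response probability over microchannel electrodes: 0.425 +/- 0.063 (M+/-SD, 30 stimuli), 8 responsive channel(s)
mean(sim$truth$outcomes$responded)   # realized Bernoulli rate this seed
#> [1] 0.4041667
velocity_from_trains(spikes, lay)
#> conduction velocity: 354 +/- 5 mm/s (M+/-SD, 8 channel(s))
```

Reading the numbers: 5112 detections fell inside the ±2 ms artifact
windows around the 60 optical impulses (2 per pulse, on all 60
electrodes) and were blanked. The recovered mean probability 0.425 tracks
the rate the generator actually drew this seed (0.404, a high draw
against the configured 0.33) plus a small contribution from spontaneous
spikes that happen to fall in the 5–50 ms windows — exactly what the
statistic measures on real recordings. The velocity estimate 354 ± 5 mm/s
recovers the configured 360 mm/s from spontaneous volleys propagating
through the channels (0.1 ms latency jitter attenuates the slope
slightly).

## The analysis workflow

The numbered scripts under `analysis/` run the complete study-style
analysis over simulated conditions and write their tables under
`results/` (HDF5 sessions are large and regenerable; they go to
`scratch/`):

```sh
Rscript analysis/01_simulate_sessions.R   # power conditions, blockade pair, TTX, spontaneous
Rscript analysis/02_spike_detection.R     # detection + blanking, scored against truth
Rscript analysis/03_evoked_responses.R    # PSTHs, probabilities, direct/synaptic split
Rscript analysis/04_conduction_velocity.R
Rscript analysis/05_power_comparison.R    # paired Wilcoxon across powers
```

`run_pipeline()` exposes the same chain as one call driven by a JSON/YAML
configuration, for sessions simulated on the fly or loaded from HDF5
containers. The methods vignette
(`vignettes/evoked-axonal-analysis.Rmd`) documents the forward model, all
tunable parameters, and the numerical choices.

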