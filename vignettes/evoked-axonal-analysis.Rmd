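---
title: "Analysing IR-evoked axonal activity on microfluidic MEA chips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing IR-evoked axonal activity on microfluidic MEA chips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmea)
```

## The experimental system

Dissociated hippocampal neurons cultured in the chambers of a PDMS
microfluidic chip send their axons into narrow microchannels that exclude
cell bodies and dendrites. The chip sits on a planar 60-electrode array
(200 µm pitch), so the electrodes that fall under a microchannel record
isolated multi-unit axonal signals at known positions along the channel.
Stimulation — electrical trains of biphasic impulses, or short infrared
laser pulses gated by a shutter that emits a TTL marker roughly 10 ms
before each pulse — evokes action potentials that propagate along those
axons and are read out extracellularly at 20 kHz.

`axonmea` implements the complete analysis chain for such recordings, plus
a forward model that generates synthetic sessions with full ground truth so
that every stage can be validated quantitatively. The workflow scripts
under `analysis/` run the chain end to end: simulate, detect, analyse
evoked responses, estimate conduction velocity, compare conditions.

## Chip geometry

`default_layout()` encodes the canonical configuration: 8 microchannels of
800 µm connecting two chambers, 24 in-channel electrodes, 60 electrodes in
total. The public record states those three counts but not the per-channel
placement; 24 electrodes over 8 channels forces 3 per channel, and with the
array's uniform 200 µm pitch we fix them at 200, 400 and 600 µm from the
channel entrance, leaving the 0 and 800 µm ends at the channel mouths. This
placement is a geometric inference, not a measured alignment, and is the
one free choice in the layout module. Chamber electrodes carry no
coordinates because no analysis in scope uses chamber geometry.

## The forward model

`simulate_session()` generates voltage traces as a sum of four components:

* **Spontaneous bursts.** Burst onsets are separated by uniform 2–10 s
  intervals (the inter-burst range seen in mature cultures); each burst
  contains 3–8 spikes 30–100 ms apart. Burst spikes appear on the chamber
  electrodes and, with configurable probability (default 1), propagate as a
  volley through each microchannel at the configured conduction velocity.
* **Direct evoked responses.** Independently per stimulus and channel, a
  Bernoulli draw with probability `evoked_prob_per_channel` decides whether
  a direct axonal volley is emitted. Its latency at the channel entrance is
  `direct_latency_base_ms` (default 12 ms) after the laser pulse onset;
  each in-channel electrode then sees the spike delayed by
  position/velocity. The mapping from radiation power to response
  probability is an empirical finding, not a model assumption, so callers
  set the probability per condition.
* **Synaptic responses.** With probability `synaptic_prob`, an additional
  volley at a latency drawn uniformly from 15–40 ms — at or above the
  15 ms boundary that separates direct from synaptically mediated activity.
  `blockers_applied = TRUE` (CNQX/CPP-style blockade) suppresses exactly
  this component; `ttx_applied = TRUE` suppresses all spikes while leaving
  the stimulation artifacts in place.
* **Artifacts and noise.** Optical pulses inject a critically damped
  transient (default 400 µV peak, ten times the spike amplitude; time
  constant 0.3 ms, decayed within ~2 ms) on every electrode at pulse onset
  and again at pulse offset, matching the two artifact delays observed with
  thulium-laser stimulation. White Gaussian noise (default 5 µV SD) is
  added throughout.

The spike waveform is a negative-leading biphasic template of 1 ms total
width scaled to 40 µV trough depth — the standard extracellular shape, and
sufficient for a threshold detector; nothing downstream depends on its
details. Waveforms are evaluated continuously, so sub-sample spike timing
is preserved in the traces.

Why `direct_latency_base_ms = 12`? The quantitative latency of
optically evoked direct responses is not publicly recorded beyond the
facts that direct responses fall below 15 ms and induced spikes are
counted from 5 ms. The value 12 places all in-channel direct latencies
(12.6–13.7 ms at 360 mm/s) inside the direct window while keeping them
clear of the blanked artifact intervals at pulse onset and offset for both
6 and 10 ms pulses. It is a free parameter of the generator, not a
measured quantity.

**Determinism and pairing.** All randomness derives from one integer seed.
Bursts, evoked outcomes, synaptic draws and per-electrode noise use
separate sub-streams derived deterministically from it, which has a useful
consequence: flipping `blockers_applied` changes *only* the synaptic
spikes. A control/blockade pair simulated with the same seed therefore
emulates the real experiment — the same culture measured twice — and the
classifier's recovered synaptic count can be checked against truth exactly.

## Spike detection

The acquisition system's own detector is not publicly specified, so the
package adopts the field-standard minimal design, which has the virtue of
being checkable against an exhaustive per-sample oracle:

* noise sigma estimated robustly as `median(|x − median(x)|)/0.6745`
  (floored at 0.1 µV so noise-free synthetic traces keep a finite
  threshold); on traces longer than 200 000 samples the two medians are
  taken on a deterministic 200 000-sample stride, where the estimator's
  standard error is already far below a percent;
* a spike at every negative-going crossing of −5σ (negative polarity by
  default; extracellular spikes lead with their trough);
* spike time at the trace minimum within 1 ms after the crossing, ties
  broken toward the earlier sample, refined to sub-sample precision by
  parabolic interpolation around the trough;
* a 1 ms dead time, enforced at sample resolution so the refractory
  decision never depends on the sub-sample refinement.

Artifact handling is post-detection blanking rather than trace
interpolation: detections within ±2 ms of each optical impulse (pulse
onset, and offset one pulse duration later) are removed. This matches the
practice of reading responses outside the artifact delays, and keeps the
detector contract simple. Blanking is parameterised per event — a 10 ms
pulse blanks around 10 ms after onset, not a hard-coded 16–20 ms.

## Stimulus-locked analysis

Latencies are referenced to the laser pulse onset (TTL + 10 ms) for
optical stimuli and to the stimulus time itself for electrical ones; both
conventions are available explicitly via `window_config(reference =)`.
The PSTH covers 0–50 ms in half-open, left-closed 1 ms bins (bin width is
not publicly specified; 1 ms resolves the sub-millisecond inter-electrode
delays). Induced spikes are counted from 5 to 50 ms.

The per-electrode response probability is the fraction of stimuli followed
by at least one induced-window spike on that electrode, scored
independently for each of the 24 microchannel electrodes; the summary is
their mean ± SD (sample SD, n−1 denominator, reported in the M±SD
convention). All 24 electrodes enter the mean whether or not their channel
responded — the probability formula is defined per electrode, and
restricting to responsive channels would bias the estimate upward. A
channel counts as responsive when any of its electrodes has non-zero
probability; no threshold above zero is publicly recorded.

`classify_components()` compares a control PSTH against a blockade PSTH:
the direct count is the induced activity below 15 ms under blockade, the
synaptic count is the ≥15 ms activity lost upon blockade (floored at
zero), and the direct response "persists" when its blocked count is at
least half the control count. One known tension in the source record —
prose stating the axonal response appears *after* 15 ms while the figure
convention places direct responses *below* 15 ms — is resolved in favour
of the figure convention, which is the one consistent with blockade
persistence; the cutoff is a parameter should users prefer otherwise.

## Conduction velocity

Spontaneous volleys crossing a channel are reconstructed by greedy forward
chaining: sweeping the electrodes in position order, a spike joins an
event when it follows the previous electrode's spike by a strictly
positive lag of at most 5 ms (pitch / 5 ms = 40 mm/s, well below any
plausible axonal velocity); each spike joins at most one event, and only
events spanning the whole channel are kept. The strictly positive lag
enforces propagation toward the channel exit; reversed volleys simply fail
to chain.

Per event, velocity is the least-squares slope of position (mm) on time
(s) — regressing this way round makes the slope the velocity directly, and
with three nearly collinear points the distinction from the inverse
regression is negligible. The per-channel velocity is the *median* over
events (robust to chance coincidences); the summary mean ± SD is taken
over channels with at least `min_events` events, mirroring a summary
"averaged over channels". With 0.1 ms timing jitter the
errors-in-variables attenuation of the slope stays under ~2% at
500 mm/s in our validation runs — within the 10% recovery tolerance the
tests enforce — so the simpler, prescribed regression direction is kept.

## Condition comparison

The "Wilcoxon T test" is implemented as the paired signed-rank test — T is
the classical name of its statistic — paired across the 24 microchannel
electrodes, which are the same physical electrodes under each condition.
Zero differences are dropped (Wilcoxon's classical procedure; Pratt's
variant is a flag), ties receive mid-ranks, and for up to 25 effective
pairs the two-sided p-value is exact over all 2^n sign assignments
(computed by dynamic programming over the rank multiset, which is the same
sum organised differently). Beyond that, a normal approximation with
continuity correction uses the general moments `mu = Σr/2`,
`var = Σr²/4`, which are valid under ties without a separate correction
term. No multiple-testing correction is applied across the two pairwise
power comparisons — none is applied in the source analysis, and adding one
silently would change the inference; `p.adjust` on the output is the
user's call.

## What passing tests do and do not show

The generator reproduces the *statistical structure* of the recordings:
burst timing, volley propagation at a configurable velocity, response
probabilities in the observed 10–59% regime, artifact geometry,
pharmacological suppression. It does not model biophysics (membrane
dynamics, IR heating, electrode filtering), realistic field potentials,
per-electrode response dropout within a channel, electrode-specific noise
spectra, or any power→probability dose–response law. Tests passing on
synthetic sessions therefore validate the *analysis chain* — detection,
blanking, windowing, counting, matching, regression, testing — under known
truth; they cannot certify performance on vendor recordings, whose noise
and waveform diversity the model deliberately omits.

Problem sizes in the test and acceptance runs are the package's own
choices: stimulus trains of 30 pulses at the protocol intervals (3 s
electrical, 5 s optical) for probability recovery, a 300-pulse train at a
shortened 0.5 s interval when pinning the estimate to four binomial
standard errors, ~50 s of spontaneous activity (≥20 volleys per channel)
for velocity recovery, and 1000 replicates for the type-I calibration of
the exact test.

## Known limitations

* The 3-electrodes-per-channel placement is inferred from the electrode
  counts, not from a documented alignment.
* Detection is multi-unit: no spike sorting, no unit assignment — matching
  the analyses in scope, which never separate units.
* The HDF5 session container is this package's own documented layout;
  vendor `.mcd`/`.msrd` files and NWB export are out of scope.
* Noise false positives at a 5σ threshold occur at a rate of roughly
  3 × 10⁻⁷ per sample; analyses that need an exactly empty background
  (e.g. artifact-blanking validation) use noise-free sessions, and
  probability estimates absorb the residual rate without bias worth
  noting.

## A minimal session

```{r example, eval = FALSE}
lay <- default_layout()
cfg <- sim_config(duration_s = 155, seed = 1,
                  evoked_prob_per_channel = 0.33, blockers_applied = TRUE)
ev <- make_stimulus_train("optical", 30, 5, start_s = 2,
                          pulse_duration_ms = 6, power_W = 0.33)
sim <- simulate_session(lay, cfg, ev)
spikes <- blank_artifacts(detect_session(sim$session), ev)
response_probability(spikes, ev, lay)
velocity_from_trains(spikes, lay)
```
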