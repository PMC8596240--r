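#' Analysis window configuration for stimulus-locked statistics
#'
#' The evoked response is read in a 50 ms window after each stimulus.
#' Induced spikes are counted from 5 to 50 ms; responses below the 15 ms
#' cutoff are direct axonal responses (they persist under synaptic
#' blockade), responses above it are synaptically mediated. For optical
#' stimuli latencies are referenced to the laser pulse onset (TTL marker
#' plus the TTL-to-pulse delay); for electrical stimuli to the stimulus
#' delivery time itself.
#'
#' @param psth_window_ms two-element window `[start, end)` of the histogram
#'   (ms relative to the reference).
#' @param induced_window_ms window in which induced spikes are counted (ms).
#' @param direct_cutoff_ms latency boundary between direct and synaptic
#'   responses (ms).
#' @param bin_ms histogram bin width (ms); must divide the window length.
#'   Bins are half-open, left-closed.
#' @param reference `"auto"` (pulse onset for optical stimuli, TTL for
#'   electrical), `"ttl"` or `"pulse_onset"`.
#' @return A list of class `window_config`.
#' @export
window_config <- function(psth_window_ms = c(0, 50),
                          induced_window_ms = c(5, 50),
                          direct_cutoff_ms = 15,
                          bin_ms = 1,
                          reference = c("auto", "ttl", "pulse_onset")) {
  reference <- match.arg(reference)
  if (induced_window_ms[1] < psth_window_ms[1] ||
      induced_window_ms[2] > psth_window_ms[2] ||
      induced_window_ms[1] >= induced_window_ms[2])
    stop("induced window must be an increasing range inside the PSTH window")
  width <- diff(psth_window_ms)
  if (abs(width / bin_ms - round(width / bin_ms)) > 1e-9)
    stop("bin_ms must divide the PSTH window length")
  structure(list(psth_window_ms = psth_window_ms,
                 induced_window_ms = induced_window_ms,
                 direct_cutoff_ms = direct_cutoff_ms,
                 bin_ms = bin_ms, reference = reference),
            class = "window_config")
}

# internal: reference time (s) of each stimulus for latency computation
event_reference_times <- function(events, windows) {
  ref <- windows$reference
  use_onset <- switch(ref,
                      auto = events$kind == "optical",
                      ttl = rep(FALSE, nrow(events)),
                      pulse_onset = rep(TRUE, nrow(events)))
  events$ttl_time_s +
    ifelse(use_onset, events$ttl_to_pulse_delay_ms / 1000, 0)
}

#' Peristimulus time histogram over the microchannel electrodes
#'
#' Pools spike latencies relative to every stimulus into a per-electrode
#' histogram over the configured window (default 0-50 ms, 1 ms bins,
#' half-open left-closed). Spike trains should already have artifact windows
#' blanked; any blanked intervals recorded by [blank_artifacts()] are carried
#' into the result.
#'
#' @param trains spike data frame (`electrode_id`, `time_s`).
#' @param events stimulus event data frame (>= 1 row).
#' @param layout a `chip_layout`; by default only its microchannel
#'   electrodes enter the histogram.
#' @param windows a `window_config`.
#' @param electrodes `"microchannel"` (default) or `"all"`.
#' @return An object of class `psth_result`: `bin_edges_ms`, `counts`
#'   (electrodes x bins integer matrix, row names electrode ids),
#'   `electrode_ids`, `n_stimuli`, `excluded_intervals_s`.
#' @export
compute_psth <- function(trains, events, layout,
                         windows = window_config(),
                         electrodes = c("microchannel", "all")) {
  electrodes <- match.arg(electrodes)
  if (is.null(events) || nrow(events) == 0) stop("no stimuli")
  validate_layout(layout)
  ids <- if (electrodes == "microchannel") microchannel_electrodes(layout)
         else layout$electrodes$id
  edges <- seq(windows$psth_window_ms[1], windows$psth_window_ms[2],
               by = windows$bin_ms)
  counts <- matrix(0L, nrow = length(ids), ncol = length(edges) - 1L,
                   dimnames = list(as.character(ids), NULL))
  refs <- event_reference_times(events, windows)
  tr <- trains[trains$electrode_id %in% ids, , drop = FALSE]
  if (nrow(tr)) {
    row_of <- match(tr$electrode_id, ids)
    for (i in seq_along(refs)) {
      lat <- (tr$time_s - refs[i]) * 1000
      inw <- lat >= windows$psth_window_ms[1] & lat < windows$psth_window_ms[2]
      if (!any(inw)) next
      b <- findInterval(lat[inw], edges, rightmost.closed = FALSE)
      for (k in seq_along(b))
        counts[row_of[inw][k], b[k]] <- counts[row_of[inw][k], b[k]] + 1L
    }
  }
  structure(list(bin_edges_ms = edges, counts = counts, electrode_ids = ids,
                 n_stimuli = nrow(events),
                 excluded_intervals_s = attr(trains, "blanked_intervals_s")),
            class = "psth_result")
}

#' Per-electrode evoked-response probability
#'
#' For each electrode, the fraction of stimuli after which at least one
#' spike was detected in the induced window (default 5-50 ms after the
#' reference). The summary mean and standard deviation are taken over the
#' microchannel electrodes (all 24 in the canonical layout), and a
#' microchannel is counted as responsive when any of its electrodes has a
#' non-zero probability.
#'
#' @inheritParams compute_psth
#' @return An object of class `response_probability_table`: `table` (data
#'   frame `electrode_id`, `prob` for every layout electrode), `mean`, `sd`
#'   (sample SD over microchannel electrodes), `n_stimuli`,
#'   `responsive_channels`.
#' @export
response_probability <- function(trains, events, layout,
                                 windows = window_config()) {
  if (is.null(events) || nrow(events) == 0) stop("no stimuli")
  validate_layout(layout)
  el <- layout$electrodes
  refs <- event_reference_times(events, windows)
  lo <- windows$induced_window_ms[1] / 1000
  hi <- windows$induced_window_ms[2] / 1000
  prob <- numeric(nrow(el))
  for (k in seq_len(nrow(el))) {
    ts <- trains$time_s[trains$electrode_id == el$id[k]]
    if (!length(ts)) next
    hit <- vapply(refs, function(r)
      any(ts - r >= lo & ts - r < hi), logical(1))
    prob[k] <- mean(hit)
  }
  tab <- data.frame(electrode_id = el$id, prob = prob)
  mc <- el$compartment == "microchannel"
  resp_ch <- length(unique(el$channel_index[mc & prob > 0]))
  structure(list(table = tab,
                 microchannel_ids = el$id[mc],
                 mean = mean(prob[mc]),
                 sd = sd(prob[mc]),
                 n_stimuli = nrow(events),
                 responsive_channels = resp_ch),
            class = "response_probability_table")
}

#' @export
print.response_probability_table <- function(x, ...) {
  cat(sprintf(
    "response probability over microchannel electrodes: %.3f +/- %.3f (M+/-SD, %d stimuli), %d responsive channel(s)\n",
    x$mean, x$sd, x$n_stimuli, x$responsive_channels))
  invisible(x)
}

#' Classify evoked activity into direct and synaptic components
#'
#' Compares the stimulus-locked histograms recorded before (control) and
#' after applying synaptic blockers. The direct axonal response occupies
#' induced latencies below the cutoff (15 ms) and persists under blockade;
#' the synaptic component occupies latencies at or above the cutoff and is
#' abolished by the blockers.
#'
#' @param psth_control `psth_result` for the control condition.
#' @param psth_blocked `psth_result` with synaptic blockers applied.
#' @param windows the shared `window_config`.
#' @return List with `direct_count` (induced spikes below the cutoff under
#'   blockade), `synaptic_count` (induced spikes at/above the cutoff in
#'   control minus the same count under blockade, floored at zero) and
#'   `direct_persists` (`TRUE` when the blocked direct count is at least
#'   half the control direct count).
#' @export
classify_components <- function(psth_control, psth_blocked,
                                windows = window_config()) {
  if (!identical(psth_control$bin_edges_ms, psth_blocked$bin_edges_ms))
    stop("PSTHs do not share binning")
  starts <- psth_control$bin_edges_ms[-length(psth_control$bin_edges_ms)]
  ind <- windows$induced_window_ms
  cut <- windows$direct_cutoff_ms
  early <- starts >= ind[1] & starts < cut
  late <- starts >= cut & starts < ind[2]
  ctrl_direct <- sum(psth_control$counts[, early, drop = FALSE])
  blk_direct <- sum(psth_blocked$counts[, early, drop = FALSE])
  ctrl_late <- sum(psth_control$counts[, late, drop = FALSE])
  blk_late <- sum(psth_blocked$counts[, late, drop = FALSE])
  list(direct_count = blk_direct,
       synaptic_count = max(0L, ctrl_late - blk_late),
       direct_persists = blk_direct >= 0.5 * ctrl_direct)
}
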