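#' Spike detection configuration
#'
#' Parameters of the noise-scaled threshold-crossing detector. The detector
#' is the field-standard minimal design for multi-unit MEA activity: a
#' robust (median absolute deviation) noise estimate, a threshold at
#' `threshold_k` times that estimate, trough alignment of spike times and a
#' refractory dead time.
#'
#' @param threshold_k threshold in multiples of the noise sigma.
#' @param polarity `"negative"` (default; extracellular spikes lead with a
#'   negative trough) or `"both"`.
#' @param dead_time_ms refractory period: further crossings within this time
#'   of an accepted spike are suppressed (ms).
#' @param sigma_floor_uV lower bound on the noise sigma (uV) so that
#'   noise-free synthetic traces do not produce a zero threshold.
#' @param artifact_blank_ms half-width of the interval blanked around each
#'   stimulation-artifact impulse (ms).
#' @param align_window_ms spike time is the trace minimum within this window
#'   after the threshold crossing (ms).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(threshold_k = 5,
                             polarity = c("negative", "both"),
                             dead_time_ms = 1,
                             sigma_floor_uV = 0.1,
                             artifact_blank_ms = 2,
                             align_window_ms = 1) {
  polarity <- match.arg(polarity)
  if (threshold_k <= 0) stop("threshold_k must be positive")
  if (dead_time_ms < 0) stop("dead_time_ms must be non-negative")
  structure(list(threshold_k = threshold_k, polarity = polarity,
                 dead_time_ms = dead_time_ms, sigma_floor_uV = sigma_floor_uV,
                 artifact_blank_ms = artifact_blank_ms,
                 align_window_ms = align_window_ms),
            class = "detection_config")
}

#' Robust noise estimate of a voltage trace
#'
#' Median absolute deviation scaled to the standard deviation of a Gaussian:
#' `median(|x - median(x)|) / 0.6745`. Insensitive to the spikes riding on
#' the noise, which occupy a tiny fraction of samples.
#'
#' @param trace numeric voltage trace (uV).
#' @return Estimated noise sigma (uV).
#' @export
estimate_noise_sigma <- function(trace) {
  if (!length(trace)) stop("empty trace")
  stats::median(abs(trace - stats::median(trace))) / 0.6745
}

# internal: one polarity pass. Returns, per candidate, the trough sample
# index (used for the refractory decision, at sample resolution) and the
# sub-sample refined time for the trace handed in.
detect_negative <- function(x, fs, k_sigma_thr, win, n) {
  below <- x < -k_sigma_thr
  if (!any(below)) return(list(sample = integer(), time = numeric()))
  cross <- which(below & !c(FALSE, below[-n]))
  j_out <- integer(length(cross))
  t_out <- numeric(length(cross))
  for (m in seq_along(cross)) {
    i0 <- cross[m]
    i1 <- min(i0 + win, n)
    seg <- x[i0:i1]
    j <- i0 + which.min(seg) - 1L      # earliest minimum on ties
    delta <- 0
    if (j > 1L && j < n) {
      y0 <- x[j - 1L]; y1 <- x[j]; y2 <- x[j + 1L]
      den <- y0 - 2 * y1 + y2          # parabolic trough interpolation
      if (is.finite(den) && den > 0) {
        delta <- 0.5 * (y0 - y2) / den
        delta <- max(-0.5, min(0.5, delta))
      }
    }
    j_out[m] <- j
    t_out[m] <- (j - 1L + delta) / fs
  }
  list(sample = j_out, time = t_out)
}

#' Detect spikes in a single voltage trace
#'
#' Median-centres the trace, estimates the noise sigma robustly (floored at
#' `sigma_floor_uV`), and reports a spike at every negative-going crossing of
#' `-threshold_k * sigma`. The spike time is the trace minimum within
#' `align_window_ms` after the crossing, refined to sub-sample precision by
#' parabolic interpolation around the trough; crossings within
#' `dead_time_ms` of an accepted spike are suppressed.
#'
#' @param trace numeric voltage trace (uV).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param config a `detection_config`.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
detect_spikes <- function(trace, sampling_rate_hz,
                          config = detection_config()) {
  if (sampling_rate_hz <= 0) stop("sampling rate must be positive")
  if (!length(trace)) stop("empty trace")
  fs <- sampling_rate_hz
  # noise statistics on a deterministic stride capped at 200k samples: the
  # MAD's standard error is already negligible there, and sorting the full
  # trace would dominate the run time on long recordings
  sub <- if (length(trace) > 200000L)
    trace[seq(1L, length(trace), length.out = 200000L)] else trace
  ctr <- stats::median(sub)
  x <- trace - ctr
  sigma <- max(estimate_noise_sigma(sub), config$sigma_floor_uV)
  thr <- config$threshold_k * sigma
  n <- length(x)
  win <- max(1L, round(config$align_window_ms / 1000 * fs))

  cand <- detect_negative(x, fs, thr, win, n)
  if (config$polarity == "both") {
    pos <- detect_negative(-x, fs, thr, win, n)
    cand <- list(sample = c(cand$sample, pos$sample),
                 time = c(cand$time, pos$time))
  }
  if (!length(cand$sample)) return(numeric())
  ord <- order(cand$sample)
  smp <- cand$sample[ord]
  tim <- cand$time[ord]
  dup <- duplicated(smp)
  smp <- smp[!dup]
  tim <- tim[!dup]

  # refractory decision at sample resolution, so it does not depend on the
  # sub-sample refinement
  dead_samp <- config$dead_time_ms / 1000 * fs
  keep <- logical(length(smp))
  last <- -Inf
  for (m in seq_along(smp)) {
    if (smp[m] - last > dead_samp) {
      keep[m] <- TRUE
      last <- smp[m]
    }
  }
  sort(tim[keep])
}

#' Detect spikes on every electrode of a session
#'
#' @param session a `recording_session`.
#' @param config a `detection_config`.
#' @return Data frame with columns `electrode_id`, `time_s`, sorted per
#'   electrode.
#' @export
detect_session <- function(session, config = detection_config()) {
  if (!inherits(session, "recording_session")) stop("not a recording_session")
  out <- vector("list", length(session$electrode_ids))
  for (j in seq_along(session$electrode_ids)) {
    ts <- detect_spikes(session$traces[, j], session$sampling_rate_hz, config)
    out[[j]] <- if (length(ts))
      data.frame(electrode_id = session$electrode_ids[j], time_s = ts)
    else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(electrode_id = integer(), time_s = numeric())
  rownames(res) <- NULL
  res
}

#' Remove detections inside stimulation-artifact windows
#'
#' Optical stimulation produces two large non-biological transients per
#' pulse: one at the laser pulse onset (one TTL-to-pulse delay after the TTL
#' marker) and one at the pulse offset (one pulse duration later). Detected
#' spikes within `blank_ms` of either impulse are removed; real responses
#' are read outside these delays.
#'
#' @param trains spike data frame (`electrode_id`, `time_s`).
#' @param events stimulus event data frame; only optical events generate
#'   artifact windows.
#' @param blank_ms half-width of the blanked interval around each impulse
#'   (ms).
#' @return The filtered spike data frame, with attributes `n_removed` (count
#'   of removed detections) and `blanked_intervals_s` (data frame of
#'   `start_s`, `end_s`).
#' @export
blank_artifacts <- function(trains, events, blank_ms = 2) {
  stopifnot(is.data.frame(trains))
  centers <- numeric()
  if (!is.null(events) && nrow(events)) {
    opt <- events[events$kind == "optical", , drop = FALSE]
    if (nrow(opt)) {
      onset <- opt$ttl_time_s + opt$ttl_to_pulse_delay_ms / 1000
      centers <- sort(c(onset, onset + opt$pulse_duration_ms / 1000))
    }
  }
  half <- blank_ms / 1000
  intervals <- data.frame(start_s = centers - half, end_s = centers + half)
  keep <- rep(TRUE, nrow(trains))
  if (nrow(trains) && length(centers)) {
    for (ctr in centers)
      keep <- keep & abs(trains$time_s - ctr) > half
  }
  out <- trains[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "blanked_intervals_s") <- intervals
  out
}
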