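#' Match spikes propagating along a microchannel
#'
#' Greedy forward chaining of the spike sequence across a channel's
#' electrodes in position order: a spike on the next electrode joins an
#' event when it occurs within `(0, max_lag_ms]` after the event's spike on
#' the previous electrode; each spike joins at most one event. Only events
#' spanning at least `min_span` electrodes (default: all of them) are
#' returned, which suppresses chance coincidences; a strictly positive lag
#' enforces propagation toward the channel exit.
#'
#' @param trains spike data frame (`electrode_id`, `time_s`).
#' @param layout a `chip_layout`.
#' @param channel_index 0-based channel index.
#' @param max_lag_ms maximum inter-electrode lag (ms); the default of 5
#'   admits velocities down to pitch / 5 ms = 40 mm/s.
#' @param min_span minimum number of consecutive electrodes an event must
#'   span (`NULL` = all electrodes of the channel).
#' @return List of `propagation_event` objects, each a list with
#'   `channel_index`, `electrode_ids`, `positions_um` and `times_s` (all
#'   ordered along the channel).
#' @export
match_propagating_spikes <- function(trains, layout, channel_index,
                                     max_lag_ms = 5, min_span = NULL) {
  if (max_lag_ms <= 0) stop("max_lag_ms must be positive")
  info <- channel_electrodes(layout, channel_index)
  if (nrow(info) < 2) stop("channel has fewer than 2 electrodes")
  if (is.null(min_span)) min_span <- nrow(info)
  min_span <- max(2L, as.integer(min_span))
  lag_s <- max_lag_ms / 1000

  sp <- lapply(info$id, function(id)
    sort(trains$time_s[trains$electrode_id == id]))
  used <- lapply(sp, function(v) rep(FALSE, length(v)))

  events <- list()
  n_el <- nrow(info)
  for (start in seq_len(n_el - min_span + 1L)) {
    for (m in seq_along(sp[[start]])) {
      if (used[[start]][m]) next
      chain_idx <- m
      chain_el <- start
      t_prev <- sp[[start]][m]
      k <- start + 1L
      while (k <= n_el) {
        cand <- which(!used[[k]] & sp[[k]] > t_prev &
                        sp[[k]] <= t_prev + lag_s)
        if (!length(cand)) break
        j <- cand[1L]                      # earliest admissible spike
        chain_idx <- c(chain_idx, j)
        chain_el <- c(chain_el, k)
        t_prev <- sp[[k]][j]
        k <- k + 1L
      }
      if (length(chain_el) >= min_span) {
        for (q in seq_along(chain_el))
          used[[chain_el[q]]][chain_idx[q]] <- TRUE
        events[[length(events) + 1L]] <- structure(
          list(channel_index = as.integer(channel_index),
               electrode_ids = info$id[chain_el],
               positions_um = info$position_um[chain_el],
               times_s = vapply(seq_along(chain_el), function(q)
                 sp[[chain_el[q]]][chain_idx[q]], numeric(1))),
          class = "propagation_event")
      }
    }
  }
  events
}

#' Estimate conduction velocity from propagation events
#'
#' Per event, the velocity is the slope of the least-squares regression of
#' electrode position (mm) on spike time (s), so the slope is the velocity
#' directly. Events with zero time spread are discarded with a warning, and
#' events whose slope is not positive (propagation against the channel
#' direction) are rejected. The per-channel velocity is the median over that
#' channel's events, for robustness to chance coincidences; the summary mean
#' and SD are taken across channels with at least `min_events` events.
#'
#' @param events list of `propagation_event` (possibly from several
#'   channels).
#' @param min_events minimum events for a channel to enter the summary.
#' @return An object of class `velocity_estimate`: `per_channel` (data frame
#'   `channel_index`, `velocity_mm_s`, `n_events`), `mean_mm_s`, `sd_mm_s`,
#'   `n_channels` (channels entering the summary).
#' @export
estimate_velocity <- function(events, min_events = 3) {
  if (!length(events)) stop("no propagation events")
  v_ev <- numeric(0)
  ch_ev <- integer(0)
  n_degenerate <- 0L
  for (ev in events) {
    tt <- ev$times_s
    if (diff(range(tt)) <= 0) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    x_mm <- ev$positions_um / 1000
    v <- unname(coef(lm(x_mm ~ tt))[2])
    if (!is.finite(v) || v <= 0) next
    v_ev <- c(v_ev, v)
    ch_ev <- c(ch_ev, ev$channel_index)
  }
  if (n_degenerate > 0)
    warning(n_degenerate, " event(s) with zero time spread discarded")
  if (!length(v_ev)) stop("no usable propagation events")
  chans <- sort(unique(ch_ev))
  per <- data.frame(
    channel_index = chans,
    velocity_mm_s = vapply(chans, function(c0) median(v_ev[ch_ev == c0]),
                           numeric(1)),
    n_events = vapply(chans, function(c0) sum(ch_ev == c0), integer(1))
  )
  qual <- per$n_events >= min_events
  if (!any(qual)) stop("no channel has at least ", min_events, " events")
  structure(list(per_channel = per,
                 mean_mm_s = mean(per$velocity_mm_s[qual]),
                 sd_mm_s = sd(per$velocity_mm_s[qual]),
                 n_channels = sum(qual)),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("conduction velocity: %.0f +/- %.0f mm/s (M+/-SD, %d channel(s))\n",
              x$mean_mm_s, if (is.na(x$sd_mm_s)) 0 else x$sd_mm_s,
              x$n_channels))
  invisible(x)
}

#' Conduction velocity straight from a session's spike trains
#'
#' Convenience wrapper: matches propagating spikes in every microchannel and
#' summarises the velocities.
#'
#' @param trains spike data frame.
#' @param layout a `chip_layout`.
#' @param max_lag_ms passed to [match_propagating_spikes()].
#' @param min_events passed to [estimate_velocity()].
#' @return A `velocity_estimate`.
#' @export
velocity_from_trains <- function(trains, layout, max_lag_ms = 5,
                                 min_events = 3) {
  events <- list()
  for (c_idx in seq_len(layout$n_channels) - 1L)
    events <- c(events,
                match_propagating_spikes(trains, layout, c_idx, max_lag_ms))
  estimate_velocity(events, min_events = min_events)
}
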