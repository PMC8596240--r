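# Independent oracles used to freeze expected values. These deliberately
# re-derive each quantity by the most literal method available (per-sample
# scans, full enumeration, closed-form slopes) and share no code with the
# package implementation beyond the definitions under test.

# Exhaustive per-sample threshold-scan spike detector (sample resolution).
oracle_detect <- function(trace, fs, k = 5, dead_ms = 1, floor_uV = 0.1,
                          align_ms = 1) {
  m <- median(trace)
  s <- max(median(abs(trace - m)) / 0.6745, floor_uV)
  thr <- -k * s
  x <- trace - m
  n <- length(x)
  win <- max(1, round(align_ms / 1000 * fs))
  cand <- integer()
  for (i in seq_len(n)) {
    if (x[i] < thr && (i == 1 || x[i - 1] >= thr)) {
      idx <- i:min(i + win, n)
      cand <- c(cand, idx[which.min(x[idx])])
    }
  }
  cand <- sort(unique(cand))
  out <- integer()
  last <- -Inf
  for (j in cand) {
    if (j - last > dead_ms / 1000 * fs) {
      out <- c(out, j)
      last <- j
    }
  }
  (out - 1) / fs
}

# Greedy one-to-one matching of two sorted time lists within a tolerance;
# returns the number of matched pairs.
oracle_match_count <- function(a, b, tol) {
  a <- sort(a); b <- sort(b)
  used <- rep(FALSE, length(b))
  hits <- 0L
  for (t0 in a) {
    cand <- which(!used & abs(b - t0) <= tol)
    if (length(cand)) {
      used[cand[which.min(abs(b[cand] - t0))]] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

# Full 2^n enumeration of the Wilcoxon signed-rank null (two-sided p).
oracle_wilcox_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    sel <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    ws[mask + 1] <- sum(r[sel])
  }
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# Brute-force pooled in-window spike count (PSTH total).
oracle_psth_total <- function(trains, ref_times_s, window_ms) {
  total <- 0L
  for (r in ref_times_s) {
    lat <- (trains$time_s - r) * 1000
    total <- total + sum(lat >= window_ms[1] & lat < window_ms[2])
  }
  total
}

# Closed-form least-squares slope of position (mm) on time (s).
oracle_slope_mm_s <- function(positions_um, times_s) {
  x <- positions_um / 1000
  sum((times_s - mean(times_s)) * (x - mean(x))) /
    sum((times_s - mean(times_s))^2)
}

# Construct a propagation event by hand (for feeding estimate_velocity).
manual_event <- function(channel_index, positions_um, times_s,
                         electrode_ids = seq_along(positions_um)) {
  structure(list(channel_index = as.integer(channel_index),
                 electrode_ids = electrode_ids,
                 positions_um = positions_um,
                 times_s = times_s),
            class = "propagation_event")
}
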