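#' Write / read a recording session as an HDF5 container
#'
#' The vendor's proprietary acquisition format is out of scope; sessions are
#' stored in a documented open HDF5 layout so every pipeline stage is
#' file-separable:
#' \itemize{
#'   \item `/traces/e<id>` — one float32 dataset per electrode (uV), with an
#'     `electrode_id` attribute;
#'   \item `/events/<column>` — stimulus event table columns;
#'   \item `/meta` — `sampling_rate_hz`, `duration_s`, `blockers_applied`,
#'     `ttx_applied`, `label` and the chip layout as a JSON string.
#' }
#' Voltages are stored as 32-bit floats, times as 64-bit floats. A session
#' that has been through one write/read cycle round-trips exactly thereafter.
#'
#' @param session a `recording_session`.
#' @param layout the matching `chip_layout`.
#' @param path HDF5 file path (overwritten if present).
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns `list(session, layout)`.
#' @export
write_session <- function(session, layout, path) {
  if (!inherits(session, "recording_session")) stop("not a recording_session")
  validate_layout(layout)
  if (!setequal(session$electrode_ids, layout$electrodes$id))
    stop("session electrode ids do not match the layout")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "traces")
  rhdf5::h5createGroup(path, "events")
  rhdf5::h5createGroup(path, "meta")

  n <- nrow(session$traces)
  fid <- rhdf5::H5Fopen(path)
  for (j in seq_along(session$electrode_ids)) {
    id <- session$electrode_ids[j]
    name <- sprintf("traces/e%d", id)
    rhdf5::h5createDataset(fid, name, dims = n, storage.mode = "double",
                           H5type = "H5T_IEEE_F32LE",
                           chunk = min(n, 262144L), level = 1)
    rhdf5::h5write(session$traces[, j], fid, name)
    did <- rhdf5::H5Dopen(fid, name)
    rhdf5::h5writeAttribute(as.integer(id), did, "electrode_id")
    rhdf5::H5Dclose(did)
  }
  ev <- session$events
  rhdf5::h5write(nrow(ev), fid, "events/n")
  for (cn in names(ev)) rhdf5::h5write(ev[[cn]], fid, paste0("events/", cn))
  rhdf5::h5write(session$sampling_rate_hz, fid, "meta/sampling_rate_hz")
  rhdf5::h5write(session$duration_s, fid, "meta/duration_s")
  rhdf5::h5write(as.integer(isTRUE(session$condition$blockers_applied)),
                 fid, "meta/blockers_applied")
  rhdf5::h5write(as.integer(isTRUE(session$condition$ttx_applied)),
                 fid, "meta/ttx_applied")
  rhdf5::h5write(as.character(session$condition$label %||% ""), fid, "meta/label")
  lay_json <- jsonlite::toJSON(list(
    n_channels = layout$n_channels,
    channel_length_um = layout$channel_length_um,
    pitch_um = layout$pitch_um,
    electrode_diameter_um = layout$electrode_diameter_um,
    electrodes = layout$electrodes
  ), auto_unbox = TRUE, digits = NA, na = "null")
  rhdf5::h5write(as.character(lay_json), fid, "meta/layout_json")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  entries <- file.path(ls$group, ls$name)
  need <- c("/ traces", "/ events", "/ meta")
  for (grp in c("traces", "events", "meta"))
    if (!any(ls$group == "/" & ls$name == grp))
      stop(grp, " not found in session container ", path)
  for (ds in c("sampling_rate_hz", "duration_s", "layout_json"))
    if (!any(ls$group == "/meta" & ls$name == ds))
      stop("meta/", ds, " not found in session container ", path)

  fs <- as.numeric(rhdf5::h5read(path, "meta/sampling_rate_hz"))
  duration_s <- as.numeric(rhdf5::h5read(path, "meta/duration_s"))
  lay_doc <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "meta/layout_json")))
  el <- lay_doc$electrodes
  el$channel_index <- suppressWarnings(as.integer(el$channel_index))
  el$position_um <- as.numeric(el$position_um)
  layout <- structure(
    list(electrodes = el,
         n_channels = as.integer(lay_doc$n_channels),
         channel_length_um = as.numeric(lay_doc$channel_length_um),
         pitch_um = as.numeric(lay_doc$pitch_um),
         electrode_diameter_um = as.numeric(lay_doc$electrode_diameter_um)),
    class = "chip_layout")
  validate_layout(layout)

  trace_names <- ls$name[ls$group == "/traces"]
  if (!length(trace_names)) stop("traces not found in session container ", path)
  ids <- sort(as.integer(sub("^e", "", trace_names)))
  traces <- NULL
  for (k in seq_along(ids)) {
    v <- as.numeric(rhdf5::h5read(path, sprintf("traces/e%d", ids[k])))
    if (is.null(traces))
      traces <- matrix(0, nrow = length(v), ncol = length(ids),
                       dimnames = list(NULL, as.character(ids)))
    traces[, k] <- v
  }
  if (nrow(traces) != round(duration_s * fs))
    stop("sampling-rate mismatch: traces have ", nrow(traces),
         " samples but meta implies ", round(duration_s * fs))

  ev_names <- ls$name[ls$group == "/events"]
  if (!"n" %in% ev_names) stop("events not found in session container ", path)
  n_ev <- as.integer(rhdf5::h5read(path, "events/n"))
  cols <- setdiff(ev_names, "n")
  ev <- make_stimulus_train("optical", 1, 1)[0, ]
  if (n_ev > 0) {
    ev <- as.data.frame(lapply(setNames(cols, cols), function(cn)
      as.vector(rhdf5::h5read(path, paste0("events/", cn)))),
      stringsAsFactors = FALSE)
    ev <- ev[order(ev$ttl_time_s), , drop = FALSE]
    rownames(ev) <- NULL
  }

  cond <- list(
    blockers_applied = as.logical(tryCatch(
      rhdf5::h5read(path, "meta/blockers_applied"), error = function(e) 0L)),
    ttx_applied = as.logical(tryCatch(
      rhdf5::h5read(path, "meta/ttx_applied"), error = function(e) 0L)),
    label = as.character(tryCatch(
      rhdf5::h5read(path, "meta/label"), error = function(e) ""))
  )
  session <- structure(
    list(sampling_rate_hz = fs, duration_s = duration_s, traces = traces,
         electrode_ids = ids, events = ev, condition = cond),
    class = "recording_session")
  list(session = session, layout = layout)
}

#' Write / read spike trains as CSV
#'
#' Plain CSV with header `electrode_id,time_s`, one row per spike, times in
#' seconds printed to 9 decimal places (nanosecond resolution, far below one
#' sample at 20 kHz), so tables round-trip to that precision.
#'
#' @param trains data frame with columns `electrode_id` and `time_s`.
#' @param path CSV file path.
#' @return `write_spike_table()` returns `path` invisibly;
#'   `read_spike_table()` returns the spike data frame, sorted per electrode
#'   (with a warning if the file was unsorted). Negative times are an error.
#' @export
write_spike_table <- function(trains, path) {
  stopifnot(is.data.frame(trains),
            all(c("electrode_id", "time_s") %in% names(trains)))
  lines <- c("electrode_id,time_s",
             if (nrow(trains))
               sprintf("%d,%.9f", as.integer(trains$electrode_id),
                       trains$time_s))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  if (!file.exists(path)) stop("spike table not found: ", path)
  df <- read.csv(path, colClasses = c(electrode_id = "integer",
                                      time_s = "numeric"))
  if (nrow(df) && any(df$time_s < 0)) stop("negative spike times in ", path)
  ord <- order(df$electrode_id, df$time_s)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("spike table was not sorted; sorting on read")
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write / read a stimulus event table as CSV
#'
#' @param events stimulus event data frame (see [make_stimulus_train()]).
#' @param path CSV file path.
#' @return `write_event_table()` returns `path` invisibly;
#'   `read_event_table()` the event data frame sorted by `ttl_time_s`.
#' @export
write_event_table <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("event table not found: ", path)
  ev <- read.csv(path, stringsAsFactors = FALSE)
  ev <- ev[order(ev$ttl_time_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
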