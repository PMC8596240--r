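#' Microfluidic chip / MEA electrode layout
#'
#' Geometry of the recording setup: a planar 60-electrode array aligned with a
#' PDMS chip whose two culture chambers are connected by parallel
#' microchannels. Axons grow from the chambers into the microchannels, so the
#' electrodes that happen to lie under a microchannel record isolated axonal
#' signals at known positions along the channel; all remaining electrodes lie
#' under one of the chambers and carry no coordinates (no analysis here needs
#' chamber geometry).
#'
#' `default_layout()` builds the canonical configuration: 8 microchannels of
#' 800 um with 3 electrodes each at 200, 400 and 600 um from the channel
#' entrance (the array's uniform 200 um pitch), i.e. 24 in-channel electrodes,
#' and 36 chamber electrodes split evenly between the two chambers for a total
#' of 60.
#'
#' @param n_channels number of microchannels connecting the chambers.
#' @param electrodes_per_channel electrodes inside each microchannel.
#' @param channel_length_um microchannel length in micrometres.
#' @param pitch_um spacing between adjacent in-channel electrodes (um).
#' @param n_electrodes total number of electrodes on the array.
#' @param electrode_diameter_um electrode diameter (um), metadata only.
#'
#' @return An object of class `chip_layout`: a list with elements
#'   `electrodes` (data frame with columns `id`, `compartment`
#'   (`"chamber_A"`, `"chamber_B"` or `"microchannel"`), `channel_index`
#'   (0-based, `NA` for chamber electrodes) and `position_um` (`NA` for
#'   chamber electrodes)), `n_channels`, `channel_length_um`, `pitch_um` and
#'   `electrode_diameter_um`.
#' @examples
#' lay <- default_layout()
#' nrow(lay$electrodes)                  # 60
#' channel_electrodes(lay, 0)$position_um  # 200 400 600
#' @export
default_layout <- function(n_channels = 8L,
                           electrodes_per_channel = 3L,
                           channel_length_um = 800,
                           pitch_um = 200,
                           n_electrodes = 60L,
                           electrode_diameter_um = 30) {
  n_channels <- as.integer(n_channels)
  electrodes_per_channel <- as.integer(electrodes_per_channel)
  if (n_channels < 1L) stop("n_channels must be >= 1")
  if (electrodes_per_channel < 1L) stop("electrodes_per_channel must be >= 1")
  if (electrodes_per_channel * pitch_um >= channel_length_um)
    stop("in-channel electrode positions must stay inside the channel length")

  n_chan_el <- n_channels * electrodes_per_channel
  n_chamber <- as.integer(n_electrodes) - n_chan_el
  if (n_chamber < 0L) stop("more in-channel electrodes than electrodes total")

  mc <- data.frame(
    id = seq_len(n_chan_el),
    compartment = "microchannel",
    channel_index = rep(seq_len(n_channels) - 1L, each = electrodes_per_channel),
    position_um = rep(seq_len(electrodes_per_channel) * pitch_um,
                      times = n_channels),
    stringsAsFactors = FALSE
  )
  ch <- data.frame(
    id = n_chan_el + seq_len(n_chamber),
    compartment = rep(c("chamber_A", "chamber_B"), length.out = n_chamber),
    channel_index = NA_integer_,
    position_um = NA_real_,
    stringsAsFactors = FALSE
  )
  layout <- structure(
    list(
      electrodes = rbind(mc, ch),
      n_channels = n_channels,
      channel_length_um = channel_length_um,
      pitch_um = pitch_um,
      electrode_diameter_um = electrode_diameter_um
    ),
    class = "chip_layout"
  )
  validate_layout(layout)
}

#' Validate a chip layout
#'
#' Checks the structural invariants of a `chip_layout`: channel membership
#' fields are present exactly for microchannel electrodes, in-channel positions
#' are strictly increasing and inside the channel, and electrode ids are
#' unique.
#'
#' @param layout a `chip_layout`.
#' @return The layout, invisibly unchanged, or an error.
#' @export
validate_layout <- function(layout) {
  if (!inherits(layout, "chip_layout")) stop("not a chip_layout")
  el <- layout$electrodes
  if (anyDuplicated(el$id)) stop("electrode ids must be unique")
  mc <- el$compartment == "microchannel"
  if (any(is.na(el$channel_index[mc])) || any(is.na(el$position_um[mc])))
    stop("microchannel electrodes need channel_index and position_um")
  if (any(!is.na(el$channel_index[!mc])) || any(!is.na(el$position_um[!mc])))
    stop("chamber electrodes must not carry channel coordinates")
  if (any(el$channel_index[mc] < 0L | el$channel_index[mc] >= layout$n_channels))
    stop("channel_index out of range")
  if (any(el$position_um[mc] <= 0 | el$position_um[mc] >= layout$channel_length_um))
    stop("position_um must lie strictly inside the channel")
  for (c_idx in unique(el$channel_index[mc])) {
    pos <- el$position_um[mc & el$channel_index == c_idx]
    if (any(diff(sort(pos)) <= 0)) stop("in-channel positions must be distinct")
  }
  invisible(layout)
}

#' Electrodes of one microchannel, ordered along the channel
#'
#' @param layout a `chip_layout`.
#' @param channel_index 0-based microchannel index (matching the chip
#'   drawings), `0 <= channel_index < n_channels`.
#' @return Data frame of the channel's electrodes sorted by ascending
#'   `position_um`.
#' @export
channel_electrodes <- function(layout, channel_index) {
  validate_layout(layout)
  if (length(channel_index) != 1L || is.na(channel_index) ||
      channel_index < 0 || channel_index >= layout$n_channels ||
      channel_index != floor(channel_index))
    stop(sprintf("unknown channel index %s (layout has channels 0..%d)",
                 format(channel_index), layout$n_channels - 1L))
  el <- layout$electrodes
  keep <- el$compartment == "microchannel" & el$channel_index == channel_index
  out <- el[keep, , drop = FALSE]
  out <- out[order(out$position_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ids of all microchannel electrodes
#'
#' @param layout a `chip_layout`.
#' @return Integer vector of electrode ids lying inside microchannels.
#' @export
microchannel_electrodes <- function(layout) {
  el <- layout$electrodes
  el$id[el$compartment == "microchannel"]
}

#' Read / write a chip layout as JSON
#'
#' The on-disk representation keeps all distances in micrometres:
#' `{"n_channels", "channel_length_um", "pitch_um", "electrode_diameter_um",
#' "electrodes": [{"id", "compartment", "channel_index", "position_um"}]}`;
#' chamber electrodes carry `null` channel fields.
#'
#' @param layout a `chip_layout`.
#' @param path file path of the JSON document.
#' @return `write_layout()` returns `path` invisibly; `read_layout()` returns
#'   a validated `chip_layout`.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  doc <- list(
    n_channels = layout$n_channels,
    channel_length_um = layout$channel_length_um,
    pitch_um = layout$pitch_um,
    electrode_diameter_um = layout$electrode_diameter_um,
    electrodes = layout$electrodes
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  doc <- jsonlite::fromJSON(path)
  el <- doc$electrodes
  el$channel_index <- suppressWarnings(as.integer(el$channel_index))
  el$position_um <- as.numeric(el$position_um)
  layout <- structure(
    list(
      electrodes = el,
      n_channels = as.integer(doc$n_channels),
      channel_length_um = as.numeric(doc$channel_length_um),
      pitch_um = as.numeric(doc$pitch_um),
      electrode_diameter_um = as.numeric(doc$electrode_diameter_um)
    ),
    class = "chip_layout"
  )
  validate_layout(layout)
}

#' @export
print.chip_layout <- function(x, ...) {
  el <- x$electrodes
  cat(sprintf(
    "chip_layout: %d electrodes (%d in %d microchannels of %g um, pitch %g um)\n",
    nrow(el), sum(el$compartment == "microchannel"), x$n_channels,
    x$channel_length_um, x$pitch_um))
  invisible(x)
}
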