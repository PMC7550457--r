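#' Source-detector separation of one measurement channel
#'
#' Euclidean distance, in cm, between the source and detector optodes a
#' measurement-list entry refers to.
#'
#' @param probe A [nirs_probe()].
#' @param source_index,detector_index 1-based optode indices.
#' @return Separation in cm.
#' @export
channel_separation <- function(probe, source_index, detector_index) {
  if (any(source_index < 1) || any(source_index > nrow(probe$source_pos))) {
    abort(sprintf("source_index %s outside probe source list",
                  paste(source_index, collapse = ",")))
  }
  if (any(detector_index < 1) ||
        any(detector_index > nrow(probe$detector_pos))) {
    abort(sprintf("detector_index %s outside probe detector list",
                  paste(detector_index, collapse = ",")))
  }
  d <- probe$source_pos[source_index, , drop = FALSE] -
    probe$detector_pos[detector_index, , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Classify channels as short- or long-separation
#'
#' Computes the source-detector separation of every channel and classifies
#' it as `"short"` (separation <= `short_max`) or `"long"`. Classification
#' is a property of the source-detector pair, so both wavelength rows of a
#' pair always receive the same class. Short-separation (~1 cm) channels
#' sample scalp/systemic physiology and serve as nuisance regressors;
#' long-separation (~3 cm) channels reach cortex and are the augmentation
#' targets.
#'
#' @param rec A [nirs_recording()].
#' @param short_max Class boundary in cm; default 1.5 cm, the midpoint
#'   between nominal ~1 cm short and ~3 cm long separations.
#' @return A tibble with one row per channel (in data-column order):
#'   `channel`, `source_index`, `detector_index`, `wavelength_index`,
#'   `wavelength_nm`, `separation`, `class`.
#' @export
#' @examples
#' rec <- simulate_resting(sim_preset("dataset1", seed = 1, duration = 10))
#' dplyr::count(classify_channels(rec), class)
classify_channels <- function(rec, short_max = 1.5) {
  m <- rec$measurements
  sep <- channel_separation(rec$probe, m$source_index, m$detector_index)
  if (any(sep <= 0)) {
    k <- which(sep <= 0)[1]
    abort(sprintf(
      "geometry error: zero separation for channel %d (source %d, detector %d)",
      k, m$source_index[k], m$detector_index[k]))
  }
  tibble(
    channel = seq_len(nrow(m)),
    source_index = m$source_index,
    detector_index = m$detector_index,
    wavelength_index = m$wavelength_index,
    wavelength_nm = rec$probe$wavelengths[m$wavelength_index],
    separation = sep,
    class = ifelse(sep <= short_max, "short", "long")
  )
}

#' Distinct source-detector pairs of a recording
#'
#' One row per optode pair with its separation and short/long class;
#' `channels` is a list column of the data columns (wavelength rows)
#' belonging to the pair.
#'
#' @inheritParams classify_channels
#' @return A tibble with columns `source_index`, `detector_index`,
#'   `separation`, `class`, `channels`.
#' @export
channel_pairs <- function(rec, short_max = 1.5) {
  classify_channels(rec, short_max) |>
    dplyr::group_by(.data$source_index, .data$detector_index) |>
    dplyr::summarise(
      separation = .data$separation[1],
      class = .data$class[1],
      channels = list(.data$channel),
      .groups = "drop"
    )
}
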