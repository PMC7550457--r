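#' Construct an in-memory fNIRS recording
#'
#' A `nirs_recording` is the in-memory twin of a SNIRF file: an intensity
#' matrix (samples x channels) with a uniform time vector, a measurement
#' list pairing each column with a source/detector/wavelength triple, stimulus
#' events, auxiliary physiological channels, and the optode probe.
#'
#' @param data Numeric matrix of raw intensity, `n_samples x n_channels`,
#'   arbitrary units, non-negative.
#' @param time Numeric vector of sample times in seconds, uniformly spaced.
#' @param measurements Tibble with one row per data column, in column order:
#'   `source_index`, `detector_index`, `wavelength_index` (1-based into the
#'   probe lists) and `data_type_label` (1 = synthetic HRF added, 0 = none).
#' @param probe A [nirs_probe()].
#' @param stim Tibble of stimulus events with columns `name`, `onset` (s),
#'   `duration` (s), `value`; zero rows if the recording has no paradigm.
#' @param aux Tibble of auxiliary channels with columns `name` and list
#'   columns `time`, `series` (auxiliaries may have their own time base).
#' @param meta Named list of free-form metadata tags.
#'
#' @return An object of class `nirs_recording`.
#' @seealso [read_snirf()], [write_snirf()], [validate_recording()]
#' @export
#' @examples
#' rec <- simulate_resting(sim_config(duration = 20, n_ls_pairs = 2, n_ss_pairs = 1, seed = 1))
#' rec
nirs_recording <- function(data, time, measurements, probe,
                           stim = empty_stim(), aux = empty_aux(),
                           meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  measurements <- as_tibble(measurements)
  if (!"data_type_label" %in% names(measurements)) {
    measurements$data_type_label <- 0L
  }
  measurements$data_type_label <- as.integer(measurements$data_type_label)
  structure(
    list(
      data = data,
      time = as.double(time),
      measurements = measurements,
      stim = as_tibble(stim),
      aux = as_tibble(aux),
      probe = probe,
      meta = meta
    ),
    class = "nirs_recording"
  )
}

#' Construct an optode probe
#'
#' @param wavelengths Numeric vector of wavelengths in nm, ascending
#'   (continuous-wave systems in this toolkit use 690 and 830 nm).
#' @param source_pos,detector_pos Numeric matrices (`n x 3`) of optode
#'   coordinates in cm.
#' @param source_labels,detector_labels Character vectors of optode names;
#'   defaults `S1..`, `D1..`.
#'
#' @return An object of class `nirs_probe`.
#' @export
nirs_probe <- function(wavelengths, source_pos, detector_pos,
                       source_labels = NULL, detector_labels = NULL) {
  source_pos <- as_pos_matrix(source_pos, "source_pos")
  detector_pos <- as_pos_matrix(detector_pos, "detector_pos")
  if (is.null(source_labels)) {
    source_labels <- paste0("S", seq_len(nrow(source_pos)))
  }
  if (is.null(detector_labels)) {
    detector_labels <- paste0("D", seq_len(nrow(detector_pos)))
  }
  structure(
    list(
      wavelengths = as.double(wavelengths),
      source_pos = source_pos,
      detector_pos = detector_pos,
      source_labels = as.character(source_labels),
      detector_labels = as.character(detector_labels)
    ),
    class = "nirs_probe"
  )
}

as_pos_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) == 2) x <- cbind(x, 0) # planar probes: pad z
  if (ncol(x) != 3) {
    abort(sprintf("`%s` must have 3 coordinate columns (cm)", what))
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

empty_stim <- function() {
  tibble(name = character(), onset = double(), duration = double(),
         value = double())
}

empty_aux <- function() {
  tibble(name = character(), time = list(), series = list())
}

#' @export
print.nirs_recording <- function(x, ...) {
  fs <- sampling_rate(x)
  cat(sprintf(
    "<nirs_recording> %d channels x %d samples (%.1f s @ %.6g Hz)\n",
    ncol(x$data), nrow(x$data), recording_duration(x), fs
  ))
  cat(sprintf("  wavelengths: %s nm\n",
              paste(x$probe$wavelengths, collapse = ", ")))
  cat(sprintf("  probe: %d sources, %d detectors\n",
              nrow(x$probe$source_pos), nrow(x$probe$detector_pos)))
  n_aug <- sum(x$measurements$data_type_label == 1L)
  if (n_aug > 0) cat(sprintf("  channels flagged HRF-added: %d\n", n_aug))
  if (nrow(x$stim) > 0) {
    cat(sprintf("  stim: %s\n",
                paste(sprintf("%s (%d events)",
                              unique(x$stim$name),
                              table(x$stim$name)[unique(x$stim$name)]),
                      collapse = ", ")))
  }
  if (nrow(x$aux) > 0) {
    cat(sprintf("  aux: %s\n", paste(x$aux$name, collapse = ", ")))
  }
  invisible(x)
}

#' Sampling rate and duration of a recording
#'
#' `sampling_rate()` returns the sampling frequency in Hz implied by the time
#' vector; `recording_duration()` returns the total acquisition length in
#' seconds (`n_samples / fs`, i.e. including the final sample interval).
#'
#' @param rec A [nirs_recording()].
#' @return A scalar double.
#' @export
sampling_rate <- function(rec) {
  if (length(rec$time) < 2) return(NA_real_)
  1 / mean(diff(rec$time))
}

#' @rdname sampling_rate
#' @export
recording_duration <- function(rec) {
  nrow(rec$data) / sampling_rate(rec)
}

n_channels <- function(rec) ncol(rec$data)
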