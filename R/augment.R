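#' Prune long-separation channels by SNR
#'
#' Returns the long-separation source-detector pairs whose channels (both
#' wavelengths) have raw-intensity SNR at or above `threshold` dB — the
#' pool from which augmentation targets are drawn.
#'
#' @param rec A [nirs_recording()].
#' @param threshold SNR threshold in dB (default 5).
#' @param short_max Short/long class boundary in cm (see
#'   [classify_channels()]).
#' @return A tibble of retained pairs (columns of [channel_pairs()]) plus
#'   `min_snr_db`. Warns (and returns zero rows) when the recording has no
#'   long-separation channels.
#' @export
prune_channels <- function(rec, threshold = 5, short_max = 1.5) {
  pairs <- channel_pairs(rec, short_max)
  ls_pairs <- pairs[pairs$class == "long", ]
  if (nrow(ls_pairs) == 0) {
    warn("recording has no long-separation channels")
    ls_pairs$min_snr_db <- double()
    return(ls_pairs)
  }
  snr <- apply(rec$data, 2, snr_db)
  ls_pairs$min_snr_db <- purrr::map_dbl(ls_pairs$channels,
                                        function(ch) min(snr[ch]))
  ls_pairs[ls_pairs$min_snr_db >= threshold, ]
}

#' Plan a ground-truth augmentation
#'
#' Partitions the recording into consecutive windows of `window_len`
#' seconds (a trailing partial window receives no trial), draws one onset
#' per window uniformly from `onset_range` (relative to the window start,
#' shared by all augmented channels), and draws — once per recording — a
#' random subset of `channel_fraction` of the long-separation pairs that
#' survive SNR pruning. With the defaults the latest onset plus the 16.5 s
#' kernel exactly fills the 20 s window, so consecutive injected responses
#' never overlap. Fully reproducible from `seed`.
#'
#' @param rec A [nirs_recording()].
#' @param level Amplitude level in percent (published variants: 100/50/20).
#' @param seed Integer seed governing onset and channel draws.
#' @param window_len Window length, s (default 20).
#' @param onset_range Onset interval relative to window start, s (default
#'   `c(0, 3.5)`).
#' @param snr_threshold Pruning threshold in dB (default 5).
#' @param channel_fraction Fraction of pruned long-separation pairs to
#'   augment (default 0.5; `floor()` applied to odd counts).
#' @param kernel_duration Kernel support used for the no-spillover check
#'   and the stim event durations, s (default 16.5).
#' @return An object of class `augmentation_plan`: list with `windows`
#'   (tibble `window`, `start`, `onset` — onsets absolute, s), `channels`
#'   (tibble `source_index`, `detector_index`), and the configuration
#'   fields.
#' @export
plan_augmentation <- function(rec, level = 100, seed = 1, window_len = 20,
                              onset_range = c(0, 3.5), snr_threshold = 5,
                              channel_fraction = 0.5,
                              kernel_duration = 16.5) {
  if (onset_range[2] + kernel_duration > window_len + 1e-9) {
    abort(sprintf(
      "spillover: max onset %g s + kernel %g s exceeds the %g s window",
      onset_range[2], kernel_duration, window_len))
  }
  if (channel_fraction <= 0 || channel_fraction > 1) {
    abort("channel_fraction must be in (0, 1]")
  }
  dur <- recording_duration(rec)
  if (dur < window_len) {
    abort(sprintf("recording (%.1f s) is shorter than one %g s window",
                  dur, window_len))
  }
  n_windows <- floor(dur / window_len)
  starts <- (seq_len(n_windows) - 1) * window_len

  pool <- prune_channels(rec, snr_threshold)
  n_pick <- floor(channel_fraction * nrow(pool))
  withr::with_seed(seed, {
    onsets <- starts + runif(n_windows, onset_range[1], onset_range[2])
    picked <- sort(sample(nrow(pool), n_pick))
  })
  structure(
    list(
      windows = tibble(window = seq_len(n_windows), start = starts,
                       onset = onsets),
      channels = pool[picked, c("source_index", "detector_index")],
      level = level, seed = seed, window_len = window_len,
      onset_range = onset_range, snr_threshold = snr_threshold,
      channel_fraction = channel_fraction, kernel_duration = kernel_duration
    ),
    class = "augmentation_plan"
  )
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat(sprintf(
    "<augmentation_plan> level %g%%, seed %d: %d trials in %g s windows, %d channels\n",
    x$level, x$seed, nrow(x$windows), x$window_len, nrow(x$channels)))
  invisible(x)
}

#' Inject synthetic HRFs according to a plan
#'
#' Applies the multiplicative intensity-domain injection
#' `I'(t) = I(t) * (1 + f_lambda * h(t - onset))` at every planned onset on
#' every planned channel, where `h` is the unit-peak kernel and `f_lambda`
#' the calibrated peak fractional change (+1% at 690 nm, -2% at 830 nm at
#' the 100% level, scaled by `plan$level`). The returned recording gains
#' one stimulus channel named `HRF_<level>` with one
#' `(onset, kernel duration, 1)` event per window, and `data_type_label`
#' set to 1 on every augmented channel; all other channels, auxiliaries and
#' the probe are bit-identical to the input, which is not mutated.
#'
#' @param rec A [nirs_recording()].
#' @param plan An [plan_augmentation()] result for this recording.
#' @param kernel An [hrf_kernel()]; defaults to the standard kernel at the
#'   recording's sampling rate.
#' @return The augmented [nirs_recording()].
#' @export
apply_plan <- function(rec, plan, kernel = NULL) {
  fs <- sampling_rate(rec)
  if (is.null(kernel)) {
    kernel <- hrf_kernel(duration = plan$kernel_duration, fs = fs)
  }
  amp <- calibrate_amplitude(plan$level)
  frac_by_wl <- amp$frac[as.character(round(rec$probe$wavelengths))]
  if (anyNA(frac_by_wl)) {
    abort("amplitude calibration is defined for 690 and 830 nm recordings")
  }

  pairs <- channel_pairs(rec)
  key <- paste(pairs$source_index, pairs$detector_index)
  want <- paste(plan$channels$source_index, plan$channels$detector_index)
  hit <- match(want, key)
  if (anyNA(hit)) {
    abort(sprintf("plan channel (source %s, detector %s) not in recording",
                  plan$channels$source_index[which(is.na(hit))[1]],
                  plan$channels$detector_index[which(is.na(hit))[1]]))
  }

  out <- rec
  n <- nrow(out$data)
  len <- length(kernel$samples)
  for (p in hit) {
    for (ch in pairs$channels[[p]]) {
      f <- frac_by_wl[[rec$measurements$wavelength_index[ch]]]
      for (onset in plan$windows$onset) {
        i0 <- round(onset * fs) + 1
        idx <- i0:min(i0 + len - 1, n)
        out$data[idx, ch] <- out$data[idx, ch] *
          (1 + f * kernel$samples[seq_along(idx)])
      }
    }
    out$measurements$data_type_label[pairs$channels[[p]]] <- 1L
  }

  out$stim <- dplyr::bind_rows(rec$stim, tibble(
    name = sprintf("HRF_%g", plan$level),
    onset = plan$windows$onset,
    duration = kernel$duration,
    value = 1
  ))
  out
}

#' Plan, inject, and flag in one call
#'
#' Convenience wrapper: [plan_augmentation()] followed by [apply_plan()].
#'
#' @inheritParams plan_augmentation
#' @param ... Further arguments to [plan_augmentation()].
#' @return A list with `recording` (augmented) and `plan`.
#' @export
augment_recording <- function(rec, level = 100, seed = 1, ...) {
  plan <- plan_augmentation(rec, level = level, seed = seed, ...)
  list(recording = apply_plan(rec, plan), plan = plan)
}

#' Serialize an augmentation plan to JSON
#'
#' The sidecar ground-truth file consumed by scoring tools: windows,
#' absolute onsets, augmented channels, level and seed.
#'
#' @param plan An [plan_augmentation()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$windows <- as_tibble(raw$windows)
  raw$channels <- as_tibble(raw$channels)
  structure(raw, class = "augmentation_plan")
}
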