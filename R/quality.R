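#' Channel signal-to-noise ratio in dB
#'
#' `SNR = 20 * log10(mean(x) / sd(x))` on the raw intensity series. A
#' zero-variance (constant) channel returns `Inf`; a nonpositive mean has
#' no meaningful dB value and returns `NaN` with a warning.
#'
#' @param series Nonempty numeric vector of raw intensities.
#' @return SNR in dB.
#' @export
#' @examples
#' snr_db(rnorm(1000, mean = 100, sd = 1)) # ~40 dB
snr_db <- function(series) {
  if (length(series) == 0) abort("snr_db: empty series")
  s <- sd(series)
  m <- mean(series)
  if (s == 0) return(Inf)
  if (m <= 0) {
    warn("snr_db: nonpositive mean intensity; SNR undefined")
    return(NaN)
  }
  20 * log10(m / s)
}

#' Motion parameters
#'
#' Parameter set of the sliding-window motion-artifact detector, matching
#' the semantics of the classic Homer channel-wise detector: `t_motion` is
#' the window length over which signal excursions are judged, `t_mask` the
#' dilation applied around detected artifacts, `stdev_thresh` the multiple
#' of the channel-wide standard deviation of the sample-to-sample change
#' signal that flags a window, and `amp_thresh` an absolute amplitude
#' excursion bound in signal units.
#'
#' @param t_motion Window length, s (default 0.5).
#' @param t_mask Mask dilation, s (default 0.5).
#' @param stdev_thresh Std-multiple criterion, unitless (default 20).
#' @param amp_thresh Absolute excursion criterion, signal units (default 5).
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(t_motion = 0.5, t_mask = 0.5, stdev_thresh = 20,
                          amp_thresh = 5) {
  if (any(c(t_motion, t_mask, stdev_thresh, amp_thresh) <= 0)) {
    abort("all motion parameters must be > 0")
  }
  structure(list(t_motion = t_motion, t_mask = t_mask,
                 stdev_thresh = stdev_thresh, amp_thresh = amp_thresh),
            class = "motion_params")
}

#' Detect motion artifacts in one channel
#'
#' Slides a window of length `t_motion` across the series and flags windows
#' in which either the largest sample-to-sample change exceeds
#' `stdev_thresh` times the channel-wide standard deviation of the change
#' signal, or the raw-signal excursion (max - min) exceeds `amp_thresh` in
#' absolute units. Within each flagged window the sample
#' of maximal absolute change is taken as the artifact seed; the segment
#' `[seed, seed + t_motion]` is marked and then dilated by `t_mask` on both
#' sides, so an isolated step at time `t0` yields a mask covering
#' `[t0 - t_mask, t0 + t_motion + t_mask]`. Compatible in spirit — not bit
#' for bit — with the Homer channel-wise detector whose named parameters it
#' shares.
#'
#' @param series Numeric vector (conventionally dOD, see [qc_report()]).
#' @param time Uniform time vector, s.
#' @param params A [motion_params()].
#' @return Logical mask, `TRUE` on motion-contaminated samples.
#' @export
detect_motion <- function(series, time, params = motion_params()) {
  n <- length(series)
  stopifnot(length(time) == n)
  fs <- 1 / mean(diff(time))
  w <- round(params$t_motion * fs)
  if (w < 2) abort("t_motion must span at least 2 samples")
  if (n <= w) return(rep(FALSE, n))

  roll_max <- zoo::rollmax(series, k = w, align = "left")
  roll_min <- -zoo::rollmax(-series, k = w, align = "left")
  amp_excursion <- roll_max - roll_min
  d <- diff(series)
  # std criterion on the change signal: a smooth oscillation has window
  # excursions far above its per-sample changes, so judging the raw-signal
  # range against sd(diff) would flag any noiseless sinusoid
  d_excursion <- zoo::rollmax(abs(d), k = w - 1, align = "left")
  flagged <- which(d_excursion[seq_along(amp_excursion)] >
                     params$stdev_thresh * sd(d) |
                     amp_excursion > params$amp_thresh)
  if (length(flagged) == 0) return(rep(FALSE, n))

  # artifact seed: steepest sample-to-sample change within each flagged window
  seeds <- unique(vapply(flagged, function(s) {
    j <- which.max(abs(d[s:min(s + w - 2, n - 1)]))
    s + j # index of the sample after the largest jump
  }, integer(1)))

  m <- round(params$t_mask * fs)
  mask_start <- pmax(1L, seeds - m)
  mask_end <- pmin(n, seeds + w + m)
  delta <- integer(n + 1)
  for (i in seq_along(seeds)) {
    delta[mask_start[i]] <- delta[mask_start[i]] + 1L
    delta[mask_end[i] + 1L] <- delta[mask_end[i] + 1L] - 1L
  }
  cumsum(delta[seq_len(n)]) > 0
}

#' Fraction of acquisition time flagged as motion
#'
#' @param mask Logical mask from [detect_motion()].
#' @return `mean(mask)`, in `[0, 1]`.
#' @export
motion_ratio <- function(mask) {
  if (length(mask) == 0) abort("motion_ratio: empty mask")
  mean(mask)
}

#' Per-channel quality report
#'
#' Computes, for every channel of a recording, the raw-intensity SNR in dB
#' and the motion ratio (fraction of samples flagged by [detect_motion()]).
#' Motion detection runs on dOD by default — the Homer convention, which
#' makes `amp_thresh` comparable across channels — or on raw intensity.
#'
#' @param rec A [nirs_recording()].
#' @param params A [motion_params()].
#' @param domain Signal domain for motion detection: `"od"` (default) or
#'   `"intensity"`.
#' @return A tibble of class `qc_report`, one row per channel: the
#'   [classify_channels()] columns plus `snr_db` and `motion_ratio`.
#' @seealso [qc_summary()] for the per-recording aggregate.
#' @export
qc_report <- function(rec, params = motion_params(),
                      domain = c("od", "intensity")) {
  domain <- match.arg(domain)
  classes <- classify_channels(rec)
  sig <- if (domain == "od") intensity_to_od(rec$data) else rec$data
  classes$snr_db <- apply(rec$data, 2, snr_db)
  classes$motion_ratio <- apply(sig, 2, function(x) {
    motion_ratio(detect_motion(x, rec$time, params))
  })
  class(classes) <- c("qc_report", class(classes))
  classes
}

#' Per-recording quality summary
#'
#' Mean and standard deviation of channel SNR plus the mean motion ratio —
#' the per-participant aggregates conventionally reported for these data.
#'
#' @param report A [qc_report()] tibble.
#' @return A one-row tibble: `n_channels`, `mean_snr_db`, `sd_snr_db`,
#'   `mean_motion_ratio`.
#' @export
qc_summary <- function(report) {
  finite_snr <- report$snr_db[is.finite(report$snr_db)]
  tibble(
    n_channels = nrow(report),
    mean_snr_db = mean(finite_snr),
    sd_snr_db = sd(finite_snr),
    mean_motion_ratio = mean(report$motion_ratio)
  )
}

#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("channel", "class", "snr_db", "motion_ratio")],
    c("snr_db", "motion_ratio"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$channel, y = .data$value,
                                     colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Channel", y = NULL, colour = "Separation",
                  title = "Channel quality metrics")
}
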