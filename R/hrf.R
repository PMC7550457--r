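#' Synthetic hemodynamic response kernel
#'
#' Builds the peak-normalized gamma-shaped HRF time course
#' `h(t) = (t/tp)^a * exp(a * (1 - t/tp))` on the closed grid
#' `t = 0, 1/fs, ..., duration`, with time-to-peak `tp` and shape `a`.
#' The default shape `a = 10` leaves a terminal residual
#' `h(duration) < 0.001` so the truncation at `duration` is numerically
#' clean; smaller shapes that violate this bound are rejected.
#'
#' @param time_to_peak Time of the kernel maximum, s (default 6).
#' @param duration Total kernel support, s (default 16.5).
#' @param fs Sampling rate, Hz (default 50).
#' @param shape Unitless gamma shape parameter `a > 1` (default 10).
#' @return An object of class `hrf_kernel`: list with `samples` (unit peak,
#'   `round(duration * fs) + 1` values), `time`, and the parameters.
#' @export
#' @examples
#' k <- hrf_kernel()
#' k$time[which.max(k$samples)] # 6 s
hrf_kernel <- function(time_to_peak = 6, duration = 16.5, fs = 50,
                       shape = 10) {
  if (time_to_peak <= 0 || time_to_peak >= duration) {
    abort("need 0 < time_to_peak < duration")
  }
  if (fs <= 0) abort("fs must be > 0")
  if (shape <= 1) abort("shape must be > 1")
  gamma_h <- function(t) (t / time_to_peak)^shape *
    exp(shape * (1 - t / time_to_peak))
  resid <- gamma_h(duration)
  if (resid >= 0.001) {
    min_shape <- ceiling(uniroot(
      function(a) a * (log(duration / time_to_peak) + 1 -
                         duration / time_to_peak) - log(0.001),
      c(1 + 1e-6, 1e3))$root * 10) / 10
    abort(sprintf(
      "shape %.3g leaves a truncation residual of %.2g at %g s; use shape >= %.1f",
      shape, resid, duration, min_shape))
  }
  time <- seq(0, round(duration * fs)) / fs
  structure(
    list(samples = gamma_h(time), time = time, time_to_peak = time_to_peak,
         duration = duration, fs = fs, shape = shape),
    class = "hrf_kernel"
  )
}

#' @importFrom stats uniroot
#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf(
    "<hrf_kernel> gamma, peak at %g s, support %g s (%d samples @ %g Hz), shape %g\n",
    x$time_to_peak, x$duration, length(x$samples), x$fs, x$shape))
  invisible(x)
}

#' @method autoplot hrf_kernel
#' @export
autoplot.hrf_kernel <- function(object, ...) {
  ggplot2::ggplot(tibble(time = object$time, h = object$samples),
                  ggplot2::aes(x = .data$time, y = .data$h)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Normalized response",
                  title = "Synthetic HRF kernel")
}

#' Calibrate injection amplitudes for a contrast level
#'
#' Maps a percentage amplitude level to the per-wavelength peak fractional
#' intensity changes and the implied hemoglobin concentration peaks. The
#' 100% level is defined as +1% intensity change at 690 nm and -2% at
#' 830 nm which, inverted through the modified Beer-Lambert law at 3 cm
#' separation with DPF 6, corresponds to a concentration peak of roughly
#' +0.66 uM HbO2 and -0.23 uM HbR (the exact value depends on the
#' extinction table). Lower levels scale both linearly, emulating lower
#' contrast-to-noise responses.
#'
#' @param level Amplitude level in percent, `>= 0` (the published variants
#'   use 100, 50 and 20).
#' @param separation,dpf Geometry used for the concentration calibration
#'   (defaults 3 cm, DPF 6).
#' @param ext Optional extinction table override.
#' @return An object of class `amplitude_spec`: list with `level`,
#'   `frac` (named fractional peak changes at 690/830 nm) and `conc_peak`
#'   (tibble `hbo2`, `hbr`, molar).
#' @export
#' @examples
#' calibrate_amplitude(100)$conc_peak * 1e6 # micromolar
calibrate_amplitude <- function(level, separation = 3, dpf = 6, ext = NULL) {
  if (level < 0) abort("level must be >= 0 percent")
  frac <- c("690" = 0.01, "830" = -0.02) * level / 100
  # concentration peak scales linearly from the 100% reference so that
  # conc_peak(level) = level/100 * conc_peak(100) holds exactly
  od_ref <- cbind(-log10(1.01), -log10(0.98))
  conc_peak <- od_to_conc(od_ref, wavelengths = c(690, 830),
                          separation = separation, dpf = dpf, ext = ext) *
    (level / 100)
  structure(
    list(level = level, frac = frac, conc_peak = conc_peak,
         separation = separation, dpf = dpf),
    class = "amplitude_spec"
  )
}

#' @export
print.amplitude_spec <- function(x, ...) {
  cat(sprintf(
    "<amplitude_spec> level %g%%: %+.3g%% @690 nm, %+.3g%% @830 nm -> %+.3g / %+.3g uM HbO2/HbR\n",
    x$level, 100 * x$frac[["690"]], 100 * x$frac[["830"]],
    1e6 * x$conc_peak$hbo2, 1e6 * x$conc_peak$hbr))
  invisible(x)
}
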