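#' Hemoglobin extinction coefficients
#'
#' Looks up the decadic molar extinction coefficients of oxy- and
#' deoxyhemoglobin at the requested wavelengths from the shipped
#' Gratzer/Prahl compilation (the coefficient set distributed with the Homer
#' processing ecosystem), interpolating linearly between tabulated
#' wavelengths. Units are cm^-1 (mole/liter)^-1 in the base-10 absorbance
#' convention matching [intensity_to_od()].
#'
#' @param wavelengths Wavelengths in nm (within the tabulated 660-850 nm
#'   range).
#' @param table Optional replacement table: a data frame or CSV path with
#'   columns `wavelength_nm`, `eps_hbo2`, `eps_hbr`.
#' @return A tibble with columns `wavelength_nm`, `eps_hbo2`, `eps_hbr`.
#' @export
#' @examples
#' extinction_coefficients(c(690, 830))
extinction_coefficients <- function(wavelengths, table = NULL) {
  tab <- load_extinction_table(table)
  rng <- range(tab$wavelength_nm)
  if (any(wavelengths < rng[1] | wavelengths > rng[2])) {
    abort(sprintf("wavelengths must lie within the tabulated %g-%g nm range",
                  rng[1], rng[2]))
  }
  tibble(
    wavelength_nm = as.double(wavelengths),
    eps_hbo2 = approx(tab$wavelength_nm, tab$eps_hbo2, wavelengths)$y,
    eps_hbr = approx(tab$wavelength_nm, tab$eps_hbr, wavelengths)$y
  )
}

load_extinction_table <- function(table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "extinction_gratzer.csv",
                        package = "nirsynth", mustWork = TRUE)
    table <- utils::read.csv(path, comment.char = "#")
  } else if (is.character(table)) {
    table <- utils::read.csv(table, comment.char = "#")
  }
  stopifnot(all(c("wavelength_nm", "eps_hbo2", "eps_hbr") %in% names(table)))
  if (any(table$eps_hbo2 <= 0) || any(table$eps_hbr <= 0)) {
    abort("extinction coefficients must be positive")
  }
  as_tibble(table)
}

#' Intensity to optical density change
#'
#' Converts raw intensity to the change in optical density,
#' `dOD = -log10(I / I0)`, with the baseline `I0` defaulting to the series
#' mean (standard continuous-wave practice).
#'
#' @param series Positive intensity vector or samples-x-channels matrix.
#' @param baseline Baseline intensity; a scalar, or one value per channel
#'   for matrix input. Defaults to per-channel means.
#' @return dOD, same shape as `series` (unitless).
#' @export
intensity_to_od <- function(series, baseline = NULL) {
  if (any(series <= 0)) {
    abort(sprintf("nonpositive intensity at sample %d",
                  which(series <= 0)[1]))
  }
  if (is.matrix(series)) {
    if (is.null(baseline)) baseline <- colMeans(series)
    if (any(baseline <= 0)) abort("baseline must be positive")
    return(-log10(sweep(series, 2, baseline, "/")))
  }
  if (is.null(baseline)) baseline <- mean(series)
  if (any(baseline <= 0)) abort("baseline must be positive")
  -log10(series / baseline)
}

#' Optical density to hemoglobin concentration change (modified Beer-Lambert)
#'
#' Solves the two-wavelength modified Beer-Lambert law
#' `dOD_lambda = (eps_HbO2,lambda * dHbO2 + eps_HbR,lambda * dHbR) * L * DPF_lambda`
#' for the chromophore concentration changes, per sample. `L` is the
#' source-detector separation (cm) and DPF the differential pathlength
#' factor scaling the geometric separation to the effective photon path.
#'
#' @param od Numeric matrix (or 2-vector) of dOD with one column per
#'   wavelength, in the order of `wavelengths`.
#' @param wavelengths The two wavelengths in nm (default `c(690, 830)`).
#' @param separation Source-detector separation in cm (default 3).
#' @param dpf Differential pathlength factor, recycled to one value per
#'   wavelength (default 6 at both).
#' @param ext Optional extinction table override (see
#'   [extinction_coefficients()]).
#' @return A tibble with columns `hbo2`, `hbr` in molar units (multiply by
#'   1e6 for micromolar), one row per sample.
#' @export
#' @examples
#' # level-100 calibration: +1% at 690 nm, -2% at 830 nm
#' od <- cbind(-log10(1.01), -log10(0.98))
#' od_to_conc(od) * 1e6 # micromolar
od_to_conc <- function(od, wavelengths = c(690, 830), separation = 3,
                       dpf = 6, ext = NULL) {
  if (length(wavelengths) != 2) {
    abort("od_to_conc requires exactly two wavelengths")
  }
  if (separation <= 0) abort("separation must be > 0 cm")
  dpf <- rep_len(dpf, 2)
  if (any(dpf <= 0)) abort("dpf must be > 0")
  od <- matrix(od, ncol = 2)
  E <- mbll_matrix(wavelengths, separation, dpf, ext)
  kappa <- kappa(E)
  if (!is.finite(kappa) || kappa > 1e12) {
    abort("extinction matrix is singular for these wavelengths")
  }
  conc <- t(solve(E, t(od)))
  tibble(hbo2 = conc[, 1], hbr = conc[, 2])
}

#' @rdname od_to_conc
#' @param conc Matrix/tibble with columns `hbo2`, `hbr` in molar, or a
#'   2-vector `(hbo2, hbr)`.
#' @return For `conc_to_od()`: a matrix of dOD with one column per
#'   wavelength — the exact inverse of [od_to_conc()].
#' @export
conc_to_od <- function(conc, wavelengths = c(690, 830), separation = 3,
                       dpf = 6, ext = NULL) {
  if (is.data.frame(conc)) conc <- cbind(conc$hbo2, conc$hbr)
  conc <- matrix(conc, ncol = 2)
  dpf <- rep_len(dpf, 2)
  E <- mbll_matrix(wavelengths, separation, dpf, ext)
  od <- conc %*% t(E)
  colnames(od) <- paste0("od_", wavelengths)
  od
}

mbll_matrix <- function(wavelengths, separation, dpf, ext = NULL) {
  eps <- extinction_coefficients(wavelengths, table = ext)
  # rows: wavelengths; cols: HbO2, HbR; pathlength folded in per wavelength
  cbind(eps$eps_hbo2, eps$eps_hbr) * (separation * dpf)
}

#' Convert a recording to hemoglobin concentration series
#'
#' Applies [intensity_to_od()] (mean baseline) and [od_to_conc()] to every
#' source-detector pair of a recording, using each pair's own geometric
#' separation. The per-pair result is the standard input to HRF recovery.
#'
#' @param rec A [nirs_recording()] with two wavelengths.
#' @param dpf Differential pathlength factor (default 6 at both wavelengths).
#' @param lowpass_fc Optional low-pass cutoff in Hz applied to the dOD
#'   series with [lowpass_filter()] before conversion; `NULL` to skip.
#' @param ext Optional extinction table override.
#' @return A list with `time` (s), `pairs` (tibble from [channel_pairs()]),
#'   and `hbo2`, `hbr`: samples-x-pairs matrices in molar units.
#' @export
recording_to_conc <- function(rec, dpf = 6, lowpass_fc = NULL, ext = NULL) {
  if (length(rec$probe$wavelengths) != 2) {
    abort("recording_to_conc requires a two-wavelength recording")
  }
  pairs <- channel_pairs(rec)
  od <- intensity_to_od(rec$data)
  if (!is.null(lowpass_fc)) {
    od <- lowpass_filter(od, fs = sampling_rate(rec), fc = lowpass_fc)
  }
  wl_idx <- rec$measurements$wavelength_index
  hbo2 <- matrix(NA_real_, nrow(rec$data), nrow(pairs))
  hbr <- matrix(NA_real_, nrow(rec$data), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    ch <- pairs$channels[[p]]
    ch <- ch[order(wl_idx[ch])] # column order = wavelength order
    conc <- od_to_conc(od[, ch, drop = FALSE],
                       wavelengths = rec$probe$wavelengths,
                       separation = pairs$separation[p], dpf = dpf, ext = ext)
    hbo2[, p] <- conc$hbo2
    hbr[, p] <- conc$hbr
  }
  list(time = rec$time, pairs = pairs, hbo2 = hbo2, hbr = hbr)
}
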