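#' Simulation configuration
#'
#' Parameters of the resting-state recording simulator. Channel structure
#' mirrors the continuous-wave probes the toolkit targets: `n_ls_pairs`
#' long-separation (3 cm) and `n_ss_pairs` short-separation (1 cm)
#' source-detector pairs, each measured at 690 and 830 nm, sampled at `fs`.
#' The physiological components are multiplicative fluctuations around
#' `baseline_intensity`: cardiac pulsation (default 1.1 Hz), respiration
#' (0.25 Hz), Mayer waves (0.1 Hz), a 1/f-like drift, and white measurement
#' noise. Short-separation channels carry the shared systemic signal at
#' full weight; long-separation channels receive it scaled by
#' `systemic_coupling`. The default amplitudes yield channel SNRs of
#' roughly 28-42 dB. Cardiac phase is shared with the PPG and BP
#' auxiliaries; motion events (at `motion_rate` per minute) appear jointly
#' as intensity steps and accelerometer excursions.
#'
#' @param duration Recording length, s.
#' @param fs Sampling rate, Hz (default 50; must exceed twice the cardiac
#'   frequency).
#' @param n_ls_pairs,n_ss_pairs Long-/short-separation pair counts
#'   (defaults 26/2, the occipital-probe layout).
#' @param baseline_intensity Mean raw intensity, arbitrary units.
#' @param cardiac_freq,cardiac_amp Cardiac frequency (Hz) and relative
#'   amplitude.
#' @param resp_freq,resp_amp Respiration frequency (Hz) and relative
#'   amplitude.
#' @param mayer_freq,mayer_amp Mayer-wave frequency (Hz) and relative
#'   amplitude.
#' @param drift_amp Relative amplitude of the per-channel 1/f drift.
#' @param noise_sd Relative standard deviation of white measurement noise.
#' @param systemic_coupling Fraction of the shared systemic signal coupled
#'   into long-separation channels, in `[0, 1]`.
#' @param motion_rate Motion events per minute (default 0).
#' @param motion_amp Relative intensity excursion of a motion event.
#' @param aux Names of auxiliary channels to generate, a subset of
#'   AccelX/AccelY/AccelZ/PPG/BP/RESP.
#' @param seed Integer seed; the recording is a pure function of the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 300, fs = 50, n_ls_pairs = 26,
                       n_ss_pairs = 2, baseline_intensity = 1000,
                       cardiac_freq = 1.1, cardiac_amp = 0.010,
                       resp_freq = 0.25, resp_amp = 0.005,
                       mayer_freq = 0.1, mayer_amp = 0.008,
                       drift_amp = 0.010, noise_sd = 0.003,
                       systemic_coupling = 0.5, motion_rate = 0,
                       motion_amp = 0.2,
                       aux = c("AccelX", "AccelY", "AccelZ", "PPG", "BP",
                               "RESP"),
                       seed = 1) {
  amps <- c(cardiac_amp, resp_amp, mayer_amp, drift_amp, noise_sd,
            motion_amp)
  if (any(amps < 0)) abort("component amplitudes must be >= 0")
  if (fs <= 2 * cardiac_freq) {
    abort("fs must exceed twice the cardiac frequency")
  }
  if (systemic_coupling < 0 || systemic_coupling > 1) {
    abort("systemic_coupling must be in [0, 1]")
  }
  if (n_ss_pairs > n_ls_pairs) {
    abort("simulator layout requires n_ss_pairs <= n_ls_pairs")
  }
  bad_aux <- setdiff(aux, c("AccelX", "AccelY", "AccelZ", "PPG", "BP",
                            "RESP"))
  if (length(bad_aux) > 0) {
    abort(sprintf("unknown aux channel(s): %s",
                  paste(bad_aux, collapse = ", ")))
  }
  structure(as.list(environment())[c(
    "duration", "fs", "n_ls_pairs", "n_ss_pairs", "baseline_intensity",
    "cardiac_freq", "cardiac_amp", "resp_freq", "resp_amp", "mayer_freq",
    "mayer_amp", "drift_amp", "noise_sd", "systemic_coupling",
    "motion_rate", "motion_amp", "aux", "seed")],
    class = "sim_config")
}

#' Dataset presets
#'
#' Canned configurations reproducing the two probe layouts the toolkit
#' emulates: `"dataset1"` — 5 min, 26 long- + 2 short-separation pairs,
#' full auxiliary set (accelerometer, PPG, blood pressure, respiration);
#' `"dataset2"` — 10 min, 48 long- + 8 short-separation pairs,
#' accelerometer only.
#'
#' @param name `"dataset1"` or `"dataset2"`.
#' @param ... Overrides passed to [sim_config()] (e.g. `seed`, `duration`).
#' @return A [sim_config()].
#' @export
#' @examples
#' sim_preset("dataset1")$duration # 300 s
sim_preset <- function(name = c("dataset1", "dataset2"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    dataset1 = list(duration = 300, n_ls_pairs = 26, n_ss_pairs = 2,
                    aux = c("AccelX", "AccelY", "AccelZ", "PPG", "BP",
                            "RESP")),
    dataset2 = list(duration = 600, n_ls_pairs = 48, n_ss_pairs = 8,
                    aux = c("AccelX", "AccelY", "AccelZ"))
  )
  do.call(sim_config, modifyList(base, list(...)))
}

#' Simulate a resting-state multimodal recording
#'
#' Generates a [nirs_recording()] from a [sim_config()]: a synthetic probe
#' with the requested pair counts (long-separation detectors 3 cm from
#' their source, short-separation detectors 1 cm), intensity channels
#' carrying shared systemic physiology plus independent drift and noise,
#' and phase-locked auxiliary channels. The output is a deterministic
#' function of the configuration (including its seed), strictly positive,
#' and passes [validate_recording()].
#'
#' @param cfg A [sim_config()] or [sim_preset()].
#' @return A [nirs_recording()].
#' @export
simulate_resting <- function(cfg = sim_config()) {
  n <- round(cfg$duration * cfg$fs)
  if (n < 2) abort("duration too short for the sampling rate")
  time <- (seq_len(n) - 1) / cfg$fs

  probe <- sim_probe(cfg$n_ls_pairs, cfg$n_ss_pairs)
  n_pairs <- cfg$n_ls_pairs + cfg$n_ss_pairs
  # pair p -> source p for LS, source p for SS pair p; detectors: LS then SS
  pair_src <- c(seq_len(cfg$n_ls_pairs), seq_len(cfg$n_ss_pairs))
  pair_det <- c(seq_len(cfg$n_ls_pairs),
                cfg$n_ls_pairs + seq_len(cfg$n_ss_pairs))
  is_ss <- c(rep(FALSE, cfg$n_ls_pairs), rep(TRUE, cfg$n_ss_pairs))
  measurements <- tibble(
    source_index = rep(pair_src, each = 2),
    detector_index = rep(pair_det, each = 2),
    wavelength_index = rep(1:2, n_pairs),
    data_type_label = 0L
  )

  withr::with_seed(cfg$seed, {
    cardiac <- jittered_sine(n, cfg$fs, cfg$cardiac_freq)
    resp <- jittered_sine(n, cfg$fs, cfg$resp_freq)
    mayer <- jittered_sine(n, cfg$fs, cfg$mayer_freq)
    systemic <- cfg$cardiac_amp * cardiac + cfg$resp_amp * resp +
      cfg$mayer_amp * mayer

    n_events <- round(cfg$motion_rate * cfg$duration / 60)
    motion <- numeric(n)
    if (n_events > 0) {
      ev_t <- sort(runif(n_events, 1, max(1.001, cfg$duration - 2)))
      ev_sign <- sample(c(-1, 1), n_events, replace = TRUE)
      for (e in seq_len(n_events)) {
        idx <- which(time >= ev_t[e] & time < ev_t[e] + 0.5)
        motion[idx] <- motion[idx] + ev_sign[e] * cfg$motion_amp
      }
    }

    data <- matrix(NA_real_, n, 2 * n_pairs)
    for (p in seq_len(n_pairs)) {
      w_sys <- if (is_ss[p]) 1 else cfg$systemic_coupling
      for (wl in 1:2) {
        drift <- cumsum(rnorm(n))
        drift <- if (sd(drift) > 0) {
          (drift - mean(drift)) / sd(drift) * cfg$drift_amp
        } else numeric(n)
        rel <- w_sys * systemic + drift + rnorm(n, 0, cfg$noise_sd) + motion
        data[, 2 * (p - 1) + wl] <- cfg$baseline_intensity * (1 + rel)
      }
    }
    if (any(data <= 0)) {
      abort("component amplitudes drive intensity nonpositive; reduce them")
    }

    aux <- empty_aux()
    accel_noise <- function() 0.02 * rnorm(n)
    accel_motion <- 10 * motion # g-scale excursions mirroring the events
    for (nm in cfg$aux) {
      series <- switch(nm,
        AccelX = accel_noise() + accel_motion,
        AccelY = accel_noise() + accel_motion,
        AccelZ = 1 + accel_noise() + accel_motion,
        PPG = cardiac + 0.05 * rnorm(n),
        BP = 80 + 3 * cardiac + 5 * mayer + 0.5 * rnorm(n),
        RESP = resp + 0.05 * rnorm(n)
      )
      aux <- dplyr::bind_rows(aux, tibble(name = nm, time = list(time),
                                          series = list(series)))
    }
  })

  nirs_recording(data, time, measurements, probe, aux = aux,
                 meta = list(SubjectID = "sim"))
}

# phase-jittered unit sinusoid: slow random phase walk emulates heart-rate
# (and respiratory-rate) variability without changing the mean frequency
jittered_sine <- function(n, fs, freq, jitter = 0.3) {
  phase_walk <- cumsum(rnorm(n, 0, jitter / sqrt(fs)))
  sin(2 * pi * freq * (seq_len(n) - 1) / fs + phase_walk)
}

sim_probe <- function(n_ls_pairs, n_ss_pairs) {
  # sources on a 4 cm grid line; LS detector 3 cm along x from its source,
  # SS detector 1 cm along y from its source
  src <- cbind(4 * (seq_len(n_ls_pairs) - 1), 0, 0)
  det_ls <- cbind(4 * (seq_len(n_ls_pairs) - 1) + 3, 0, 0)
  det <- if (n_ss_pairs > 0) {
    rbind(det_ls, cbind(4 * (seq_len(n_ss_pairs) - 1), 1, 0))
  } else {
    det_ls
  }
  nirs_probe(wavelengths = c(690, 830), source_pos = src,
             detector_pos = det)
}
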