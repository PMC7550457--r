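# fixtures are built in code; nothing is read from disk

# a noise-free (constant-intensity) simulated recording
flat_recording <- function(duration = 60, n_ls_pairs = 4, n_ss_pairs = 1,
                           seed = 1, ...) {
  simulate_resting(sim_config(
    duration = duration, n_ls_pairs = n_ls_pairs, n_ss_pairs = n_ss_pairs,
    cardiac_amp = 0, resp_amp = 0, mayer_amp = 0, drift_amp = 0,
    noise_sd = 0, seed = seed, ...
  ))
}

# minimal hand-built recording: n_pairs long-separation pairs on a line,
# optional short-separation pair, channel data supplied per column
manual_recording <- function(data, n_ls_pairs, n_ss_pairs = 0, fs = 50) {
  probe <- nirs_probe(
    wavelengths = c(690, 830),
    source_pos = cbind(4 * (seq_len(n_ls_pairs) - 1), 0, 0),
    detector_pos = rbind(
      cbind(4 * (seq_len(n_ls_pairs) - 1) + 3, 0, 0),
      if (n_ss_pairs > 0) cbind(4 * (seq_len(n_ss_pairs) - 1), 1, 0)
    )
  )
  pair_src <- c(seq_len(n_ls_pairs), seq_len(n_ss_pairs))
  pair_det <- c(seq_len(n_ls_pairs), n_ls_pairs + seq_len(n_ss_pairs))
  measurements <- tibble::tibble(
    source_index = rep(pair_src, each = 2),
    detector_index = rep(pair_det, each = 2),
    wavelength_index = rep(1:2, n_ls_pairs + n_ss_pairs),
    data_type_label = 0L
  )
  stopifnot(ncol(data) == nrow(measurements))
  nirs_recording(data, (seq_len(nrow(data)) - 1) / fs, measurements, probe)
}

# alternating-sign series with exact sample sd and mean:
# mean + a*(+1,-1,...) over even n has sd a*sqrt(n/(n-1))
series_with_snr <- function(snr_db_target, n = 1000, mean = 100) {
  sd_target <- mean * 10^(-snr_db_target / 20)
  a <- sd_target * sqrt((n - 1) / n)
  mean + a * rep(c(1, -1), n / 2)
}

expect_recording_equal <- function(a, b) {
  expect_identical(a$data, b$data)
  expect_identical(a$time, b$time)
  expect_equal(as.data.frame(a$measurements), as.data.frame(b$measurements))
  expect_equal(as.data.frame(a$stim), as.data.frame(b$stim))
  expect_equal(a$aux$name, b$aux$name)
  expect_equal(a$aux$time, b$aux$time)
  expect_equal(a$aux$series, b$aux$series)
  expect_equal(a$probe$wavelengths, b$probe$wavelengths)
  expect_equal(a$probe$source_pos, b$probe$source_pos)
  expect_equal(a$probe$detector_pos, b$probe$detector_pos)
}
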