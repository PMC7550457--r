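test_that("the zero-phase low-pass has unit DC gain and no phase shift", {
  fs <- 50
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  expect_equal(lowpass_filter(rep(3.7, length(t)), fs), rep(3.7, length(t)),
               tolerance = 1e-6)

  x <- sin(2 * pi * 0.1 * t)
  y <- lowpass_filter(x, fs)
  # phase from the cross-spectrum at the stimulus frequency
  mid <- seq(500, length(t) - 500) # avoid filter edge transients
  phase <- acos(sum(x[mid] * y[mid]) /
                  sqrt(sum(x[mid]^2) * sum(y[mid]^2))) / (2 * pi)
  expect_lt(phase, 1e-4) # cycles

  z <- sin(2 * pi * 5 * t) # 10x the cutoff
  atten_db <- 20 * log10(max(abs(lowpass_filter(z, fs)[mid])) / 1)
  expect_lt(atten_db, -30)
  expect_error(lowpass_filter(x, fs, fc = 30), "Nyquist")
})

test_that("block averaging of a single epoch returns it baseline-subtracted", {
  rec <- flat_recording(duration = 40, n_ls_pairs = 2, n_ss_pairs = 1)
  aug0 <- augment_recording(rec, level = 100, seed = 1)
  conc <- recording_to_conc(aug0$recording)
  onset <- aug0$plan$windows$onset[1]
  est <- block_average(conc, onsets = onset, channels = 1)
  expect_identical(est$n_trials, 1L)
  expect_equal(est$estimate$hbo2[1], 0) # onset sample is the baseline
  fs <- sampling_rate(rec)
  i0 <- round(onset * fs) + 1
  direct <- conc$hbo2[i0:(i0 + length(est$estimate$time) - 1), 1]
  expect_equal(est$estimate$hbo2, direct - direct[1])
})

test_that("the GLM recovers a noise-free injection within 5% at the peak", {
  rec <- flat_recording(duration = 120, n_ls_pairs = 4, n_ss_pairs = 1)
  aug <- augment_recording(rec, level = 100, seed = 4)
  est <- recover_hrf(aug$recording, method = "glm", fc = NULL)
  sc <- score_estimate(est, 100)
  expect_true(all(abs(sc$peak_rel_error) < 0.05))
  # HbO2 positive-peaked, HbR negative-peaked
  expect_gt(max(est$estimate$hbo2), 0)
  expect_lt(min(est$estimate$hbr), 0)
})

test_that("block averaging and the GLM agree when nothing confounds them", {
  rec <- flat_recording(duration = 120, n_ls_pairs = 4, n_ss_pairs = 1)
  aug <- augment_recording(rec, level = 100, seed = 4)
  b <- recover_hrf(aug$recording, method = "block", fc = NULL)
  g <- recover_hrf(aug$recording, method = "glm", fc = NULL)
  expect_equal(max(g$estimate$hbo2), max(b$estimate$hbo2), tolerance = 0.02)
  expect_equal(min(g$estimate$hbr), min(b$estimate$hbr), tolerance = 0.02)
})

test_that("short-separation regression pays off under strong systemic noise", {
  cfg <- sim_config(duration = 300, n_ls_pairs = 6, n_ss_pairs = 2,
                    mayer_amp = 0.02, cardiac_amp = 0.01,
                    systemic_coupling = 0.9, drift_amp = 0.002,
                    noise_sd = 0.001, seed = 31)
  aug <- augment_recording(simulate_resting(cfg), level = 100, seed = 31)
  with_ss <- recover_hrf(aug$recording, method = "glm",
                         cfg = glm_config(ss_regressors = TRUE))
  without_ss <- recover_hrf(aug$recording, method = "glm",
                            cfg = glm_config(ss_regressors = FALSE))
  err <- function(est) abs(score_estimate(est, 100)$peak_rel_error[1])
  expect_lt(err(with_ss), err(without_ss))
})

test_that("an empty stimulus design is refused", {
  rec <- flat_recording(duration = 40, n_ls_pairs = 2, n_ss_pairs = 1)
  conc <- recording_to_conc(rec)
  expect_error(glm_fit(conc, onsets = numeric(0)), "empty design")
  expect_error(block_average(conc, onsets = numeric(0)), "onsets")
  expect_error(recover_hrf(rec), "no stimulus")
})

test_that("tidy and glance expose the estimate in broom shape", {
  rec <- flat_recording(duration = 60, n_ls_pairs = 4, n_ss_pairs = 1)
  aug <- augment_recording(rec, level = 100, seed = 2)
  est <- recover_hrf(aug$recording, method = "block", fc = NULL)
  td <- tidy(est)
  expect_true(all(c("time", "chromophore", "estimate") %in% names(td)))
  expect_identical(nrow(td), 2L * nrow(est$estimate))
  g <- glance(est)
  expect_identical(nrow(g), 1L)
  expect_equal(g$peak_hbo2_um, 1e6 * max(est$estimate$hbo2))
  expect_gt(g$peak_hbo2_um, 0)
  expect_lt(g$peak_hbr_um, 0)
  p <- autoplot(est)
  expect_s3_class(p, "ggplot")
})
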