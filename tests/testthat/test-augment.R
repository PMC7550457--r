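test_that("pruning keeps pairs whose both wavelengths clear the threshold", {
  n <- 1000
  # pair SNRs: A (40, 38), B (4, 30), C (12, 12) dB, plus one SS pair
  cols <- cbind(series_with_snr(40, n), series_with_snr(38, n),
                series_with_snr(4, n), series_with_snr(30, n),
                series_with_snr(12, n), series_with_snr(12, n),
                series_with_snr(35, n), series_with_snr(35, n))
  rec <- manual_recording(cols, n_ls_pairs = 3, n_ss_pairs = 1)
  kept <- prune_channels(rec, threshold = 5)
  expect_identical(kept$source_index, c(1L, 3L)) # A and C survive
  expect_identical(nrow(prune_channels(rec, threshold = -Inf)), 3L)
  # constant channels have infinite SNR and always survive
  flat <- manual_recording(matrix(1000, 100, 8), 3, 1)
  expect_identical(nrow(prune_channels(flat, threshold = 5)), 3L)
})

test_that("a recording with no long channels prunes to nothing, with warning", {
  probe <- nirs_probe(c(690, 830), rbind(c(0, 0, 0)), rbind(c(1, 0, 0)))
  m <- tibble::tibble(source_index = 1L, detector_index = 1L,
                      wavelength_index = 1:2, data_type_label = 0L)
  rec <- nirs_recording(matrix(1, 50, 2), (0:49) / 50, m, probe)
  expect_warning(kept <- prune_channels(rec), "no long-separation")
  expect_identical(nrow(kept), 0L)
})

test_that("window partitioning yields floor(duration / 20) trials", {
  rec300 <- flat_recording(duration = 300, n_ls_pairs = 2, n_ss_pairs = 0)
  expect_identical(nrow(plan_augmentation(rec300, seed = 1)$windows), 15L)
  rec600 <- flat_recording(duration = 600, n_ls_pairs = 2, n_ss_pairs = 0)
  expect_identical(nrow(plan_augmentation(rec600, seed = 1)$windows), 30L)
  # trailing partial window receives no trial
  rec219 <- flat_recording(duration = 219, n_ls_pairs = 2, n_ss_pairs = 0)
  expect_identical(nrow(plan_augmentation(rec219, seed = 1)$windows), 10L)
  expect_error(plan_augmentation(flat_recording(duration = 15,
                                                n_ls_pairs = 2), seed = 1),
               "shorter")
})

test_that("onsets stay inside the window's onset range", {
  rec <- flat_recording(duration = 200, n_ls_pairs = 4, n_ss_pairs = 1)
  for (seed in 1:5) {
    plan <- plan_augmentation(rec, seed = seed)
    rel <- plan$windows$onset - plan$windows$start
    expect_true(all(rel >= 0 & rel <= 3.5))
  }
})

test_that("the channel subset is half the pruned long-separation pool", {
  rec <- flat_recording(duration = 60, n_ls_pairs = 5, n_ss_pairs = 1)
  plan <- plan_augmentation(rec, seed = 2)
  expect_identical(nrow(plan$channels), 2L) # floor(0.5 * 5)
  pool <- prune_channels(rec)
  expect_true(all(paste(plan$channels$source_index,
                        plan$channels$detector_index) %in%
                    paste(pool$source_index, pool$detector_index)))
})

test_that("plans are reproducible from the seed and differ across seeds", {
  rec <- simulate_resting(sim_config(duration = 100, n_ls_pairs = 6,
                                     n_ss_pairs = 1, seed = 4))
  p1 <- plan_augmentation(rec, seed = 42)
  p2 <- plan_augmentation(rec, seed = 42)
  expect_equal(p1$windows, p2$windows)
  expect_equal(p1$channels, p2$channels)
  p3 <- plan_augmentation(rec, seed = 43)
  expect_false(isTRUE(all.equal(p1$windows$onset, p3$windows$onset)))
})

test_that("spillover configurations are rejected up front", {
  rec <- flat_recording(duration = 60, n_ls_pairs = 2)
  expect_error(plan_augmentation(rec, seed = 1, onset_range = c(0, 5)),
               "spillover")
  expect_silent(plan_augmentation(rec, seed = 1, onset_range = c(0, 3.5)))
})

test_that("level-0 injection is the identity on the data", {
  rec <- flat_recording(duration = 40, n_ls_pairs = 3, n_ss_pairs = 1)
  aug <- augment_recording(rec, level = 0, seed = 3)
  expect_identical(aug$recording$data, rec$data)
})

test_that("level-100 injection peaks at exactly +1% / -2% on a constant fixture", {
  rec <- flat_recording(duration = 60, n_ls_pairs = 4, n_ss_pairs = 1)
  aug <- augment_recording(rec, level = 100, seed = 2)
  cls <- classify_channels(rec)
  flagged <- which(aug$recording$measurements$data_type_label == 1L)
  rel <- (aug$recording$data[, flagged] - rec$data[, flagged]) /
    rec$data[, flagged]
  wl <- cls$wavelength_nm[flagged]
  expect_equal(max(rel[, wl == 690]), 0.01, tolerance = 1e-12)
  expect_equal(min(rel[, wl == 830]), -0.02, tolerance = 1e-12)
  expect_true(all(rel[, wl == 690] >= 0))
  expect_true(all(rel[, wl == 830] <= 0))
})

test_that("non-selected channels, aux, and probe are bit-identical", {
  rec <- simulate_resting(sim_config(duration = 60, n_ls_pairs = 4,
                                     n_ss_pairs = 1, seed = 6))
  aug <- augment_recording(rec, level = 100, seed = 9)
  untouched <- which(aug$recording$measurements$data_type_label == 0L)
  expect_identical(aug$recording$data[, untouched], rec$data[, untouched])
  expect_identical(aug$recording$aux, rec$aux)
  expect_identical(aug$recording$probe, rec$probe)
  expect_identical(rec$measurements$data_type_label,
                   rep(0L, ncol(rec$data))) # input not mutated
})

test_that("stim events and flags mirror the plan", {
  rec <- simulate_resting(sim_config(duration = 80, n_ls_pairs = 4,
                                     n_ss_pairs = 1, seed = 7))
  aug <- augment_recording(rec, level = 50, seed = 11)
  stim <- aug$recording$stim
  expect_identical(unique(stim$name), "HRF_50")
  expect_identical(nrow(stim), nrow(aug$plan$windows))
  expect_equal(stim$onset, aug$plan$windows$onset)
  expect_true(all(stim$duration == 16.5))
  flagged <- aug$recording$measurements[
    aug$recording$measurements$data_type_label == 1L, ]
  expect_setequal(paste(flagged$source_index, flagged$detector_index),
                  paste(aug$plan$channels$source_index,
                        aug$plan$channels$detector_index))
})

test_that("a plan naming channels absent from the recording is refused", {
  rec <- flat_recording(duration = 40, n_ls_pairs = 2, n_ss_pairs = 0)
  plan <- plan_augmentation(rec, seed = 1)
  plan$channels <- tibble::tibble(source_index = 99L, detector_index = 99L)
  expect_error(apply_plan(rec, plan), "99")
})

test_that("same seed gives byte-identical augmented files", {
  rec <- simulate_resting(sim_preset("dataset1", duration = 40, seed = 7))
  f1 <- withr::local_tempfile(fileext = ".snirf")
  f2 <- withr::local_tempfile(fileext = ".snirf")
  write_snirf(augment_recording(rec, 100, seed = 5)$recording, f1)
  write_snirf(augment_recording(rec, 100, seed = 5)$recording, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("plans round-trip through the JSON sidecar", {
  rec <- flat_recording(duration = 60, n_ls_pairs = 4, n_ss_pairs = 1)
  plan <- plan_augmentation(rec, level = 20, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_equal(back$windows$onset, plan$windows$onset)
  expect_equal(as.data.frame(back$channels), as.data.frame(plan$channels))
  expect_equal(back$level, 20)
})

test_that("noise-free injection is recoverable to within 1% relative RMS", {
  rec <- flat_recording(duration = 120, n_ls_pairs = 4, n_ss_pairs = 1)
  aug <- augment_recording(rec, level = 100, seed = 4)
  est <- recover_hrf(aug$recording, method = "block", fc = NULL)
  sc <- score_estimate(est, 100)
  expect_true(all(sc$rms_rel_error < 0.01))
})
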