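test_that("a recording survives the file round trip field by field", {
  rec <- simulate_resting(sim_preset("dataset1", duration = 12, seed = 11))
  rec$stim <- tibble::tibble(name = "HRF_100", onset = c(1, 5), duration = 2,
                             value = 1)
  path <- withr::local_tempfile(fileext = ".snirf")
  write_snirf(rec, path)
  back <- read_snirf(path)
  expect_recording_equal(back, rec)
})

test_that("column k pairs with measurement-list entry k on disk", {
  probe <- nirs_probe(
    wavelengths = c(690, 830),
    source_pos = cbind(0:3, 0, 0),
    detector_pos = cbind(seq(0.5, by = 0.5, length.out = 18), 1, 0)
  )
  m <- tibble::tibble(
    source_index = rep(1:4, each = 3)[1:12],
    detector_index = rep(1:6, 2),
    wavelength_index = rep(1:2, 6),
    data_type_label = 0L
  )
  m$source_index[10] <- 2L
  m$detector_index[10] <- 18L
  m$wavelength_index[10] <- 1L
  rec <- nirs_recording(matrix(runif(50 * 12) + 1, 50), (0:49) / 50, m, probe)
  path <- withr::local_tempfile(fileext = ".snirf")
  write_snirf(rec, path)
  entry <- read_snirf(path)$measurements[10, ]
  expect_identical(entry$source_index, 2L)
  expect_identical(entry$detector_index, 18L)
  expect_identical(entry$wavelength_index, 1L)
})

test_that("permuting channels before writing permutes the list identically", {
  rec <- simulate_resting(sim_config(duration = 5, n_ls_pairs = 3,
                                     n_ss_pairs = 1, seed = 4))
  perm <- rev(seq_len(ncol(rec$data)))
  rec2 <- rec
  rec2$data <- rec$data[, perm]
  rec2$measurements <- rec$measurements[perm, ]
  path <- withr::local_tempfile(fileext = ".snirf")
  write_snirf(rec2, path)
  back <- read_snirf(path)
  expect_identical(back$data, rec2$data)
  expect_equal(as.data.frame(back$measurements),
               as.data.frame(rec2$measurements), ignore_attr = TRUE)
})

test_that("mandatory groups are enforced and aux names are retrievable", {
  rec <- simulate_resting(sim_preset("dataset1", duration = 5, seed = 2))
  path <- withr::local_tempfile(fileext = ".snirf")
  write_snirf(rec, path)
  expect_identical(as.character(rhdf5::h5read(path, "/nirs/aux2/name")),
                   "AccelY")
  rhdf5::h5delete(path, "/nirs/probe")
  expect_error(read_snirf(path), "probe")
  expect_error(read_snirf(withr::local_tempfile(fileext = ".snirf")),
               "no such file")
})

test_that("a recording without stim writes a file with zero stim groups", {
  rec <- flat_recording(duration = 4, n_ls_pairs = 2, n_ss_pairs = 0)
  path <- withr::local_tempfile(fileext = ".snirf")
  write_snirf(rec, path)
  ls <- rhdf5::h5ls(path)
  expect_false(any(grepl("^stim", ls$name)))
  expect_identical(nrow(read_snirf(path)$stim), 0L)
})

test_that("dataTypeLabel on disk matches the plan's channel set", {
  rec <- simulate_resting(sim_config(duration = 40, n_ls_pairs = 4,
                                     n_ss_pairs = 1, seed = 9))
  aug <- augment_recording(rec, level = 100, seed = 5)
  path <- withr::local_tempfile(fileext = ".snirf")
  write_snirf(aug$recording, path)
  back <- read_snirf(path)
  flagged <- back$measurements[back$measurements$data_type_label == 1L, ]
  got <- unique(flagged[, c("source_index", "detector_index")])
  want <- aug$plan$channels[order(aug$plan$channels$source_index), ]
  expect_equal(as.data.frame(got[order(got$source_index), ]),
               as.data.frame(want), ignore_attr = TRUE)
  # all non-plan channels stay 0
  expect_identical(sum(back$measurements$data_type_label),
                   2L * nrow(aug$plan$channels))
})

test_that("validate_recording reports constructed violations and none else", {
  rec <- flat_recording(duration = 4, n_ls_pairs = 2, n_ss_pairs = 1)
  expect_identical(nrow(validate_recording(rec)), 0L)

  bad <- rec
  bad$measurements <- bad$measurements[-1, ]
  f <- validate_recording(bad)
  expect_true(any(f$rule == "length" & f$field == "measurements"))

  bad2 <- rec
  bad2$data[3, 2] <- -1
  f2 <- validate_recording(bad2)
  expect_true(any(f2$rule == "non-negative"))
  expect_match(f2$message[f2$rule == "non-negative"], "sample 3")

  bad3 <- rec
  bad3$stim <- tibble::tibble(name = "x", onset = c(2, 1), duration = 1,
                              value = 1)
  expect_true(any(validate_recording(bad3)$rule == "onset-order"))

  expect_error(write_snirf(bad2, withr::local_tempfile(fileext = ".snirf")),
               "validation")
})
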