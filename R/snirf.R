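#' Read a SNIRF v1.0 file
#'
#' Reads the continuous-wave subset of the Shared Near Infrared File Format
#' (SNIRF v1.0, an HDF5 container): `/nirs/data1` (intensity time series +
#' measurement list), `/nirs/probe`, and any `/nirs/stimK` and `/nirs/auxK`
#' groups. The k-th data column corresponds to measurement-list entry k.
#' Per-channel `dataTypeLabel` entries follow the ground-truth convention of
#' this toolkit: 1 for channels with a synthetic HRF added, 0 otherwise
#' (accepted as integer or string on disk). Missing optional fields (stim,
#' aux, dataTypeLabel, labels) yield empty or zero defaults.
#'
#' @param path Path to an existing `.snirf` file.
#' @return A [nirs_recording()].
#' @export
read_snirf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path))
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path, recursive = TRUE)
  groups <- file.path(ls$group, ls$name)
  for (mandatory in c("/nirs/data1", "/nirs/probe")) {
    if (!mandatory %in% groups) {
      abort(sprintf("not a SNIRF recording: missing mandatory group '%s'",
                    mandatory))
    }
  }

  data <- h5read_num(path, "/nirs/data1/dataTimeSeries")
  time <- as.double(h5read_num(path, "/nirs/data1/time"))
  if (length(time) > 2) {
    dt <- diff(time)
    if (max(abs(dt - mean(dt))) > 1e-9) {
      abort("sampling error: /nirs/data1/time is not uniform within 1e-9 s")
    }
  }

  ml_names <- ls$name[ls$group == "/nirs/data1" &
                        grepl("^measurementList[0-9]+$", ls$name)]
  ml_idx <- sort(as.integer(sub("measurementList", "", ml_names)))
  if (length(ml_idx) != ncol(data)) {
    abort(sprintf(
      "format error: %d measurementList entries for %d data columns",
      length(ml_idx), ncol(data)))
  }
  measurements <- purrr::map_dfr(ml_idx, function(k) {
    base <- sprintf("/nirs/data1/measurementList%d", k)
    tibble(
      source_index = as.integer(h5read_num(path, file.path(base, "sourceIndex"))),
      detector_index = as.integer(h5read_num(path, file.path(base, "detectorIndex"))),
      wavelength_index = as.integer(h5read_num(path, file.path(base, "wavelengthIndex"))),
      data_type_label = read_dtl(path, base)
    )
  })

  probe <- nirs_probe(
    wavelengths = as.double(h5read_num(path, "/nirs/probe/wavelengths")),
    source_pos = h5read_num(path, "/nirs/probe/sourcePos"),
    detector_pos = h5read_num(path, "/nirs/probe/detectorPos"),
    source_labels = h5read_opt(path, "/nirs/probe/sourceLabels", groups),
    detector_labels = h5read_opt(path, "/nirs/probe/detectorLabels", groups)
  )

  stim_names <- ls$name[ls$group == "/nirs" & grepl("^stim[0-9]+$", ls$name)]
  stim <- empty_stim()
  for (k in sort(as.integer(sub("stim", "", stim_names)))) {
    base <- sprintf("/nirs/stim%d", k)
    events <- h5read_num(path, file.path(base, "data"))
    if (is.null(dim(events))) events <- matrix(events, ncol = 3)
    stim <- dplyr::bind_rows(stim, tibble(
      name = as.character(rhdf5::h5read(path, file.path(base, "name"))),
      onset = events[, 1], duration = events[, 2], value = events[, 3]
    ))
  }

  aux_names <- ls$name[ls$group == "/nirs" & grepl("^aux[0-9]+$", ls$name)]
  aux <- empty_aux()
  for (k in sort(as.integer(sub("aux", "", aux_names)))) {
    base <- sprintf("/nirs/aux%d", k)
    aux <- dplyr::bind_rows(aux, tibble(
      name = as.character(rhdf5::h5read(path, file.path(base, "name"))),
      time = list(as.double(h5read_num(path, file.path(base, "time")))),
      series = list(as.double(h5read_num(path, file.path(base, "dataTimeSeries"))))
    ))
  }

  meta <- list()
  tag_rows <- ls$group == "/nirs/metaDataTags"
  for (tag in ls$name[tag_rows]) {
    meta[[tag]] <- as.vector(rhdf5::h5read(path, file.path("/nirs/metaDataTags", tag)))
  }

  nirs_recording(data, time, measurements, probe, stim, aux, meta)
}

h5read_num <- function(path, name) {
  x <- rhdf5::h5read(path, name)
  if (is.raw(x)) x <- as.integer(x)
  x
}

h5read_opt <- function(path, name, groups) {
  if (name %in% groups) as.character(rhdf5::h5read(path, name)) else NULL
}

read_dtl <- function(path, base) {
  name <- file.path(base, "dataTypeLabel")
  ok <- tryCatch({
    x <- rhdf5::h5read(path, name)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(0L)
  x <- rhdf5::h5read(path, name)
  as.integer(as.character(x)) # accepts "1"/"0" or numeric on disk
}

#' Write a SNIRF v1.0 file
#'
#' Serializes a [nirs_recording()] to the HDF5 layout read by
#' [read_snirf()]: `/nirs/data1/dataTimeSeries` + `time`, one
#' `measurementListK` group per channel (with the ground-truth
#' `dataTypeLabel` flag), one `/nirs/stimK` group per stimulus name with
#' `(onset, duration, value)` rows, one `/nirs/auxK` group per auxiliary
#' channel, and `/nirs/probe`. The recording is validated first; any
#' invariant violation aborts the write.
#'
#' @param rec A valid [nirs_recording()].
#' @param path Output path (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_snirf <- function(rec, path) {
  findings <- validate_recording(rec)
  if (nrow(findings) > 0) {
    abort(paste0("recording fails validation:\n",
                 paste(sprintf("- %s: %s", findings$field, findings$message),
                       collapse = "\n")))
  }
  if (file.exists(path)) file.remove(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  h5put(path, "/formatVersion", "1.0")
  rhdf5::h5createGroup(path, "/nirs")

  rhdf5::h5createGroup(path, "/nirs/metaDataTags")
  meta <- modifyList(
    list(SubjectID = "sim", MeasurementDate = "unknown",
         MeasurementTime = "unknown", LengthUnit = "cm", TimeUnit = "s",
         FrequencyUnit = "Hz"),
    rec$meta %||% list()
  )
  for (tag in names(meta)) {
    h5put(path, file.path("/nirs/metaDataTags", tag), meta[[tag]])
  }

  rhdf5::h5createGroup(path, "/nirs/data1")
  h5put(path, "/nirs/data1/dataTimeSeries", rec$data)
  h5put(path, "/nirs/data1/time", rec$time)
  for (k in seq_len(nrow(rec$measurements))) {
    base <- sprintf("/nirs/data1/measurementList%d", k)
    rhdf5::h5createGroup(path, base)
    m <- rec$measurements[k, ]
    h5put(path, file.path(base, "sourceIndex"), as.integer(m$source_index))
    h5put(path, file.path(base, "detectorIndex"), as.integer(m$detector_index))
    h5put(path, file.path(base, "wavelengthIndex"), as.integer(m$wavelength_index))
    h5put(path, file.path(base, "dataTypeLabel"), as.integer(m$data_type_label))
    h5put(path, file.path(base, "dataType"), 1L) # CW amplitude
  }

  stim_names <- unique(rec$stim$name)
  for (k in seq_along(stim_names)) {
    base <- sprintf("/nirs/stim%d", k)
    rhdf5::h5createGroup(path, base)
    ev <- rec$stim[rec$stim$name == stim_names[k], ]
    h5put(path, file.path(base, "name"), stim_names[k])
    h5put(path, file.path(base, "data"),
          cbind(ev$onset, ev$duration, ev$value))
  }

  for (k in seq_len(nrow(rec$aux))) {
    base <- sprintf("/nirs/aux%d", k)
    rhdf5::h5createGroup(path, base)
    h5put(path, file.path(base, "name"), rec$aux$name[k])
    h5put(path, file.path(base, "time"), rec$aux$time[[k]])
    h5put(path, file.path(base, "dataTimeSeries"), rec$aux$series[[k]])
  }

  rhdf5::h5createGroup(path, "/nirs/probe")
  h5put(path, "/nirs/probe/wavelengths", rec$probe$wavelengths)
  h5put(path, "/nirs/probe/sourcePos", rec$probe$source_pos)
  h5put(path, "/nirs/probe/detectorPos", rec$probe$detector_pos)
  h5put(path, "/nirs/probe/sourceLabels", rec$probe$source_labels)
  h5put(path, "/nirs/probe/detectorLabels", rec$probe$detector_labels)

  invisible(path)
}

h5put <- function(path, name, value) {
  rhdf5::h5write(value, path, name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a recording against its structural invariants
#'
#' Checks every `nirs_recording` invariant and returns findings rather than
#' raising: channel count vs measurement-list length, time-vector uniformity
#' (1e-9 s tolerance), non-negative intensities, measurement indices
#' resolving within the probe, `data_type_label` in \{0, 1\}, stimulus onsets
#' strictly increasing per channel with positive durations inside the
#' recording, and auxiliary time/series length agreement.
#'
#' @param rec A [nirs_recording()].
#' @return A tibble of findings with columns `field`, `rule`, `message`;
#'   zero rows iff the recording is well formed.
#' @export
validate_recording <- function(rec) {
  f <- list()
  note <- function(field, rule, message) {
    f[[length(f) + 1]] <<- tibble(field = field, rule = rule, message = message)
  }

  if (ncol(rec$data) != nrow(rec$measurements)) {
    note("measurements", "length",
         sprintf("data has %d columns but measurement list has %d entries",
                 ncol(rec$data), nrow(rec$measurements)))
  }
  if (nrow(rec$data) != length(rec$time)) {
    note("time", "length",
         sprintf("data has %d rows but time has %d samples",
                 nrow(rec$data), length(rec$time)))
  }
  if (length(rec$time) > 2) {
    dt <- diff(rec$time)
    if (max(abs(dt - mean(dt))) > 1e-9) {
      note("time", "uniform", "time vector not uniform within 1e-9 s")
    }
  }
  if (any(rec$data < 0)) {
    bad <- which(rec$data < 0, arr.ind = TRUE)[1, ]
    note("data", "non-negative",
         sprintf("negative intensity at sample %d, channel %d",
                 bad[1], bad[2]))
  }

  m <- rec$measurements
  if (nrow(m) > 0) {
    if (any(m$source_index < 1 | m$source_index > nrow(rec$probe$source_pos))) {
      note("measurements", "source-range",
           "source_index outside probe source list")
    }
    if (any(m$detector_index < 1 |
              m$detector_index > nrow(rec$probe$detector_pos))) {
      note("measurements", "detector-range",
           "detector_index outside probe detector list")
    }
    if (any(m$wavelength_index < 1 |
              m$wavelength_index > length(rec$probe$wavelengths))) {
      note("measurements", "wavelength-range",
           "wavelength_index outside probe wavelength list")
    }
    if (!all(m$data_type_label %in% c(0L, 1L))) {
      note("measurements", "label-domain", "data_type_label must be 0 or 1")
    }
  }

  if (length(rec$probe$wavelengths) > 1 &&
        is.unsorted(rec$probe$wavelengths, strictly = TRUE)) {
    note("probe", "wavelength-order", "wavelengths must be sorted ascending")
  }
  if (nrow(rec$probe$source_pos) < 1 || nrow(rec$probe$detector_pos) < 1) {
    note("probe", "non-empty", "probe needs at least one source and detector")
  }

  if (nrow(rec$stim) > 0) {
    t_end <- max(rec$time) + 1 / sampling_rate(rec)
    for (nm in unique(rec$stim$name)) {
      ev <- rec$stim[rec$stim$name == nm, ]
      if (is.unsorted(ev$onset, strictly = TRUE)) {
        note(sprintf("stim[%s]", nm), "onset-order",
             "onsets must be strictly increasing")
      }
      if (any(ev$duration <= 0)) {
        note(sprintf("stim[%s]", nm), "duration-positive",
             "durations must be > 0")
      }
      if (any(ev$onset + ev$duration > t_end + 1e-9)) {
        note(sprintf("stim[%s]", nm), "in-bounds",
             "onset + duration exceeds recording end")
      }
    }
  }

  if (nrow(rec$aux) > 0) {
    for (k in seq_len(nrow(rec$aux))) {
      tk <- rec$aux$time[[k]]
      if (length(tk) != length(rec$aux$series[[k]])) {
        note(sprintf("aux[%s]", rec$aux$name[k]), "length",
             "time and series lengths differ")
      }
      if (length(tk) > 1 && is.unsorted(tk, strictly = TRUE)) {
        note(sprintf("aux[%s]", rec$aux$name[k]), "time-order",
             "aux time must be strictly increasing")
      }
    }
  }

  if (length(f) == 0) {
    tibble(field = character(), rule = character(), message = character())
  } else {
    dplyr::bind_rows(f)
  }
}
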