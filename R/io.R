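# On-disk dialect: flat little-endian int16 sample file + JSON sidecar for
# recordings (Intan/Open-Ephys-like); delimited text with header for
# everything tabular. Samples are stored channel-interleaved
# (ch1[t1], ch2[t1], ..., chN[t1], ch1[t2], ...), counts = volts / volts_per_count.

#' Write a recording to a flat binary file plus JSON sidecar
#'
#' @param session a `recording_session`.
#' @param path base path; `<path>.bin` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_recording <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  counts <- round(session$samples / session$volts_per_count)
  if (max(abs(counts)) > 32767) {
    abort("Samples exceed int16 range at this volts_per_count.",
          class = "dlamr_io_error")
  }
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(counts), con, size = 2L, endian = "little")
  meta <- list(
    session_id = session$session_id,
    fs = session$fs,
    n_channels = nrow(session$samples),
    channel_depths_um = session$channel_depths_um,
    volts_per_count = session$volts_per_count
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from flat binary + JSON sidecar
#'
#' @param path base path as given to [write_recording()] (or the `.bin` path).
#' @return a `recording_session` with samples scaled to volts.
#' @export
read_recording <- function(path) {
  path <- sub("\\.(bin|json)$", "", path)
  bin_path <- paste0(path, ".bin")
  json_path <- paste0(path, ".json")
  if (!file.exists(json_path)) {
    abort(sprintf("Sidecar metadata '%s' not found.", json_path),
          class = "dlamr_format_error")
  }
  if (!file.exists(bin_path)) {
    abort(sprintf("Sample file '%s' not found.", bin_path),
          class = "dlamr_format_error")
  }
  meta <- tryCatch(jsonlite::read_json(json_path, simplifyVector = TRUE),
                   error = function(e) {
                     abort(sprintf("Malformed sidecar '%s': %s", json_path,
                                   conditionMessage(e)),
                           class = "dlamr_format_error")
                   })
  need <- c("fs", "n_channels", "channel_depths_um", "volts_per_count")
  if (!all(need %in% names(meta))) {
    abort("Sidecar is missing required fields.", class = "dlamr_format_error")
  }
  if (!is.numeric(meta$volts_per_count) || meta$volts_per_count <= 0) {
    abort("Sidecar volts_per_count must be positive.",
          class = "dlamr_validation_error")
  }
  n_bytes <- file.size(bin_path)
  n_vals <- n_bytes / 2L
  nch <- as.integer(meta$n_channels)
  if (n_vals %% nch != 0) {
    abort(sprintf("Sample count %d not divisible by %d channels: corrupt file.",
                  n_vals, nch),
          class = "dlamr_corrupt_file_error")
  }
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  counts <- readBin(con, "integer", n = n_vals, size = 2L,
                    signed = TRUE, endian = "little")
  samples <- matrix(counts * meta$volts_per_count, nrow = nch)
  recording_session(samples, fs = meta$fs,
                    channel_depths_um = meta$channel_depths_um,
                    volts_per_count = meta$volts_per_count,
                    session_id = meta$session_id %||% basename(path))
}

#' Read a stimulus schedule from delimited text
#'
#' Expects a blocks table (`block_id, condition, start_s, end_s`) and an
#' events table (`block_id, time_s`). Rows may be in any order; the schedule
#' is sorted and validated on construction.
#'
#' @param path path to the blocks CSV.
#' @param events_path path to the events CSV; defaults to `events.csv` next
#'   to `path` when that file exists.
#' @return a `stimulus_schedule`.
#' @export
read_schedule <- function(path, events_path = NULL) {
  blocks <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(events_path)) {
    cand <- file.path(dirname(path), "events.csv")
    if (file.exists(cand)) events_path <- cand
  }
  events <- NULL
  if (!is.null(events_path)) {
    events <- readr::read_csv(events_path, show_col_types = FALSE)
  }
  stimulus_schedule(blocks, events)
}

#' Write a stimulus schedule to delimited text
#'
#' @param schedule a `stimulus_schedule`.
#' @param dir output directory; `schedule.csv` and `events.csv` are written.
#' @return `dir`, invisibly.
#' @export
write_schedule <- function(schedule, dir) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(schedule$blocks, file.path(dir, "schedule.csv"))
  readr::write_csv(schedule$events, file.path(dir, "events.csv"))
  invisible(dir)
}

#' Write homogeneous records as a delimited text table
#'
#' Accepts a data frame, or a list of named lists that all share the same
#' field set (mixed field sets are a validation error). Column order is the
#' field order of the first record, so output is deterministic.
#'
#' @param records data frame or list of named lists.
#' @param path output path (CSV with header).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- as_tibble(records)
  } else if (is.list(records)) {
    if (!length(records)) {
      abort("Cannot infer columns from an empty record list; pass a data frame.",
            class = "dlamr_validation_error")
    }
    fields <- names(records[[1L]])
    ok <- vapply(records, function(r) identical(sort(names(r)), sort(fields)),
                 logical(1))
    if (!all(ok)) {
      abort("Records have mixed field sets.", class = "dlamr_validation_error")
    }
    df <- bind_rows(lapply(records, function(r) as_tibble(r[fields])))
  } else {
    abort("`records` must be a data frame or a list of named lists.",
          class = "dlamr_validation_error")
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a delimited text table written by [write_table()]
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read sorted units as spike + waveform tables
#'
#' `spikes.csv` holds `unit_id, time_s`; `waveforms.csv` holds
#' `unit_id, sample_idx, mV`. Depth and class, when present, ride along in
#' `units.csv`.
#'
#' @param units a `sorted_units` tibble.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_units <- function(units, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spikes <- tidyr::unnest(units[c("unit_id", "spike_times_s")],
                          cols = "spike_times_s")
  names(spikes) <- c("unit_id", "time_s")
  readr::write_csv(spikes, file.path(dir, "spikes.csv"))
  wf <- purrr::map2_dfr(units$unit_id, units$waveform, function(id, w) {
    tibble(unit_id = id, sample_idx = seq_along(w) - 1L, mV = w)
  })
  readr::write_csv(wf, file.path(dir, "waveforms.csv"))
  readr::write_csv(units[c("unit_id", "depth_um", "cls")],
                   file.path(dir, "units.csv"))
  invisible(dir)
}

#' @rdname write_units
#' @param waveform_fs template sampling rate in Hz.
#' @export
read_units <- function(dir, waveform_fs = 25000) {
  spikes <- readr::read_csv(file.path(dir, "spikes.csv"), show_col_types = FALSE)
  wf <- readr::read_csv(file.path(dir, "waveforms.csv"), show_col_types = FALSE)
  meta_path <- file.path(dir, "units.csv")
  ids <- sort(unique(c(spikes$unit_id, wf$unit_id)))
  st <- lapply(ids, function(id) spikes$time_s[spikes$unit_id == id])
  wv <- lapply(ids, function(id) {
    w <- wf[wf$unit_id == id, ]
    w$mV[order(w$sample_idx)]
  })
  depth <- rep(NA_real_, length(ids))
  cls <- rep(NA_character_, length(ids))
  if (file.exists(meta_path)) {
    meta <- readr::read_csv(meta_path, show_col_types = FALSE)
    m <- match(ids, meta$unit_id)
    depth <- meta$depth_um[m]
    cls <- as.character(meta$cls[m])
  }
  sorted_units(ids, st, wv, depth_um = depth, cls = cls,
               waveform_fs = waveform_fs)
}

#' Write / read ROI traces as a long table
#'
#' Long format with columns `roi_id, frame, F, F_neuropil`.
#'
#' @param traces a `roi_trace_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_traces <- function(traces, path) {
  stopifnot(inherits(traces, "roi_trace_set"))
  n_frames <- ncol(traces$F_roi)
  df <- tibble(
    roi_id = rep(traces$roi_id, each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, times = nrow(traces$F_roi)),
    F = as.vector(t(traces$F_roi)),
    F_neuropil = as.vector(t(traces$F_np))
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_roi_traces
#' @param frame_rate imaging frame rate in Hz.
#' @param schedule a `stimulus_schedule` for the imaging session.
#' @export
read_roi_traces <- function(path, frame_rate, schedule) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- unique(df$roi_id)
  df <- arrange(df, match(.data$roi_id, ids), .data$frame)
  n_frames <- sum(df$roi_id == ids[1L])
  F_roi <- matrix(df$F, nrow = length(ids), byrow = TRUE)
  F_np <- matrix(df$F_neuropil, nrow = length(ids), byrow = TRUE)
  roi_trace_set(F_roi, F_np, frame_rate, schedule, roi_id = ids)
}
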