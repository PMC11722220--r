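#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr arrange mutate filter select group_by summarise ungroup
#'   bind_rows left_join row_number n first last across all_of
#' @importFrom stats sd var median qf pf pt convolve rnorm rpois runif t.test
#' @importFrom utils head tail
NULL

# ---- RecordingSession -------------------------------------------------------

#' Multi-channel extracellular recording
#'
#' Container for a continuous laminar recording: a channels x time matrix of
#' voltages together with the sampling rate and the per-channel depth along
#' the probe. Depths follow the convention used throughout the package:
#' positive is superficial, negative is deep (micrometres).
#'
#' @param samples numeric matrix, channels x time, in volts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_depths_um numeric vector, one depth per channel, strictly
#'   monotone along the probe (uniform 20 um spacing for the laminar probes
#'   this package targets).
#' @param volts_per_count scale factor used when the session is serialized to
#'   integer counts on disk.
#' @param session_id identifier string.
#'
#' @return A `recording_session` object.
#' @export
recording_session <- function(samples, fs, channel_depths_um,
                              volts_per_count = 1.95e-7,
                              session_id = "session") {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number.", class = "dlamr_validation_error")
  }
  if (nrow(samples) < 1L) {
    abort("A recording needs at least one channel.", class = "dlamr_validation_error")
  }
  if (length(channel_depths_um) != nrow(samples)) {
    abort("`channel_depths_um` must have one entry per channel.",
          class = "dlamr_validation_error")
  }
  d <- diff(channel_depths_um)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    abort("Channel depths must be strictly monotone along the probe.",
          class = "dlamr_validation_error")
  }
  if (!is.numeric(volts_per_count) || length(volts_per_count) != 1L ||
      !is.finite(volts_per_count) || volts_per_count <= 0) {
    abort("`volts_per_count` must be a single positive number.",
          class = "dlamr_validation_error")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_depths_um = as.numeric(channel_depths_um),
         volts_per_count = volts_per_count,
         session_id = as.character(session_id)),
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session '%s': %d channels x %d samples @ %g Hz (%.1f s)>\n",
              x$session_id, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

# ---- StimulusSchedule -------------------------------------------------------

#' Stimulus schedule: condition blocks, reversal events, interblock gaps
#'
#' Blocks are contiguous stimulus presentations of one dichoptic condition
#' (`monocular`, `concordant`, `phase_offset`, `orthogonal`, or any other
#' label); reversal events are the phase-reversal times used for trial
#' alignment. Interblock intervals (gray screen) are derived as the gaps
#' between consecutive blocks, plus a leading gap before the first block when
#' it does not start at time zero; they are the baseline for all z-scoring
#' and dF/F in this package.
#'
#' @param blocks data frame with columns `block_id`, `condition`, `start_s`,
#'   `end_s` (seconds from session start).
#' @param events data frame with columns `block_id`, `time_s`, or `NULL` for
#'   an eventless schedule (downstream trial-aligned operations will refuse).
#'
#' @return A `stimulus_schedule` object with tibbles `blocks`, `events`,
#'   `interblock`.
#' @export
stimulus_schedule <- function(blocks, events = NULL) {
  blocks <- as_tibble(blocks)
  need <- c("block_id", "condition", "start_s", "end_s")
  if (!all(need %in% names(blocks))) {
    abort(paste0("`blocks` needs columns: ", paste(need, collapse = ", ")),
          class = "dlamr_validation_error")
  }
  blocks <- arrange(blocks[need], .data$start_s)
  if (any(blocks$end_s <= blocks$start_s)) {
    abort("Every block must end after it starts.", class = "dlamr_validation_error")
  }
  if (nrow(blocks) > 1L &&
      any(blocks$start_s[-1L] < blocks$end_s[-nrow(blocks)] - 1e-9)) {
    abort("Blocks overlap in time.", class = "dlamr_validation_error")
  }
  if (is.null(events)) {
    events <- tibble(block_id = integer(), time_s = numeric())
  }
  events <- as_tibble(events)
  if (!all(c("block_id", "time_s") %in% names(events))) {
    abort("`events` needs columns block_id, time_s.", class = "dlamr_validation_error")
  }
  events <- arrange(events[c("block_id", "time_s")], .data$time_s)
  if (nrow(events)) {
    idx <- match(events$block_id, blocks$block_id)
    if (anyNA(idx)) {
      abort("Event references a block_id absent from `blocks`.",
            class = "dlamr_validation_error")
    }
    inside <- events$time_s >= blocks$start_s[idx] - 1e-9 &
      events$time_s <= blocks$end_s[idx] + 1e-9
    if (!all(inside)) {
      abort("Reversal event lies outside its block.",
            class = "dlamr_validation_error")
    }
  }
  ib_start <- ib_end <- numeric(0)
  if (nrow(blocks)) {
    if (blocks$start_s[1L] > 1e-9) {
      ib_start <- 0
      ib_end <- blocks$start_s[1L]
    }
    if (nrow(blocks) > 1L) {
      gs <- blocks$end_s[-nrow(blocks)]
      ge <- blocks$start_s[-1L]
      keep <- ge - gs > 1e-9
      ib_start <- c(ib_start, gs[keep])
      ib_end <- c(ib_end, ge[keep])
    }
  }
  structure(
    list(blocks = blocks, events = events,
         interblock = tibble(start_s = ib_start, end_s = ib_end)),
    class = "stimulus_schedule"
  )
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule: %d blocks (%s), %d events, %d interblock intervals>\n",
              nrow(x$blocks), paste(unique(x$blocks$condition), collapse = ", "),
              nrow(x$events), nrow(x$interblock)))
  invisible(x)
}

#' Reversal events of one condition
#'
#' @param schedule a `stimulus_schedule`.
#' @param condition condition label.
#' @return numeric vector of event times (s), sorted.
#' @export
condition_events <- function(schedule, condition) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  ids <- schedule$blocks$block_id[schedule$blocks$condition == condition]
  if (!length(ids)) {
    abort(sprintf("No blocks with condition '%s' in schedule.", condition),
          class = "dlamr_validation_error")
  }
  ev <- schedule$events$time_s[schedule$events$block_id %in% ids]
  if (!length(ev)) {
    abort(sprintf("No reversal events for condition '%s'.", condition),
          class = "dlamr_validation_error")
  }
  sort(ev)
}

# ---- sorted units -----------------------------------------------------------

#' Sorted-unit table
#'
#' Builds the tidy unit table this package uses downstream of spike sorting
#' (sorting itself is consumed, not performed). One row per unit with
#' list-columns for spike times and the mean template.
#'
#' @param unit_id vector of unit identifiers.
#' @param spike_times_s list of numeric vectors (seconds, will be sorted).
#' @param waveform list of numeric vectors: mean template at `waveform_fs`,
#'   in mV.
#' @param depth_um signed depth relative to L4 (positive superficial), or NA.
#' @param cls optional class label (`"RS"`, `"FS"`), `NA` for unset.
#' @param waveform_fs template sampling rate in Hz.
#' @return tibble with class `sorted_units`.
#' @export
sorted_units <- function(unit_id, spike_times_s, waveform,
                         depth_um = NA_real_, cls = NA_character_,
                         waveform_fs = 25000) {
  spike_times_s <- lapply(spike_times_s, function(s) sort(as.numeric(s)))
  out <- tibble(
    unit_id = unit_id,
    spike_times_s = spike_times_s,
    waveform = lapply(waveform, as.numeric),
    depth_um = rep_len(as.numeric(depth_um), length(unit_id)),
    cls = rep_len(as.character(cls), length(unit_id))
  )
  attr(out, "waveform_fs") <- waveform_fs
  class(out) <- c("sorted_units", class(out))
  out
}

# ---- ROI traces -------------------------------------------------------------

#' ROI fluorescence trace set
#'
#' Per-ROI somatic fluorescence and surrounding-neuropil fluorescence from a
#' two-photon session, with the block structure needed for dF/F baselining.
#'
#' @param F_roi numeric matrix, ROIs x frames (arbitrary fluorescence units).
#' @param F_np numeric matrix, same shape: neuropil trace per ROI.
#' @param frame_rate imaging frame rate in Hz (~14.9 for the resonant system
#'   this emulates).
#' @param schedule a `stimulus_schedule` in seconds on the imaging clock.
#' @param roi_id optional ROI identifiers.
#' @return A `roi_trace_set` object.
#' @export
roi_trace_set <- function(F_roi, F_np, frame_rate, schedule, roi_id = NULL) {
  if (!is.matrix(F_roi)) F_roi <- matrix(F_roi, nrow = 1L)
  if (!is.matrix(F_np)) F_np <- matrix(F_np, nrow = 1L)
  if (!all(dim(F_roi) == dim(F_np))) {
    abort("F_roi and F_np must have identical dimensions.",
          class = "dlamr_validation_error")
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    abort("`frame_rate` must be positive.", class = "dlamr_validation_error")
  }
  stopifnot(inherits(schedule, "stimulus_schedule"))
  roi_id <- roi_id %||% paste0("roi", seq_len(nrow(F_roi)))
  structure(
    list(F_roi = F_roi, F_np = F_np, frame_rate = frame_rate,
         schedule = schedule, roi_id = roi_id),
    class = "roi_trace_set"
  )
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("<roi_trace_set: %d ROIs x %d frames @ %.2f Hz>\n",
              nrow(x$F_roi), ncol(x$F_roi), x$frame_rate))
  invisible(x)
}

# internal: sample indices covered by a set of [start_s, end_s) intervals
interval_indices <- function(intervals, fs, n) {
  idx <- integer(0)
  for (i in seq_len(nrow(intervals))) {
    a <- max(1L, floor(intervals$start_s[i] * fs) + 1L)
    b <- min(n, ceiling(intervals$end_s[i] * fs))
    if (b >= a) idx <- c(idx, a:b)
  }
  unique(idx)
}
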