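# Trial-aligned VEP extraction and component measurement. The VEP magnitude
# throughout is the peak-negative to peak-positive voltage of the
# baseline-normalized, trial-averaged, Gaussian-smoothed waveform.

#' Extract trial-aligned LFP segments for one condition
#'
#' One row per phase-reversal event of the requested condition, aligned at
#' the event time. Events whose trial window runs past the end of the
#' recording are dropped and the drop count is reported via a message.
#'
#' @param lfp an `lfp_trace`.
#' @param schedule a `stimulus_schedule`.
#' @param condition condition label to extract.
#' @param channel channel index (row of the LFP matrix).
#' @param T_trial_ms trial window length in ms post-reversal.
#' @return numeric matrix, trials x samples, with attributes `fs` and
#'   `condition`.
#' @export
extract_trials <- function(lfp, schedule, condition, channel,
                           T_trial_ms = 500) {
  stopifnot(inherits(lfp, "lfp_trace"))
  ev <- condition_events(schedule, condition)
  n_samp <- round(T_trial_ms / 1000 * lfp$fs)
  n <- ncol(lfp$samples)
  start_idx <- floor(ev * lfp$fs) + 1L
  ok <- start_idx + n_samp - 1L <= n & start_idx >= 1L
  dropped <- sum(!ok)
  if (dropped > 0L) {
    inform(sprintf("extract_trials: dropped %d of %d events too close to the recording end.",
                   dropped, length(ev)))
  }
  start_idx <- start_idx[ok]
  if (!length(start_idx)) {
    abort(sprintf("No usable trials for condition '%s'.", condition),
          class = "dlamr_validation_error")
  }
  x <- lfp$samples[channel, ]
  trials <- vapply(start_idx, function(s) x[s:(s + n_samp - 1L)],
                   numeric(n_samp))
  trials <- t(trials)
  attr(trials, "fs") <- lfp$fs
  attr(trials, "condition") <- condition
  trials
}

#' Normalize and smooth trials into a VEP waveform
#'
#' Per trial, the mean of the first 10 ms is subtracted (baseline
#' normalization); trials are then averaged and the average smoothed with a
#' 10-ms (FWHM) moving Gaussian, truncated at three standard deviations and
#' renormalized.
#'
#' @param trials trials x samples matrix from [extract_trials()].
#' @param fs sampling rate (taken from the matrix attribute when present).
#' @param baseline_ms baseline window length, default 10 ms.
#' @param smooth_fwhm_ms Gaussian smoothing width (FWHM) in ms.
#' @return a `vep_waveform`: list with `voltage` (V), `time_ms`, `n_trials`,
#'   `condition`.
#' @export
normalize_and_smooth <- function(trials, fs = attr(trials, "fs"),
                                 baseline_ms = 10, smooth_fwhm_ms = 10) {
  if (is.null(dim(trials))) trials <- matrix(trials, nrow = 1L)
  if (nrow(trials) < 1L) {
    abort("Need at least one trial.", class = "dlamr_validation_error")
  }
  nb <- round(baseline_ms / 1000 * fs)
  if (ncol(trials) < nb || nb < 1L) {
    abort("Trials shorter than the baseline window.",
          class = "dlamr_validation_error")
  }
  base <- rowMeans(trials[, seq_len(nb), drop = FALSE])
  avg <- colMeans(trials - base)
  sm <- smooth_gaussian(avg, smooth_fwhm_ms / 1000 * fs)
  structure(
    list(voltage = sm,
         time_ms = (seq_along(sm) - 1L) / fs * 1000,
         fs = fs,
         n_trials = nrow(trials),
         condition = attr(trials, "condition") %||% NA_character_),
    class = "vep_waveform"
  )
}

#' @export
print.vep_waveform <- function(x, ...) {
  cat(sprintf("<vep_waveform: %d ms, %d trials, condition %s>\n",
              round(max(x$time_ms)), x$n_trials, x$condition))
  invisible(x)
}

#' Measure VEP negative and positive components
#'
#' Negativity is the minimum voltage within the negativity search window;
#' positivity is the maximum within the positivity window constrained to
#' occur after the measured negativity (earliest latency on ties). Magnitude
#' is positivity minus negativity, the peak-to-peak measure used for all
#' VEP comparisons.
#'
#' @param waveform a `vep_waveform`.
#' @param neg_window_ms negativity search window, default 25-100 ms.
#' @param pos_window_ms positivity search window, default 60-250 ms.
#' @return one-row tibble: `negativity_V`, `negativity_latency_ms`,
#'   `positivity_V`, `positivity_latency_ms`, `magnitude_V`, `condition`.
#' @export
measure_components <- function(waveform, neg_window_ms = c(25, 100),
                               pos_window_ms = c(60, 250)) {
  stopifnot(inherits(waveform, "vep_waveform"))
  t_ms <- waveform$time_ms
  v <- waveform$voltage
  in_neg <- which(t_ms >= neg_window_ms[1L] & t_ms <= neg_window_ms[2L])
  if (!length(in_neg)) {
    abort("Negativity window is empty.", class = "dlamr_validation_error")
  }
  if (neg_window_ms[1L] >= pos_window_ms[2L]) {
    abort("Negativity window must precede the end of the positivity window.",
          class = "dlamr_validation_error")
  }
  i_neg <- in_neg[which.min(v[in_neg])]
  in_pos <- which(t_ms >= pos_window_ms[1L] & t_ms <= pos_window_ms[2L] &
                    seq_along(t_ms) > i_neg)
  if (!length(in_pos)) {
    abort("Positivity window is empty (no samples after the negativity).",
          class = "dlamr_validation_error")
  }
  i_pos <- in_pos[which.max(v[in_pos])]
  tibble(
    condition = waveform$condition,
    negativity_V = v[i_neg],
    negativity_latency_ms = t_ms[i_neg],
    positivity_V = v[i_pos],
    positivity_latency_ms = t_ms[i_pos],
    magnitude_V = v[i_pos] - v[i_neg]
  )
}

#' Normalize VEP magnitudes to a reference level
#'
#' Divides every magnitude by the magnitude at the reference level (e.g. the
#' 0 percent ipsilateral-contrast baseline), which therefore maps to 1.
#'
#' @param components tibble with columns `level` and `magnitude_V` (any
#'   extra columns are preserved).
#' @param reference_level value of `level` to normalize against.
#' @return the input tibble with an added `magnitude_norm` column.
#' @export
normalize_to_reference <- function(components, reference_level) {
  if (!all(c("level", "magnitude_V") %in% names(components))) {
    abort("`components` needs columns level, magnitude_V.",
          class = "dlamr_validation_error")
  }
  ref <- components$magnitude_V[components$level == reference_level]
  if (!length(ref)) {
    abort(sprintf("Reference level '%s' not present.", reference_level),
          class = "dlamr_validation_error")
  }
  ref <- ref[1L]
  if (ref == 0) {
    abort("Reference magnitude is zero; cannot normalize.",
          class = "dlamr_validation_error")
  }
  mutate(as_tibble(components), magnitude_norm = .data$magnitude_V / ref)
}

#' Plot a VEP waveform
#'
#' @param object a `vep_waveform`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot vep_waveform
#' @export
autoplot.vep_waveform <- function(object, ...) {
  df <- tibble(time_ms = object$time_ms, uV = object$voltage * 1e6)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uV)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from reversal (ms)", y = "VEP (µV)",
                  title = object$condition) +
    ggplot2::theme_minimal()
}
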