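# Single-unit analysis downstream of spike sorting: waveform-based RS/FS
# classification (trough-to-peak latency, 0.4 ms boundary), 1-ms-bin PSTHs,
# early (40-80 ms) and late (100-200 ms) window rates, interblock-referenced
# per-unit z-scores, and laminar assignment.

#' Trough-to-peak latency of a spike template
#'
#' Trough is the global minimum of the template (earliest sample on ties);
#' peak is the global maximum strictly after the trough.
#'
#' @param waveform numeric template (mV or any consistent unit).
#' @param fs template sampling rate in Hz, default 25 kHz.
#' @return latency in ms.
#' @export
trough_to_peak_ms <- function(waveform, fs = 25000) {
  i_trough <- which.min(waveform)
  if (i_trough >= length(waveform)) {
    abort("Template has no samples after its trough.",
          class = "dlamr_validation_error")
  }
  post <- waveform[(i_trough + 1L):length(waveform)]
  i_peak <- i_trough + which.max(post)
  (i_peak - i_trough) / fs * 1000
}

#' Classify a unit as regular- or fast-spiking
#'
#' Latencies below 0.4 ms are fast-spiking (putative PV+ interneurons),
#' above 0.4 ms regular-spiking (putative excitatory). A latency of exactly
#' 0.4 ms falls between the two stated clauses and is assigned RS with a
#' warning.
#'
#' @param latency_ms trough-to-peak latency in ms (>= 0).
#' @param threshold_ms class boundary, default 0.4 ms.
#' @return `"RS"` or `"FS"`.
#' @export
classify_unit <- function(latency_ms, threshold_ms = 0.4) {
  if (!is.finite(latency_ms) || latency_ms < 0) {
    abort("Latency must be nonnegative.", class = "dlamr_validation_error")
  }
  if (latency_ms < threshold_ms) return("FS")
  if (latency_ms == threshold_ms) {
    warn(sprintf("Trough-to-peak latency exactly %.3g ms: boundary case assigned RS.",
                 threshold_ms))
  }
  "RS"
}

#' Classify every unit in a table
#'
#' @param units a `sorted_units` tibble.
#' @param fs template sampling rate; defaults to the table's attribute.
#' @return the table with `cls` and `trough_to_peak_ms` filled.
#' @export
classify_units <- function(units, fs = attr(units, "waveform_fs") %||% 25000) {
  t2p <- vapply(units$waveform, trough_to_peak_ms, numeric(1), fs = fs)
  units$trough_to_peak_ms <- t2p
  units$cls <- vapply(t2p, classify_unit, character(1))
  units
}

#' Peri-stimulus time histogram of one unit
#'
#' Spikes are binned at 1 ms relative to each phase-reversal event of the
#' condition and counts are summed across trials; the rate in spikes/s is
#' count / (n_trials * bin width), which reduces to the "multiply by 2"
#' rule at 500 trials and 1 ms bins.
#'
#' @param spike_times_s sorted spike times in seconds.
#' @param schedule a `stimulus_schedule`.
#' @param condition condition label.
#' @param T_trial_ms trial window length, default 500 ms.
#' @param bin_ms bin width, default 1 ms.
#' @return a `psth`: `rate_hz` per bin, `time_ms` (bin left edges),
#'   `n_trials`, `bin_ms`, `condition`.
#' @export
compute_psth <- function(spike_times_s, schedule, condition,
                         T_trial_ms = 500, bin_ms = 1) {
  ev <- condition_events(schedule, condition)
  n_bins <- floor(T_trial_ms / bin_ms)
  counts <- numeric(n_bins)
  for (t0 in ev) {
    rel_ms <- (spike_times_s - t0) * 1000
    rel_ms <- rel_ms[rel_ms >= 0 & rel_ms < n_bins * bin_ms]
    if (length(rel_ms)) {
      b <- floor(rel_ms / bin_ms) + 1L
      counts <- counts + tabulate(b, nbins = n_bins)
    }
  }
  n_trials <- length(ev)
  structure(
    list(rate_hz = counts / (n_trials * bin_ms / 1000),
         time_ms = (seq_len(n_bins) - 1L) * bin_ms,
         n_trials = n_trials, bin_ms = bin_ms, condition = condition),
    class = "psth"
  )
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth: %d x %g ms bins, %d trials, condition %s>\n",
              length(x$rate_hz), x$bin_ms, x$n_trials, x$condition))
  invisible(x)
}

#' Early/late window firing rates from a PSTH
#'
#' Arithmetic means of the bin rates in the half-open windows
#' `[40, 80)` and `[100, 200)` ms post-reversal.
#'
#' @param psth a `psth`.
#' @param early_ms,late_ms window bounds in ms.
#' @return one-row tibble: `condition`, `early_rate_hz`, `late_rate_hz`.
#' @export
window_rates <- function(psth, early_ms = c(40, 80), late_ms = c(100, 200)) {
  stopifnot(inherits(psth, "psth"))
  if (max(psth$time_ms) + psth$bin_ms < late_ms[2L]) {
    abort("PSTH does not cover the late window.",
          class = "dlamr_validation_error")
  }
  ie <- psth$time_ms >= early_ms[1L] & psth$time_ms < early_ms[2L]
  il <- psth$time_ms >= late_ms[1L] & psth$time_ms < late_ms[2L]
  tibble(condition = psth$condition,
         early_rate_hz = mean(psth$rate_hz[ie]),
         late_rate_hz = mean(psth$rate_hz[il]))
}

#' Per-unit z-scored firing rate
#'
#' The unit's spike train is binned at 1 ms and smoothed with a 10-ms (FWHM)
#' Gaussian; the mean and SD of that rate over all interblock intervals give
#' the per-unit baseline. Units silent during the interblock intervals have
#' an undefined baseline and are flagged for exclusion rather than z-scored.
#'
#' @param spike_times_s spike times (s).
#' @param schedule a `stimulus_schedule`.
#' @param duration_s total duration to bin over; defaults to the schedule
#'   end.
#' @param smooth_fwhm_ms smoothing width, default 10 ms; `0` disables.
#' @return list: `z` (z-scored 1-kHz rate trace), `rate_hz`, `mean_hz`,
#'   `sd_hz`, `excluded` (TRUE when the interblock baseline is degenerate).
#' @export
zscore_unit <- function(spike_times_s, schedule, duration_s = NULL,
                        smooth_fwhm_ms = 10) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  duration_s <- duration_s %||% max(schedule$blocks$end_s,
                                    schedule$interblock$end_s)
  n <- ceiling(duration_s * 1000)
  counts <- tabulate(floor(spike_times_s * 1000) + 1L, nbins = n)
  rate <- counts * 1000                   # spikes/s in 1-ms bins
  if (smooth_fwhm_ms > 0) rate <- smooth_gaussian(rate, smooth_fwhm_ms)
  idx <- interval_indices(schedule$interblock, 1000, n)
  mu <- mean(rate[idx])
  sg <- sd(rate[idx])
  if (!is.finite(sg) || sg == 0) {
    warn("Unit silent (or constant) during interblock intervals; excluded from z-scored aggregates.")
    return(list(z = NULL, rate_hz = rate, mean_hz = mu, sd_hz = sg,
                excluded = TRUE))
  }
  list(z = (rate - mu) / sg, rate_hz = rate, mean_hz = mu, sd_hz = sg,
       excluded = FALSE)
}

#' Assign a unit to a cortical layer from its depth
#'
#' Uses the same laminar boundary table as the channel alignment.
#'
#' @param depth_um signed depth relative to the L4 sink (um, positive
#'   superficial).
#' @param alignment unused placeholder for API symmetry; the boundary table
#'   is fixed.
#' @return layer label: `"L2/3"`, `"L4"`, `"L5"`, `"L6"` or `"out"`.
#' @export
assign_unit_layer <- function(depth_um, alignment = NULL) {
  layer_of_depth(depth_um)
}

#' Per-unit, per-condition window statistics table
#'
#' Convenience wrapper running classification, PSTH, window rates and
#' z-scoring for every unit and condition: the tidy table behind the
#' RS/FS group comparisons.
#'
#' @param units a `sorted_units` tibble.
#' @param schedule a `stimulus_schedule`.
#' @param conditions condition labels, default the four dichoptic ones.
#' @param T_trial_ms trial window, default 500 ms.
#' @return tibble: `unit_id`, `cls`, `layer`, `condition`, `early_rate_hz`,
#'   `late_rate_hz`.
#' @export
unit_condition_stats <- function(units, schedule,
                                 conditions = c("monocular", "concordant",
                                                "phase_offset", "orthogonal"),
                                 T_trial_ms = 500) {
  units <- classify_units(units)
  n_u <- nrow(units)
  n_c <- length(conditions)
  early <- late <- matrix(NA_real_, n_u, n_c)
  for (i in seq_len(n_u)) {
    for (j in seq_len(n_c)) {
      p <- compute_psth(units$spike_times_s[[i]], schedule, conditions[j],
                        T_trial_ms = T_trial_ms)
      w <- window_rates(p)
      early[i, j] <- w$early_rate_hz
      late[i, j] <- w$late_rate_hz
    }
  }
  tibble(unit_id = rep(units$unit_id, each = n_c),
         cls = rep(units$cls, each = n_c),
         layer = rep(assign_unit_layer(units$depth_um), each = n_c),
         condition = rep(conditions, times = n_u),
         early_rate_hz = as.vector(t(early)),
         late_rate_hz = as.vector(t(late)))
}

#' Plot a PSTH
#'
#' @param object a `psth`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot psth
#' @export
autoplot.psth <- function(object, ...) {
  df <- tibble(time_ms = object$time_ms, rate_hz = object$rate_hz)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$rate_hz)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time from reversal (ms)", y = "Rate (spikes/s)",
                  title = object$condition) +
    ggplot2::theme_minimal()
}
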