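# Multiunit activity envelope (MUAe): a threshold-free population-spiking
# proxy. Chain: common median reference -> 60 Hz IIR notch (10-dB bandwidth)
# -> 500-5000 Hz third-order Butterworth band-pass -> full-wave rectification
# -> <250 Hz third-order Butterworth low-pass -> decimation to 1 kHz.
# Responses are expressed as z-scores against the concatenated interblock
# (gray screen) intervals.

#' Common median referencing of wide-band data
#'
#' Subtracts each channel's median, then the cross-channel median at every
#' time point. Rejects common-mode signal shared across the probe.
#'
#' @param x channels x time numeric matrix (or `recording_session`).
#' @return matrix of the same shape (or session with referenced samples).
#' @export
common_median_reference <- function(x) {
  session <- NULL
  if (inherits(x, "recording_session")) {
    session <- x
    x <- x$samples
  }
  if (!is.matrix(x) || nrow(x) < 2L) {
    abort("Common median referencing needs at least 2 channels.",
          class = "dlamr_validation_error")
  }
  med_ch <- apply(x, 1L, median)
  x <- x - med_ch
  med_t <- apply(x, 2L, median)
  x <- sweep(x, 2L, med_t)
  if (!is.null(session)) {
    session$samples <- x
    return(session)
  }
  x
}

# second-order notch biquad with a prescribed attenuation bandwidth:
# the gain is -ab_db dB at f0 +- bw_hz/2 and minimal at f0
design_notch <- function(f0, fs, bw_hz, ab_db) {
  w0 <- 2 * pi * f0 / fs
  gb <- 10^(-ab_db / 20)
  beta <- sqrt(1 - gb^2) / gb * tan(pi * bw_hz / fs)
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * gain * cos(w0), 2 * gain - 1)
  signal::Arma(b = b, a = a)
}

#' 60 Hz IIR notch with 10-dB bandwidth
#'
#' Second-order notch centered at 60 Hz whose attenuation reaches 10 dB over
#' the stated bandwidth; applied forward-backward.
#'
#' @param x channels x time matrix at `fs`.
#' @param fs sampling rate; the MUA chain runs at 25 kHz.
#' @param bw_hz bandwidth over which attenuation is >= `ab_db`, default 10 Hz.
#' @param ab_db attenuation defining the bandwidth, default 10 dB.
#' @return filtered matrix.
#' @export
notch60_iir <- function(x, fs = 25000, bw_hz = 10, ab_db = 10) {
  if (fs != 25000) {
    abort("notch60_iir expects the 25 kHz wide-band data.",
          class = "dlamr_validation_error")
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  flt <- design_notch(60, fs, bw_hz, ab_db)
  t(apply(x, 1L, function(ch) zp_filter(flt, ch, n_pad = 2000L)))
}

#' Compute the multiunit activity envelope
#'
#' @param x referenced, notched channels x time matrix at 25 kHz.
#' @param fs input sampling rate (must be 25 kHz).
#' @param target_fs output rate, 1000 Hz.
#' @return a `muae_trace`: `samples` (channels x time, nonnegative, volts),
#'   `fs = 1000`.
#' @export
compute_muae <- function(x, fs = 25000, target_fs = 1000) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (fs != 25000) {
    abort("compute_muae expects 25 kHz input.", class = "dlamr_validation_error")
  }
  if (fs %% target_fs != 0) {
    abort("Sampling ratio must be an integer.", class = "dlamr_validation_error")
  }
  bp <- signal::butter(3, c(500, 5000) / (fs / 2), type = "pass")
  lp <- signal::butter(3, 250 / (fs / 2), type = "low")
  r <- fs / target_fs
  env <- t(apply(x, 1L, function(ch) {
    s <- zp_filter(bp, ch, n_pad = 2000L)
    s <- abs(s)
    s <- zp_filter(lp, s, n_pad = 2000L)
    pmax(s[seq(1L, length(s), by = r)], 0)  # low-pass undershoot clamped
  }))
  structure(list(samples = env, fs = target_fs, z = NULL,
                 baseline_mean = NULL, baseline_sd = NULL),
            class = "muae_trace")
}

#' @export
print.muae_trace <- function(x, ...) {
  cat(sprintf("<muae_trace: %d channels x %d samples @ %g Hz%s>\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              if (is.null(x$z)) "" else ", z-scored"))
  invisible(x)
}

#' Z-score MUAe against the interblock intervals
#'
#' Mean and SD are computed per channel over all samples falling in
#' interblock (gray) intervals; the whole trace is standardized with them,
#' so `z = 1.96` marks the conventional significance bound for a visual
#' response.
#'
#' @param muae a `muae_trace`.
#' @param schedule a `stimulus_schedule` sharing the session clock.
#' @return the `muae_trace` with `z`, `baseline_mean`, `baseline_sd` filled.
#' @export
zscore_interblock <- function(muae, schedule) {
  stopifnot(inherits(muae, "muae_trace"), inherits(schedule, "stimulus_schedule"))
  if (nrow(schedule$interblock) < 1L) {
    abort("Schedule has no interblock intervals.", class = "dlamr_validation_error")
  }
  idx <- interval_indices(schedule$interblock, muae$fs, ncol(muae$samples))
  if (length(idx) < 2L) {
    abort("Interblock intervals cover fewer than 2 samples.",
          class = "dlamr_validation_error")
  }
  mu <- rowMeans(muae$samples[, idx, drop = FALSE])
  sg <- apply(muae$samples[, idx, drop = FALSE], 1L, sd)
  if (any(sg == 0)) {
    abort("Degenerate interblock baseline (zero SD).",
          class = "dlamr_validation_error")
  }
  muae$z <- (muae$samples - mu) / sg
  muae$baseline_mean <- mu
  muae$baseline_sd <- sg
  muae
}

# event-aligned average of a channels x time matrix; returns channels x n_samp
align_average <- function(x, fs, events_s, n_samp) {
  n <- ncol(x)
  starts <- floor(events_s * fs) + 1L
  starts <- starts[starts >= 1L & starts + n_samp - 1L <= n]
  if (!length(starts)) {
    abort("No usable events inside the trace.", class = "dlamr_validation_error")
  }
  acc <- matrix(0, nrow(x), n_samp)
  for (s in starts) acc <- acc + x[, s:(s + n_samp - 1L), drop = FALSE]
  acc / length(starts)
}

#' Trial-averaged z-scored MUAe per condition and layer
#'
#' Aligns the z-scored envelope to the phase-reversal events of every
#' condition, averages over trials, groups channels by layer, and forms
#' difference maps against the monocular condition.
#'
#' @param muae a z-scored `muae_trace` (see [zscore_interblock()]).
#' @param schedule a `stimulus_schedule`.
#' @param alignment a `laminar_alignment` for the probe.
#' @param conditions conditions required, default the four dichoptic ones.
#' @param reference condition the difference maps subtract, default
#'   `"monocular"`.
#' @param T_trial_ms trial window, default 500 ms.
#' @return a `condition_response`: tibbles `layer_mean` (condition, layer,
#'   time_ms, z) and `diff_vs_reference` (condition, layer, time_ms, dz),
#'   plus the per-condition channel x time averages in `z_aligned`.
#' @export
condition_response <- function(muae, schedule, alignment,
                               conditions = c("monocular", "concordant",
                                              "phase_offset", "orthogonal"),
                               reference = "monocular", T_trial_ms = 500) {
  stopifnot(inherits(muae, "muae_trace"))
  if (is.null(muae$z)) {
    abort("MUAe must be z-scored first (zscore_interblock).",
          class = "dlamr_validation_error")
  }
  present <- unique(schedule$blocks$condition)
  missing <- setdiff(conditions, present)
  if (length(missing)) {
    abort(sprintf("Condition(s) missing from schedule: %s",
                  paste(missing, collapse = ", ")),
          class = "dlamr_validation_error")
  }
  n_samp <- round(T_trial_ms / 1000 * muae$fs)
  z_aligned <- lapply(conditions, function(cond) {
    align_average(muae$z, muae$fs, condition_events(schedule, cond), n_samp)
  })
  names(z_aligned) <- conditions
  time_ms <- (seq_len(n_samp) - 1L) / muae$fs * 1000
  layers <- alignment$layer[seq_len(nrow(muae$z))]
  layer_mean <- purrr::map_dfr(conditions, function(cond) {
    purrr::map_dfr(setdiff(unique(layers), "out"), function(ly) {
      rows <- which(layers == ly)
      tibble(condition = cond, layer = ly, time_ms = time_ms,
             z = colMeans(z_aligned[[cond]][rows, , drop = FALSE]))
    })
  })
  diff_tbl <- layer_mean |>
    dplyr::left_join(
      layer_mean |> dplyr::filter(.data$condition == reference) |>
        dplyr::select("layer", "time_ms", z_ref = "z"),
      by = c("layer", "time_ms")
    ) |>
    mutate(dz = .data$z - .data$z_ref) |>
    dplyr::select("condition", "layer", "time_ms", "dz")
  structure(
    list(z_aligned = z_aligned, layer_mean = layer_mean,
         diff_vs_reference = diff_tbl, reference = reference,
         fs = muae$fs, layers = layers, time_ms = time_ms),
    class = "condition_response"
  )
}

#' Early/late window means of the condition-aligned MUAe
#'
#' Mean z in the early (40-80 ms) and late (100-200 ms) windows per
#' condition, collapsed across all in-cortex channels (layers other than
#' `"out"`). Windows are half-open `[lo, hi)`.
#'
#' @param response a `condition_response`.
#' @param early_ms,late_ms window bounds in ms.
#' @return tibble: `condition`, `early`, `late`.
#' @export
window_means <- function(response, early_ms = c(40, 80),
                         late_ms = c(100, 200)) {
  stopifnot(inherits(response, "condition_response"))
  t_ms <- response$time_ms
  ie <- which(t_ms >= early_ms[1L] & t_ms < early_ms[2L])
  il <- which(t_ms >= late_ms[1L] & t_ms < late_ms[2L])
  if (!length(ie) || !length(il)) {
    abort("Requested window lies outside the trial.",
          class = "dlamr_validation_error")
  }
  rows <- which(response$layers != "out")
  if (!length(rows)) rows <- seq_along(response$layers)
  purrr::map_dfr(names(response$z_aligned), function(cond) {
    za <- response$z_aligned[[cond]][rows, , drop = FALSE]
    tibble(condition = cond,
           early = mean(za[, ie]),
           late = mean(za[, il]))
  })
}

#' Plot layer-resolved condition responses
#'
#' @param object a `condition_response`.
#' @param ... unused.
#' @return a ggplot of z(t) per condition, faceted by layer.
#' @method autoplot condition_response
#' @export
autoplot.condition_response <- function(object, ...) {
  ggplot2::ggplot(object$layer_mean,
                  ggplot2::aes(.data$time_ms, .data$z,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::geom_hline(yintercept = 1.96, linetype = "dashed") +
    ggplot2::labs(x = "Time from reversal (ms)", y = "MUAe (z)") +
    ggplot2::theme_minimal()
}
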