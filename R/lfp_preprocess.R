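# LFP conditioning chain: DC removal -> downsample to 1 kHz -> 1-300 Hz
# third-order Butterworth -> local linear detrend (0.5 s window, 0.1 s step)
# -> 58-62 Hz third-order Butterworth notch. All IIR filters are applied
# forward-backward (zero phase) with reflect padding so evoked-component
# latencies are preserved.

# zero-phase IIR with reflect padding (pad length = n_pad samples each side)
zp_filter <- function(filt, x, n_pad = NULL) {
  n <- length(x)
  if (is.null(n_pad)) n_pad <- min(n - 1L, 3L * 100L)
  n_pad <- min(n_pad, n - 1L)
  if (n_pad > 0L) {
    xe <- c(2 * x[1L] - x[(n_pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - n_pad)])
  } else {
    xe <- x
  }
  y <- signal::filtfilt(filt, xe)
  if (n_pad > 0L) y <- y[(n_pad + 1L):(n_pad + n)]
  y
}

# Gaussian smoothing kernel parameterized by FWHM, truncated at +-3 sigma and
# renormalized to unit sum.
gaussian_kernel <- function(fwhm_samples) {
  sigma <- fwhm_samples / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

# centered moving-average style convolution with reflect padding
smooth_gaussian <- function(x, fwhm_samples) {
  k <- gaussian_kernel(fwhm_samples)
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  p <- min(half, n - 1L)
  xe <- c(x[(p + 1L):2L], x, x[(n - 1L):(n - p)])
  y <- stats::filter(xe, k, sides = 2L)
  as.numeric(y[(p + 1L):(p + n)])
}

as_lfp_trace <- function(samples, fs, channel_depths_um, provenance = list()) {
  structure(list(samples = samples, fs = fs,
                 channel_depths_um = channel_depths_um,
                 provenance = provenance),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  steps <- vapply(x$provenance, `[[`, character(1), "step")
  cat(sprintf("<lfp_trace: %d channels x %d samples @ %g Hz; steps: %s>\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              if (length(steps)) paste(steps, collapse = " -> ") else "(raw)"))
  invisible(x)
}

record_step <- function(trace, step, params = list()) {
  applied <- vapply(trace$provenance, `[[`, character(1), "step")
  if (step %in% applied) {
    abort(sprintf("Step '%s' already applied to this trace.", step),
          class = "dlamr_validation_error")
  }
  trace$provenance <- c(trace$provenance, list(list(step = step, params = params)))
  trace
}

#' Subtract the per-channel mean (DC offset)
#'
#' @param trace an `lfp_trace` (or `recording_session`, which is promoted).
#' @return an `lfp_trace` with zero-mean channels.
#' @export
remove_dc <- function(trace) {
  trace <- ensure_lfp(trace)
  if (ncol(trace$samples) == 0L) {
    abort("Empty trace.", class = "dlamr_validation_error")
  }
  trace$samples <- trace$samples - rowMeans(trace$samples)
  record_step(trace, "remove_dc")
}

ensure_lfp <- function(x) {
  if (inherits(x, "lfp_trace")) return(x)
  if (inherits(x, "recording_session")) {
    return(as_lfp_trace(x$samples, x$fs, x$channel_depths_um))
  }
  abort("Expected an lfp_trace or recording_session.",
        class = "dlamr_validation_error")
}

#' Anti-aliased downsampling to 1 kHz
#'
#' Applies a zero-phase order-4 Butterworth low-pass at 0.4 x target rate
#' (8th-order magnitude response after the forward-backward pass), then takes
#' every `fs/1000`-th sample. The input rate must be an integer multiple of
#' 1000 Hz; fractional resampling is out of scope.
#'
#' @param trace an `lfp_trace`.
#' @param target_fs target rate, 1000 Hz.
#' @return an `lfp_trace` at `target_fs`.
#' @export
downsample_to_1khz <- function(trace, target_fs = 1000) {
  trace <- ensure_lfp(trace)
  if (trace$fs < target_fs || trace$fs %% target_fs != 0) {
    abort(sprintf("fs = %g is not an integer multiple of %g Hz.",
                  trace$fs, target_fs),
          class = "dlamr_validation_error")
  }
  r <- trace$fs / target_fs
  if (r > 1) {
    bf <- signal::butter(4, 0.4 * target_fs / (trace$fs / 2), type = "low")
    trace$samples <- t(apply(trace$samples, 1L, function(x) zp_filter(bf, x)))
    keep <- seq(1L, ncol(trace$samples), by = r)
    trace$samples <- trace$samples[, keep, drop = FALSE]
  }
  trace$fs <- target_fs
  record_step(trace, "downsample_to_1khz", list(target_fs = target_fs))
}

#' Third-order 1-300 Hz Butterworth band-pass (zero phase)
#'
#' @param trace an `lfp_trace` at 1000 Hz.
#' @return filtered `lfp_trace`.
#' @export
bandpass_1_300 <- function(trace) {
  trace <- ensure_lfp(trace)
  if (trace$fs != 1000) {
    abort("bandpass_1_300 expects fs = 1000 Hz (run downsample first).",
          class = "dlamr_validation_error")
  }
  bf <- signal::butter(3, c(1, 300) / 500, type = "pass")
  trace$samples <- t(apply(trace$samples, 1L, function(x) zp_filter(bf, x)))
  record_step(trace, "bandpass_1_300")
}

# least-squares line over overlapping windows, overlap-averaged
local_trend <- function(x, win_n, step_n) {
  n <- length(x)
  acc <- numeric(n)
  wt <- numeric(n)
  starts <- unique(c(seq(1L, max(1L, n - win_n + 1L), by = step_n),
                     max(1L, n - win_n + 1L)))
  tt <- seq_len(win_n)
  tc <- tt - mean(tt)
  den <- sum(tc^2)
  for (s in starts) {
    idx <- s:(s + win_n - 1L)
    y <- x[idx]
    b <- sum(tc * y) / den
    fit <- mean(y) + b * tc
    acc[idx] <- acc[idx] + fit
    wt[idx] <- wt[idx] + 1
  }
  acc / wt
}

#' Local linear detrend (sliding-window piecewise line removal)
#'
#' Fits a least-squares line in each 0.5 s window sliding by 0.1 s, averages
#' the overlapping fits into a trend estimate and subtracts it. The trace is
#' padded by one window length with the linear extrapolation of the first
#' and last window fits, so edges see full windows without reflection
#' artifacts (exact for trends up to linear, low-variance for noise).
#'
#' @param trace an `lfp_trace`.
#' @param window_s window length in seconds.
#' @param step_s slide step in seconds; must not exceed `window_s`.
#' @return detrended `lfp_trace`.
#' @export
local_detrend <- function(trace, window_s = 0.5, step_s = 0.1) {
  trace <- ensure_lfp(trace)
  if (window_s < step_s) {
    abort("`window_s` must be >= `step_s`.", class = "dlamr_validation_error")
  }
  win_n <- round(window_s * trace$fs)
  step_n <- max(1L, round(step_s * trace$fs))
  n <- ncol(trace$samples)
  if (n < win_n) {
    abort("Trace shorter than the detrend window.",
          class = "dlamr_validation_error")
  }
  p <- min(win_n, n - 1L)
  fit_line <- function(y, at) {
    b <- stats::coef(stats::lm.fit(cbind(1, seq_along(y)), y))
    b[1L] + b[2L] * at
  }
  trace$samples <- t(apply(trace$samples, 1L, function(x) {
    head_pad <- fit_line(x[1:win_n], seq(-p + 1L, 0L))
    tail_pad <- fit_line(x[(n - win_n + 1L):n], win_n + seq_len(p))
    xe <- c(head_pad, x, tail_pad)
    tr <- local_trend(xe, win_n, step_n)
    (xe - tr)[(p + 1L):(p + n)]
  }))
  record_step(trace, "local_detrend",
              list(window_s = window_s, step_s = step_s))
}

#' Third-order 58-62 Hz Butterworth notch (zero phase)
#'
#' Removes mains interference from the conditioned LFP.
#'
#' @param trace an `lfp_trace` at 1000 Hz.
#' @return filtered `lfp_trace`.
#' @export
notch_58_62 <- function(trace) {
  trace <- ensure_lfp(trace)
  if (trace$fs != 1000) {
    abort("notch_58_62 expects fs = 1000 Hz.", class = "dlamr_validation_error")
  }
  bf <- signal::butter(3, c(58, 62) / 500, type = "stop")
  trace$samples <- t(apply(trace$samples, 1L, function(x) zp_filter(bf, x)))
  record_step(trace, "notch_58_62")
}

#' Full LFP conditioning chain
#'
#' Applies, in order: DC removal, anti-aliased downsampling to 1 kHz,
#' 1-300 Hz band-pass, local detrend, 58-62 Hz notch. Each step is recorded
#' in the trace's provenance with its parameters, so the chain can be
#' replayed bit-identically with [replay_lfp()].
#'
#' @param session a `recording_session`.
#' @param detrend_window_s,detrend_step_s local-detrend parameters.
#' @return an `lfp_trace` at 1000 Hz.
#' @export
preprocess_lfp <- function(session, detrend_window_s = 0.5,
                           detrend_step_s = 0.1) {
  trace <- ensure_lfp(session)
  stages <- list(
    remove_dc = function(tr) remove_dc(tr),
    downsample_to_1khz = function(tr) downsample_to_1khz(tr),
    bandpass_1_300 = function(tr) bandpass_1_300(tr),
    local_detrend = function(tr) local_detrend(tr, detrend_window_s,
                                               detrend_step_s),
    notch_58_62 = function(tr) notch_58_62(tr)
  )
  for (nm in names(stages)) {
    trace <- tryCatch(stages[[nm]](trace), error = function(e) {
      abort(sprintf("LFP preprocessing failed at stage '%s': %s",
                    nm, conditionMessage(e)),
            class = "dlamr_stage_error")
    })
  }
  trace
}

#' Replay a recorded preprocessing provenance
#'
#' @param session the original `recording_session`.
#' @param provenance a provenance list from a previous `lfp_trace`.
#' @return an `lfp_trace`; bit-identical to the original run.
#' @export
replay_lfp <- function(session, provenance) {
  trace <- ensure_lfp(session)
  for (st in provenance) {
    trace <- switch(
      st$step,
      remove_dc = remove_dc(trace),
      downsample_to_1khz = downsample_to_1khz(trace),
      bandpass_1_300 = bandpass_1_300(trace),
      local_detrend = local_detrend(trace, st$params$window_s, st$params$step_s),
      notch_58_62 = notch_58_62(trace),
      abort(sprintf("Unknown step '%s' in provenance.", st$step),
            class = "dlamr_validation_error")
    )
  }
  trace
}
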