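# Current-source density from trial-averaged laminar LFP. Channels are
# assumed ordered superficial -> deep with uniform spacing. The CSD here is
# the (sign-flipped) second spatial difference of the temporally and
# spatially smoothed potential, so inward current sinks are negative.

hamming5 <- c(0.08, 0.54, 1.00, 0.54, 0.08)

#' Compute a CSD map from trial-averaged laminar LFP
#'
#' Each channel is first smoothed in time with a 20-ms (FWHM) Gaussian, the
#' depth profile is smoothed with a normalized five-point Hamming window, and
#' the central second spatial difference is taken and scaled by -1/h^2 so
#' sinks are negative. The composed spatial kernel has half-width 3, so three
#' channels are dropped at each probe end: no values are extrapolated.
#'
#' @param avg_lfp channels x time matrix of trial-averaged LFP (V), ordered
#'   superficial to deep.
#' @param h_um electrode spacing in micrometres (uniform).
#' @param fs sampling rate of the time axis in Hz.
#' @param smooth_fwhm_ms temporal Gaussian FWHM, default 20 ms.
#' @param t_start_ms time of the first column relative to the reversal
#'   (negative when the trial average includes a pre-reversal baseline
#'   stretch, which sink detection needs for stable baseline statistics).
#' @return a `csd_map`: `csd` (interior channels x time, V/mm^2 up to the
#'   smoothing), `channel_index` (rows of the input each CSD row refers to),
#'   `h_um`, `time_ms`.
#' @export
compute_csd <- function(avg_lfp, h_um, fs = 1000, smooth_fwhm_ms = 20,
                        t_start_ms = 0) {
  if (!is.matrix(avg_lfp) || nrow(avg_lfp) < 5L) {
    abort("CSD needs at least 5 channels.", class = "dlamr_validation_error")
  }
  if (length(h_um) != 1L || h_um <= 0) {
    abort("Electrode spacing must be a single positive number (uniform).",
          class = "dlamr_validation_error")
  }
  sm <- t(apply(avg_lfp, 1L, smooth_gaussian,
                fwhm_samples = smooth_fwhm_ms / 1000 * fs))
  w <- hamming5 / sum(hamming5)
  n <- nrow(sm)
  # spatial Hamming smoothing: valid only where the full kernel fits
  sp <- vapply(3:(n - 2L), function(i) {
    colSums(sm[(i - 2L):(i + 2L), , drop = FALSE] * w)
  }, numeric(ncol(sm)))
  sp <- t(sp)                           # (n-4) x time, rows map to 3..n-2
  m <- nrow(sp)
  if (m < 3L) {
    abort("Too few channels after spatial smoothing.",
          class = "dlamr_validation_error")
  }
  h_mm <- h_um / 1000
  csd <- -(sp[1:(m - 2L), , drop = FALSE] -
             2 * sp[2:(m - 1L), , drop = FALSE] +
             sp[3:m, , drop = FALSE]) / h_mm^2
  structure(
    list(csd = csd,
         channel_index = 4:(n - 3L),
         h_um = h_um,
         fs = fs,
         time_ms = t_start_ms + (seq_len(ncol(csd)) - 1L) / fs * 1000),
    class = "csd_map"
  )
}

#' @export
print.csd_map <- function(x, ...) {
  cat(sprintf("<csd_map: %d interior channels (%d..%d) x %d samples, h = %g um>\n",
              nrow(x$csd), min(x$channel_index), max(x$channel_index),
              ncol(x$csd), x$h_um))
  invisible(x)
}

#' Locate the layer-4 sink channel in a CSD map
#'
#' Per channel, a baseline mean and SD are computed over the baseline window
#' (by default a 250 ms pre-reversal stretch, so the SD is estimated from
#' enough effectively independent samples of the smoothed CSD);
#' a sink crossing is the first time in the search window the CSD drops below
#' mean - k*SD, and a source crossing the first time it exceeds mean + k*SD.
#' Candidates are channels with a sustained sink crossing, restricted to
#' those lying deeper than some channel with a source crossing. Among the
#' candidates whose (interpolated) crossing time falls within `tie_ms` of
#' the earliest crossing, the one with the deepest trough (most negative
#' CSD) wins: the earliest, deepest sink immediately below the superficial
#' source.
#'
#' @param csd a `csd_map` (rows ordered superficial to deep).
#' @param baseline_window_ms window (ms, on the CSD time axis) for the per-
#'   channel baseline statistics; default -250-0 ms, i.e. the quiet stretch
#'   before the reversal (build the CSD with a negative `t_start_ms`). For a
#'   map starting at 0 use e.g. `c(0, 20)`, before the evoked response.
#' @param search_window_ms window in which crossings are sought, default
#'   20-120 ms.
#' @param k threshold in baseline SDs, default 2.
#' @param min_duration_ms a crossing only counts when the CSD stays beyond
#'   the threshold for at least this long (default 5 ms), so single-sample
#'   noise excursions do not qualify as sinks or sources.
#' @param floor_frac the threshold offset is never smaller than this
#'   fraction of the map's peak absolute CSD in the search window (default
#'   0.5, i.e. a candidate sink must reach half the map's peak response).
#'   This floors the `k * SD` rule, which is degenerate for noise-free data
#'   (SD ~ 0) and spuriously permissive for shoulder artifacts of the
#'   detrend/band-pass stages that survive trial averaging.
#' @param tie_ms crossings within this many ms of the earliest crossing are
#'   treated as simultaneous and resolved by sink magnitude (default 10 ms,
#'   on the order of the crossing-time jitter the 20-ms temporal smoothing
#'   leaves in the averaged map).
#' @return the L4 channel index (in the original channel numbering).
#' @export
find_l4_sink <- function(csd, baseline_window_ms = c(-250, 0),
                         search_window_ms = c(20, 120), k = 2,
                         min_duration_ms = 5, floor_frac = 0.5,
                         tie_ms = 10) {
  stopifnot(inherits(csd, "csd_map"))
  t_ms <- csd$time_ms
  ib <- which(t_ms >= baseline_window_ms[1L] & t_ms <= baseline_window_ms[2L])
  is <- which(t_ms >= search_window_ms[1L] & t_ms <= search_window_ms[2L])
  if (!length(ib) || !length(is)) {
    abort("Baseline or search window lies outside the CSD time axis.",
          class = "dlamr_validation_error")
  }
  m <- nrow(csd$csd)
  min_run <- max(1L, round(min_duration_ms / 1000 * csd$fs))
  first_sustained <- function(flags) {
    # index into `is` of the first run of >= min_run consecutive TRUEs
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= min_run)
    if (!length(hit)) return(NA_integer_)
    ends[hit[1L]] - r$lengths[hit[1L]] + 1L
  }
  # crossing time refined by linear interpolation against the threshold
  # level, so near-simultaneous crossings on neighboring channels are
  # resolved by which channel genuinely reaches the level first
  cross_time <- function(x, j_is, level, downward) {
    j <- is[j_is]
    if (j == 1L) return(t_ms[j])
    x0 <- x[j - 1L]; x1 <- x[j]
    if ((downward && x0 <= level) || (!downward && x0 >= level) || x1 == x0) {
      return(t_ms[j])
    }
    t_ms[j - 1L] + (level - x0) / (x1 - x0) * (t_ms[j] - t_ms[j - 1L])
  }
  sink_t <- rep(NA_real_, m)
  src_t <- rep(NA_real_, m)
  floor_abs <- floor_frac * max(abs(csd$csd[, is]))
  for (i in seq_len(m)) {
    x <- csd$csd[i, ]
    mu <- mean(x[ib]); s <- sd(x[ib])
    thr <- max(k * s, floor_abs)
    j_sink <- first_sustained(x[is] < mu - thr)
    j_src <- first_sustained(x[is] > mu + thr)
    if (!is.na(j_sink)) sink_t[i] <- cross_time(x, j_sink, mu - thr, TRUE)
    if (!is.na(j_src)) src_t[i] <- cross_time(x, j_src, mu + thr, FALSE)
  }
  cand <- which(!is.na(sink_t))
  if (!length(cand)) {
    abort("No channel crosses the sink threshold: no sink found.",
          class = "dlamr_no_sink_error")
  }
  src_rows <- which(!is.na(src_t))
  if (length(src_rows)) {
    ok <- cand[vapply(cand, function(i) any(src_rows < i), logical(1))]
    if (length(ok)) cand <- ok
  }
  # earliest crossing, with near-simultaneous crossings resolved in favor
  # of the deepest (most negative) sink; sink magnitude is averaged over a
  # 20 ms window around the map's trough so a single noisy sample cannot
  # decide between neighboring channels
  near <- cand[sink_t[cand] <= min(sink_t[cand]) + tie_ms]
  sub <- csd$csd[near, is, drop = FALSE]
  t_star <- which(sub == min(sub), arr.ind = TRUE)[1L, 2L]
  jwin <- is[max(1L, t_star - round(0.01 * csd$fs)):
               min(length(is), t_star + round(0.01 * csd$fs))]
  trough <- rowMeans(csd$csd[near, jwin, drop = FALSE])
  winner <- max(near[trough <= min(trough) + 1e-12 * max(abs(trough))])
  csd$channel_index[winner]
}

# layer boundary table, depths in um relative to the L4 sink (positive
# superficial); half-open bins, upper bound exclusive
layer_of_depth <- function(depth_um) {
  out <- rep("out", length(depth_um))
  out[depth_um >= 60 & depth_um < 300] <- "L2/3"
  out[depth_um >= -80 & depth_um < 60] <- "L4"
  out[depth_um >= -260 & depth_um < -80] <- "L5"
  out[depth_um >= -460 & depth_um < -260] <- "L6"
  out
}

#' Laminar alignment: signed depths and layer labels from the L4 reference
#'
#' Depth of channel i is `(l4_channel - i) * h_um`, positive superficial,
#' zero at the L4 sink. Layers follow the boundary table L2/3 +300..+60,
#' L4 +60..-80, L5 -80..-260, L6 -260..-460 um (half-open, upper-exclusive);
#' depths outside that range are labeled `"out"`.
#'
#' @param l4_channel L4 sink channel index.
#' @param n_channels number of channels on the probe.
#' @param h_um electrode spacing in um.
#' @return a `laminar_alignment` with `l4_channel`, `depth_um`, `layer`.
#' @export
laminar_alignment <- function(l4_channel, n_channels, h_um = 20) {
  if (l4_channel < 1L || l4_channel > n_channels) {
    abort("L4 channel outside the probe.", class = "dlamr_validation_error")
  }
  depth <- (l4_channel - seq_len(n_channels)) * h_um
  structure(
    list(l4_channel = l4_channel, n_channels = n_channels, h_um = h_um,
         depth_um = depth, layer = layer_of_depth(depth)),
    class = "laminar_alignment"
  )
}

#' @export
print.laminar_alignment <- function(x, ...) {
  cat(sprintf("<laminar_alignment: L4 at channel %d of %d (h = %g um)>\n",
              x$l4_channel, x$n_channels, x$h_um))
  invisible(x)
}

#' Per-channel layer table of an alignment
#'
#' @param alignment a `laminar_alignment`.
#' @return tibble with `channel`, `depth_um`, `layer`.
#' @export
assign_layers <- function(alignment) {
  stopifnot(inherits(alignment, "laminar_alignment"))
  tibble(channel = seq_len(alignment$n_channels),
         depth_um = alignment$depth_um,
         layer = alignment$layer)
}

#' Plot a CSD map
#'
#' @param object a `csd_map`.
#' @param ... unused.
#' @return a ggplot (sinks in blue, sources in red by convention).
#' @method autoplot csd_map
#' @export
autoplot.csd_map <- function(object, ...) {
  df <- tibble(
    channel = rep(object$channel_index, times = ncol(object$csd)),
    time_ms = rep(object$time_ms, each = nrow(object$csd)),
    csd = as.vector(object$csd)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$channel,
                                   fill = .data$csd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "Time (ms)", y = "Channel (superficial at top)",
                  fill = "CSD") +
    ggplot2::theme_minimal()
}
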