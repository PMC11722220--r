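# Synthetic laminar sessions with known ground truth. The LFP forward model
# prescribes a current-source-density depth profile (an L4 sink below a
# superficial source) and integrates it twice along depth with zero-mean
# boundary conditions, so the CSD stage has an exact inverse target. Trial
# time courses encode the condition effects the analysis is meant to
# recover: a concordant-enhanced / phase-offset-suppressed early component
# (40-80 ms) and an orthogonal-enhanced late component (100-200 ms).
# Defaults follow the acute-recording protocol: 64 channels at 20 um, 25 kHz,
# 100 s blocks with 30 s interblock gray, five blocks per condition, one
# phase reversal per second (500 trials per condition).

dichoptic_conditions <- c("monocular", "concordant", "phase_offset",
                          "orthogonal")

# deterministic per-stream child seeds from one global seed
child_seed <- function(seed, stream) {
  streams <- c(schedule = 1L, lfp = 2L, spikes = 3L, calcium = 4L,
               templates = 5L)
  (as.integer(seed) %% 1000003L) * 1009L + streams[[stream]] * 7919L
}

#' Parameters of a synthetic laminar session
#'
#' Defaults encode the acute-recording protocol and the qualitative
#' condition effects: concordant stimulation enhances and phase-offset
#' stimulation suppresses the early response, while orthogonal stimulation
#' prolongs elevated late activity.
#'
#' @param n_channels channels on the probe (>= 5 for the CSD kernel).
#' @param spacing_um electrode spacing, 20 um.
#' @param fs sampling rate in Hz.
#' @param n_blocks_per_condition,block_s,interblock_s block structure in
#'   seconds.
#' @param reversal_hz phase reversals per second within blocks.
#' @param conditions condition labels.
#' @param g_early,g_late named per-condition gains (>= 0) of the early and
#'   late response components.
#' @param evoked_amplitude_V evoked LFP scale at the sink (V).
#' @param sink_channel L4 sink channel; `NULL` draws one at random (kept
#'   away from the probe ends).
#' @param source_offset channels between the sink and the superficial
#'   source (2-4 in cortex).
#' @param noise_pink_V RMS of the 1/f background per channel (V).
#' @param noise_line_V amplitude of the 60 Hz line component (V).
#' @return a named list of validated parameters.
#' @export
session_params <- function(n_channels = 64, spacing_um = 20, fs = 25000,
                           n_blocks_per_condition = 5, block_s = 100,
                           interblock_s = 30, reversal_hz = 1,
                           conditions = dichoptic_conditions,
                           g_early = c(monocular = 1, concordant = 1.5,
                                       phase_offset = 0.5, orthogonal = 1),
                           g_late = c(monocular = 0.3, concordant = 0.3,
                                      phase_offset = 0.3, orthogonal = 1.5),
                           evoked_amplitude_V = 150e-6,
                           sink_channel = NULL, source_offset = 3,
                           noise_pink_V = 30e-6, noise_line_V = 20e-6) {
  if (n_channels < 5L) {
    abort("The CSD kernel needs at least 5 channels.",
          class = "dlamr_validation_error")
  }
  if (any(g_early < 0) || any(g_late < 0)) {
    abort("Condition gains must be nonnegative.",
          class = "dlamr_validation_error")
  }
  if (!all(conditions %in% names(g_early)) ||
      !all(conditions %in% names(g_late))) {
    abort("Every condition needs an entry in g_early and g_late.",
          class = "dlamr_validation_error")
  }
  as.list(environment())
}

# pink (1/f amplitude) noise via spectral shaping of white Gaussian noise
pink_noise <- function(n, rms) {
  w <- rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))             # avoid the DC bin
  f <- pmin(f, n - f + 1)               # symmetric frequency index
  W <- W / sqrt(f)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x * rms / sd(x)
}

# raised-cosine bump on [a, b] ms, unit peak
window_bump <- function(t_ms, a, b) {
  out <- numeric(length(t_ms))
  inside <- t_ms >= a & t_ms <= b
  out[inside] <- 0.5 * (1 - cos(2 * pi * (t_ms[inside] - a) / (b - a)))
  out
}

# early LFP kernel: difference of Gaussians, positive lobe peaking ~65 ms,
# negative lobe ~115 ms (yields the canonical negativity-then-positivity at
# the sink after depth integration)
kernel_early_lfp <- function(t_ms) {
  exp(-(t_ms - 65)^2 / (2 * 10^2)) - 0.7 * exp(-(t_ms - 115)^2 / (2 * 25^2))
}

# late plateau on 100-200 ms with smooth edges
kernel_late_lfp <- function(t_ms) {
  k <- numeric(length(t_ms))
  core <- t_ms >= 110 & t_ms <= 190
  rise <- t_ms >= 100 & t_ms < 110
  fall <- t_ms > 190 & t_ms <= 200
  k[core] <- 1
  k[rise] <- 0.5 * (1 - cos(pi * (t_ms[rise] - 100) / 10))
  k[fall] <- 0.5 * (1 + cos(pi * (t_ms[fall] - 190) / 10))
  k
}

# spiking kernels: unit-peak bumps strictly supported on the analysis windows
kernel_early_spk <- function(t_ms) window_bump(t_ms, 40, 80)
kernel_late_spk <- function(t_ms) window_bump(t_ms, 100, 200)

# prescribed CSD depth profile: Gaussian sink at sink_channel, balanced
# Gaussian source source_offset channels above
csd_depth_profile <- function(n_channels, sink_channel, source_offset) {
  i <- seq_len(n_channels)
  sink <- exp(-(i - sink_channel)^2 / (2 * 1.0^2))
  src <- exp(-(i - (sink_channel - source_offset))^2 / (2 * 1.0^2))
  -sink + src * sum(sink) / sum(src)    # source-sink balanced
}

# potential profile whose CSD (as computed by compute_csd) is ~ the
# prescribed profile: phi'' = -C * h_mm^2, double cumulative sum, zero-mean
potential_from_csd <- function(csd_profile, h_um) {
  h_mm <- h_um / 1000
  d2 <- -csd_profile * h_mm^2
  # phi[i+1] - 2 phi[i] + phi[i-1] = d2[i]: integrate twice, with the first
  # integral lagged one channel so the second difference is centered
  phi <- cumsum(c(0, head(cumsum(d2), -1L)))
  phi <- phi - mean(phi)
  phi / max(abs(phi))   # unit peak: evoked_amplitude_V sets the LFP scale
}

#' Generate the block/event schedule of a synthetic session
#'
#' Blocks of each condition are pseudorandomly interleaved with interblock
#' gray gaps; reversal events tile each block at the configured rate.
#'
#' @param params from [session_params()].
#' @param seed integer seed.
#' @return a `stimulus_schedule`.
#' @export
generate_schedule <- function(params, seed = 1) {
  set.seed(child_seed(seed, "schedule"))
  order <- sample(rep(params$conditions, params$n_blocks_per_condition))
  n_b <- length(order)
  starts <- params$interblock_s +
    (seq_len(n_b) - 1L) * (params$block_s + params$interblock_s)
  blocks <- tibble(block_id = seq_len(n_b), condition = order,
                   start_s = starts, end_s = starts + params$block_s)
  times <- lapply(seq_len(n_b), function(b) {
    seq(blocks$start_s[b], blocks$end_s[b] - 1 / params$reversal_hz,
        by = 1 / params$reversal_hz)
  })
  events <- tibble(block_id = rep(seq_len(n_b), lengths(times)),
                   time_s = unlist(times))
  stimulus_schedule(blocks, events)
}

#' Generate a synthetic laminar recording with known ground truth
#'
#' @param params from [session_params()].
#' @param seed integer seed; identical seed and params give bit-identical
#'   output.
#' @param schedule optionally a pre-built `stimulus_schedule` (otherwise
#'   generated from `params` and `seed`).
#' @return list: `session` (`recording_session`), `schedule`
#'   (`stimulus_schedule`), `truth` (list with the sink/source channels,
#'   per-condition gains, noise levels, and seed).
#' @export
generate_session <- function(params = session_params(), seed = 1,
                             schedule = NULL) {
  schedule <- schedule %||% generate_schedule(params, seed)
  set.seed(child_seed(seed, "lfp"))
  sink <- params$sink_channel %||%
    sample(seq(params$source_offset + 4L, params$n_channels - 4L), 1L)
  if (sink - params$source_offset < 1L || sink > params$n_channels) {
    abort("Sink/source placement falls off the probe.",
          class = "dlamr_validation_error")
  }
  dur_s <- max(schedule$blocks$end_s) + params$interblock_s
  n_t <- round(dur_s * params$fs)
  profile <- csd_depth_profile(params$n_channels, sink, params$source_offset)
  phi <- potential_from_csd(profile, params$spacing_um)
  # per-event trial kernel, sampled at fs over 0..300 ms
  kt_ms <- (seq_len(round(0.3 * params$fs)) - 1L) / params$fs * 1000
  kE <- kernel_early_lfp(kt_ms)
  kL <- kernel_late_lfp(kt_ms)
  # evoked time course over the whole session, one vector per condition mix
  evoked_t <- numeric(n_t)
  ev_idx <- match(schedule$events$block_id, schedule$blocks$block_id)
  ev_cond <- schedule$blocks$condition[ev_idx]
  for (cond in unique(ev_cond)) {
    gE <- params$g_early[[cond]]
    gL <- params$g_late[[cond]]
    kern <- gE * kE + gL * kL
    for (t0 in schedule$events$time_s[ev_cond == cond]) {
      i0 <- round(t0 * params$fs) + 1L
      i1 <- min(n_t, i0 + length(kern) - 1L)
      if (i0 <= n_t) {
        evoked_t[i0:i1] <- evoked_t[i0:i1] + kern[seq_len(i1 - i0 + 1L)]
      }
    }
  }
  samples <- params$evoked_amplitude_V * outer(phi, evoked_t)
  if (params$noise_pink_V > 0) {
    for (ch in seq_len(params$n_channels)) {
      samples[ch, ] <- samples[ch, ] + pink_noise(n_t, params$noise_pink_V)
    }
  }
  if (params$noise_line_V > 0) {
    tt <- (seq_len(n_t) - 1L) / params$fs
    line <- params$noise_line_V * sin(2 * pi * 60 * tt + runif(1) * 2 * pi)
    samples <- sweep(samples, 2L, line, `+`)
  }
  depths <- rev(seq_len(params$n_channels)) * params$spacing_um
  session <- recording_session(
    samples, fs = params$fs, channel_depths_um = depths,
    session_id = sprintf("synthetic-%d", seed)
  )
  truth <- list(sink_channel = sink,
                source_channel = sink - params$source_offset,
                g_early = params$g_early, g_late = params$g_late,
                evoked_amplitude_V = params$evoked_amplitude_V,
                noise_pink_V = params$noise_pink_V,
                noise_line_V = params$noise_line_V,
                spacing_um = params$spacing_um, seed = seed)
  list(session = session, schedule = schedule, truth = truth)
}

#' Biphasic spike template with a prescribed trough-to-peak latency
#'
#' Gaussian trough followed by a Gaussian peak `t2p_ms` later; the shape
#' used for all synthetic units (RS: 0.5-0.8 ms, FS: 0.2-0.3 ms).
#'
#' @param t2p_ms trough-to-peak latency in ms.
#' @param fs sampling rate in Hz.
#' @param len_ms template length in ms.
#' @param amplitude_mV trough amplitude (negative), mV.
#' @return numeric template (mV).
#' @export
spike_template <- function(t2p_ms, fs = 25000, len_ms = 2.4,
                           amplitude_mV = -0.08) {
  n <- round(len_ms / 1000 * fs)
  t_ms <- (seq_len(n) - 1L) / fs * 1000
  t_trough <- 0.6
  w <- amplitude_mV * exp(-(t_ms - t_trough)^2 / (2 * 0.06^2)) -
    0.45 * amplitude_mV * exp(-(t_ms - (t_trough + t2p_ms))^2 / (2 * 0.12^2))
  w
}

#' Generate synthetic sorted units (inhomogeneous Poisson spiking)
#'
#' Each unit fires as an inhomogeneous Poisson process with
#' `rate(t) = base * (1 + gE(c) * kE(t) + gL(c) * kL(t))` inside trials,
#' where `kE` is a unit-peak bump on 40-80 ms and `kL` on 100-200 ms
#' post-reversal, and at `base` elsewhere. RS templates have trough-to-peak
#' latencies of 0.5-0.8 ms, FS templates 0.2-0.3 ms.
#'
#' @param params from [session_params()] (gains are read from here).
#' @param schedule a `stimulus_schedule`.
#' @param seed integer seed.
#' @param n_units number of units.
#' @param rs_fraction fraction of regular-spiking units.
#' @param base_rate_hz mean baseline rate; per-unit rates are drawn
#'   lognormally around it.
#' @param spike_band if `TRUE`, also return a 25 kHz single-channel trace
#'   with the scaled templates inserted at the spike times (for MUAe tests).
#' @param spike_band_noise_V Gaussian noise RMS added to that trace (V).
#' @return list: `units` (a `sorted_units` tibble with true classes in
#'   `cls_true` and `cls` unset), `truth` (per-unit table), and optionally
#'   `trace` (volts) with `fs = 25000`.
#' @export
generate_units <- function(params, schedule, seed = 1, n_units = 20,
                           rs_fraction = 0.8, base_rate_hz = 5,
                           spike_band = FALSE, spike_band_noise_V = 5e-6) {
  set.seed(child_seed(seed, "spikes"))
  dur_s <- max(schedule$blocks$end_s, schedule$interblock$end_s)
  n_bins <- ceiling(dur_s * 1000)       # 1-ms rate grid
  t_trial_ms <- 0:299
  kE <- kernel_early_spk(t_trial_ms)
  kL <- kernel_late_spk(t_trial_ms)
  ev_idx <- match(schedule$events$block_id, schedule$blocks$block_id)
  ev_cond <- schedule$blocks$condition[ev_idx]
  # shared modulation shape per condition (unit gains multiply it)
  mod_e <- numeric(n_bins)
  mod_l <- numeric(n_bins)
  cond_of_bin_e <- rep(0, n_bins)
  for (j in seq_along(schedule$events$time_s)) {
    i0 <- round(schedule$events$time_s[j] * 1000) + 1L
    i1 <- min(n_bins, i0 + 299L)
    seg <- seq_len(i1 - i0 + 1L)
    gE <- params$g_early[[ev_cond[j]]]
    gL <- params$g_late[[ev_cond[j]]]
    mod_e[i0:i1] <- mod_e[i0:i1] + gE * kE[seg]
    mod_l[i0:i1] <- mod_l[i0:i1] + gL * kL[seg]
  }
  n_rs <- round(n_units * rs_fraction)
  is_rs <- c(rep(TRUE, n_rs), rep(FALSE, n_units - n_rs))
  t2p <- ifelse(is_rs, runif(n_units, 0.5, 0.8), runif(n_units, 0.2, 0.3))
  base <- stats::rlnorm(n_units, log(base_rate_hz), 0.3)
  depth <- runif(n_units, -450, 290)
  spike_times <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    rate <- base[u] * (1 + mod_e + mod_l)
    if (any(rate < 0)) {
      warn("Negative instantaneous rate clipped to zero.")
      rate <- pmax(rate, 0)
    }
    counts <- rpois(n_bins, rate / 1000)
    nz <- which(counts > 0L)
    st <- rep((nz - 1L) / 1000, counts[nz]) + runif(sum(counts[nz])) / 1000
    spike_times[[u]] <- sort(st)
  }
  templates <- lapply(t2p, spike_template)
  units <- sorted_units(
    unit_id = sprintf("u%02d", seq_len(n_units)),
    spike_times_s = spike_times,
    waveform = templates,
    depth_um = depth,
    cls = NA_character_
  )
  units$cls_true <- ifelse(is_rs, "RS", "FS")
  truth <- tibble(unit_id = units$unit_id, cls_true = units$cls_true,
                  t2p_ms = t2p, base_rate_hz = base, depth_um = depth)
  out <- list(units = units, truth = truth)
  if (spike_band) {
    fs <- 25000
    n_t <- round(dur_s * fs)
    tr <- rnorm(n_t, 0, spike_band_noise_V)
    for (u in seq_len(n_units)) {
      tr <- insert_template(tr, spike_times[[u]], templates[[u]], fs)
    }
    out$trace <- matrix(tr, nrow = 1L)
    out$trace_fs <- fs
  }
  out
}

#' Insert a spike template into a wide-band trace at given times
#'
#' @param trace numeric vector (volts).
#' @param spike_times_s spike times in seconds.
#' @param template_mV template in mV (scaled to volts on insertion).
#' @param fs sampling rate in Hz.
#' @return the trace with templates added.
#' @export
insert_template <- function(trace, spike_times_s, template_mV, fs = 25000) {
  n_t <- length(trace)
  tmpl <- template_mV * 1e-3
  for (s in spike_times_s) {
    i0 <- round(s * fs) + 1L
    i1 <- min(n_t, i0 + length(tmpl) - 1L)
    if (i0 <= n_t && i1 >= i0) {
      trace[i0:i1] <- trace[i0:i1] + tmpl[seq_len(i1 - i0 + 1L)]
    }
  }
  trace
}

#' Generate synthetic ROI calcium traces
#'
#' Per-ROI spiking follows the condition-gain table (`preset` or explicit
#' `gains`); spikes are convolved with an exponential indicator kernel, a
#' shared neuropil background plus a fraction of the mean population signal
#' is mixed in, and shot noise added. The imaging protocol defaults to the
#' two-photon one: ~14.9 Hz frames, 10 s blocks with 10 s gray gaps, 24
#' blocks per condition.
#'
#' @param params ignored except for condition labels; pass `NULL` to use the
#'   four dichoptic conditions.
#' @param seed integer seed.
#' @param n_roi number of ROIs.
#' @param preset `"excitatory"` (orthogonal enhanced relative to monocular)
#'   or `"som"` (somatostatin-like: orthogonal suppressed).
#' @param gains optional named per-condition rate gains overriding the
#'   preset.
#' @param frame_rate,block_s,interblock_s,n_blocks_per_condition imaging
#'   protocol.
#' @param base_rate_hz baseline firing rate driving the indicator.
#' @param kernel_amplitude,kernel_tau_s indicator transient amplitude
#'   (fluorescence units per spike) and decay constant.
#' @param alpha_mix neuropil contamination coefficient mixed into the
#'   measured ROI fluorescence.
#' @param shot_noise_sd Gaussian noise SD on the measured trace.
#' @param units optional `sorted_units` whose spike trains drive the ROIs
#'   (recycled over ROIs); by default spiking is simulated here, since the
#'   imaging block structure differs from the electrophysiology one.
#' @return list: `traces` (a `roi_trace_set`), `truth` (gains, kernel,
#'   mixing, per-ROI true fluorescence matrix `F_true`).
#' @export
generate_calcium <- function(params = NULL, seed = 1, n_roi = 120,
                             preset = c("excitatory", "som"),
                             gains = NULL, frame_rate = 14.9,
                             block_s = 10, interblock_s = 10,
                             n_blocks_per_condition = 24,
                             base_rate_hz = 2, kernel_amplitude = 8,
                             kernel_tau_s = 0.7, alpha_mix = 0.7,
                             shot_noise_sd = 1, units = NULL) {
  preset <- match.arg(preset)
  if (kernel_tau_s <= 0) {
    abort("Indicator decay tau must be positive.",
          class = "dlamr_validation_error")
  }
  gains <- gains %||% switch(
    preset,
    excitatory = c(monocular = 1.0, concordant = 1.3, phase_offset = 0.8,
                   orthogonal = 1.8),
    som = c(monocular = 1.0, concordant = 1.3, phase_offset = 1.0,
            orthogonal = 0.3)
  )
  set.seed(child_seed(seed, "calcium"))
  sched_params <- session_params(
    n_channels = 5, fs = 1000, block_s = block_s,
    interblock_s = interblock_s,
    n_blocks_per_condition = n_blocks_per_condition,
    conditions = names(gains),
    g_early = gains, g_late = gains
  )
  schedule <- generate_schedule(sched_params, seed)
  dur_s <- max(schedule$blocks$end_s) + interblock_s
  n_frames <- floor(dur_s * frame_rate)
  t_frames <- (seq_len(n_frames) - 1L) / frame_rate
  # per-frame condition gain (1 during gray)
  gain_t <- rep(1, n_frames)
  for (b in seq_len(nrow(schedule$blocks))) {
    inb <- t_frames >= schedule$blocks$start_s[b] &
      t_frames < schedule$blocks$end_s[b]
    gain_t[inb] <- gains[[schedule$blocks$condition[b]]]
  }
  kern_len <- ceiling(5 * kernel_tau_s * frame_rate)
  kern <- kernel_amplitude * exp(-(seq_len(kern_len) - 1L) /
                                   (kernel_tau_s * frame_rate))
  F0 <- 100
  F_true <- matrix(0, n_roi, n_frames)
  for (r in seq_len(n_roi)) {
    if (!is.null(units)) {
      st <- units$spike_times_s[[((r - 1L) %% nrow(units)) + 1L]]
      counts <- tabulate(floor(st * frame_rate) + 1L, nbins = n_frames)
    } else {
      counts <- rpois(n_frames, base_rate_hz * gain_t / frame_rate)
    }
    tr <- convolve(counts, rev(kern), type = "open")[seq_len(n_frames)]
    F_true[r, ] <- F0 + tr
  }
  np_background <- 30 + 5 * sin(2 * pi * t_frames / 60)
  pop <- colMeans(F_true) - mean(F_true)
  F_np <- matrix(rep(np_background + 0.3 * pop, n_roi),
                 nrow = n_roi, byrow = TRUE)
  F_roi <- F_true + alpha_mix * F_np +
    matrix(rnorm(n_roi * n_frames, 0, shot_noise_sd), n_roi)
  traces <- roi_trace_set(F_roi, F_np, frame_rate, schedule)
  truth <- list(gains = gains, preset = preset,
                kernel_amplitude = kernel_amplitude,
                kernel_tau_s = kernel_tau_s, alpha_mix = alpha_mix,
                base_rate_hz = base_rate_hz, F_true = F_true, seed = seed)
  list(traces = traces, truth = truth)
}

#' Insert unit spike templates into a session's wide-band trace
#'
#' Adds each unit's template (scaled to volts) at its spike times on the
#' channel nearest the unit's depth, given the ground-truth L4 channel, so
#' the 25 kHz trace carries spike-band energy consistent with the units.
#'
#' @param session a `recording_session` at 25 kHz.
#' @param units a `sorted_units` tibble (templates in mV).
#' @param truth ground-truth list from [generate_session()] (for the sink
#'   channel and spacing).
#' @return the session with templates added.
#' @export
insert_spike_templates <- function(session, units, truth) {
  stopifnot(inherits(session, "recording_session"))
  fs <- session$fs
  n_ch <- nrow(session$samples)
  n_t <- ncol(session$samples)
  for (u in seq_len(nrow(units))) {
    ch <- round(truth$sink_channel - units$depth_um[u] / truth$spacing_um)
    ch <- min(max(ch, 1L), n_ch)
    tmpl <- units$waveform[[u]] * 1e-3
    for (s in units$spike_times_s[[u]]) {
      i0 <- round(s * fs) + 1L
      i1 <- min(n_t, i0 + length(tmpl) - 1L)
      if (i0 <= n_t && i1 >= i0) {
        session$samples[ch, i0:i1] <- session$samples[ch, i0:i1] +
          tmpl[seq_len(i1 - i0 + 1L)]
      }
    }
  }
  session
}

#' Trial-averaged signal matrix aligned to events
#'
#' Averages channels x time data over windows aligned at the given event
#' times (optionally starting before the event); windows extending past the
#' data are dropped.
#'
#' @param x channels x time matrix.
#' @param fs sampling rate in Hz.
#' @param events_s event times (s).
#' @param T_ms window length after the event (ms).
#' @param pre_ms window length before the event (ms).
#' @return channels x samples matrix covering `-pre_ms .. T_ms`.
#' @export
trial_average <- function(x, fs, events_s, T_ms, pre_ms = 0) {
  n_samp <- round((pre_ms + T_ms) / 1000 * fs)
  align_average(x, fs, events_s - pre_ms / 1000, n_samp)
}

#' Simulate a multi-subject windowed-firing experiment
#'
#' Generates `n_subjects` independent synthetic sessions, computes every
#' unit's early (40-80 ms) and late (100-200 ms) window rates per condition,
#' and returns the subject x condition matrices of unit-averaged rates —
#' the input to the repeated-measures inference stage. With `null = TRUE`
#' all conditions share the same gains, so any detected condition effect is
#' a false positive.
#'
#' @param seed integer seed (each subject derives its own stream from it).
#' @param n_subjects number of subjects (sessions).
#' @param n_units units per subject.
#' @param block_s seconds per condition block (one block per condition).
#' @param base_rate_hz mean baseline firing rate.
#' @param null if `TRUE`, use equal gains across conditions.
#' @param conditions condition labels.
#' @return list of subjects x conditions matrices `early` and `late`.
#' @export
simulate_window_experiment <- function(seed, n_subjects = 8, n_units = 20,
                                       block_s = 30, base_rate_hz = 10,
                                       null = FALSE,
                                       conditions = dichoptic_conditions) {
  extra <- if (null) {
    flat_e <- stats::setNames(rep(1, length(conditions)), conditions)
    flat_l <- stats::setNames(rep(0.3, length(conditions)), conditions)
    list(g_early = flat_e, g_late = flat_l)
  } else {
    list()
  }
  per_subject <- lapply(seq_len(n_subjects), function(sj) {
    p <- do.call(session_params,
                 c(list(n_channels = 5, fs = 1000,
                        n_blocks_per_condition = 1, block_s = block_s,
                        interblock_s = 5, conditions = conditions),
                   extra))
    sj_seed <- (seed * 131L + sj) %% 2147483647L
    sch <- generate_schedule(p, seed = sj_seed)
    gu <- generate_units(p, sch, seed = sj_seed, n_units = n_units,
                         base_rate_hz = base_rate_hz)
    st <- unit_condition_stats(gu$units, sch, conditions = conditions,
                               T_trial_ms = 300)
    f <- factor(st$condition, levels = conditions)
    list(early = tapply(st$early_rate_hz, f, mean),
         late = tapply(st$late_rate_hz, f, mean))
  })
  grab <- function(col) {
    m <- t(vapply(per_subject, `[[`, numeric(length(conditions)), col))
    colnames(m) <- conditions
    m
  }
  list(early = grab("early"), late = grab("late"))
}
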