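# small fixtures shared across test files, all built in code

# two-condition schedule: blocks [5,15) and [25,35), gray gaps elsewhere
tiny_schedule <- function(conditions = c("monocular", "concordant"),
                          block_s = 10, gap_s = 5, events_hz = 1) {
  n <- length(conditions)
  starts <- gap_s + (seq_len(n) - 1) * (block_s + gap_s)
  blocks <- tibble::tibble(block_id = seq_len(n), condition = conditions,
                           start_s = starts, end_s = starts + block_s)
  events <- do.call(rbind, lapply(seq_len(n), function(b) {
    data.frame(block_id = b,
               time_s = seq(starts[b], starts[b] + block_s - 1 / events_hz,
                            by = 1 / events_hz))
  }))
  stimulus_schedule(blocks, events)
}

# small synthetic laminar session at 1 kHz for CSD / VEP tests
small_session <- function(seed = 1, n_channels = 32, sink = NULL,
                          noise = TRUE, block_s = 15) {
  p <- session_params(
    n_channels = n_channels, fs = 1000, n_blocks_per_condition = 1,
    block_s = block_s, interblock_s = 5, sink_channel = sink,
    noise_pink_V = if (noise) 30e-6 else 0,
    noise_line_V = if (noise) 20e-6 else 0
  )
  generate_session(p, seed = seed)
}

# attenuation (dB) of a sinusoid through a single-channel filter function,
# measured over the central half of the trace to avoid edge transients
sine_attenuation_db <- function(filter_fun, freq_hz, fs, dur_s = 2) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq_hz * t)
  y <- filter_fun(x)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  20 * log10(stats::sd(y[mid]) / stats::sd(x[mid]))
}

# run one channel through an lfp_trace-based step
lfp_step <- function(x, fs, step) {
  tr <- dlamr:::as_lfp_trace(matrix(x, nrow = 1), fs, 0)
  step(tr)$samples[1, ]
}
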