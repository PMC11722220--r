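test_that("generation is fully deterministic for a fixed seed", {
  s1 <- small_session(seed = 5, n_channels = 8, block_s = 5)
  s2 <- small_session(seed = 5, n_channels = 8, block_s = 5)
  expect_identical(s1$session$samples, s2$session$samples)
  expect_identical(s1$schedule$blocks, s2$schedule$blocks)
  expect_identical(s1$truth, s2$truth)
  s3 <- small_session(seed = 6, n_channels = 8, block_s = 5)
  expect_false(identical(s1$session$samples, s3$session$samples))
})

test_that("zero gains and zero noise give a flat recording with zero CSD", {
  p <- session_params(n_channels = 16, fs = 1000, n_blocks_per_condition = 1,
                      block_s = 5, interblock_s = 2,
                      g_early = c(monocular = 0, concordant = 0,
                                  phase_offset = 0, orthogonal = 0),
                      g_late = c(monocular = 0, concordant = 0,
                                 phase_offset = 0, orthogonal = 0),
                      noise_pink_V = 0, noise_line_V = 0)
  sim <- generate_session(p, seed = 1)
  expect_equal(max(abs(sim$session$samples)), 0)
  csd <- compute_csd(sim$session$samples[, 1:500], 20, fs = 1000)
  expect_equal(max(abs(csd$csd)), 0)
})

test_that("the CSD of a noise-free generated session has its minimum at the prescribed sink", {
  sim <- small_session(seed = 2, n_channels = 32, sink = 20, noise = FALSE)
  ev <- sort(sim$schedule$events$time_s)
  avg <- trial_average(sim$session$samples, 1000, ev, T_ms = 300)
  csd <- compute_csd(avg, 20, fs = 1000)
  peak <- which(csd$csd == min(csd$csd), arr.ind = TRUE)
  expect_equal(csd$channel_index[peak[1, 1]], 20)
  # sink time within one smoothing width of the early-component peak (65 ms)
  expect_lt(abs(csd$time_ms[peak[1, 2]] - 65), 20)
})

test_that("the evoked LFP is linear in the prescribed amplitude (noise off)", {
  p1 <- session_params(n_channels = 16, fs = 1000, n_blocks_per_condition = 1,
                       block_s = 5, interblock_s = 2, sink_channel = 8,
                       noise_pink_V = 0, noise_line_V = 0)
  p2 <- p1
  p2$evoked_amplitude_V <- 2 * p1$evoked_amplitude_V
  a1 <- generate_session(p1, seed = 3)$session$samples
  a2 <- generate_session(p2, seed = 3)$session$samples
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
})

test_that("units with zero gains fire at their base rate (homogeneous Poisson)", {
  p <- session_params(n_channels = 5, fs = 1000, n_blocks_per_condition = 1,
                      block_s = 20, interblock_s = 2,
                      g_early = c(monocular = 0, concordant = 0,
                                  phase_offset = 0, orthogonal = 0),
                      g_late = c(monocular = 0, concordant = 0,
                                 phase_offset = 0, orthogonal = 0))
  sch <- generate_schedule(p, seed = 4)
  gu <- generate_units(p, sch, seed = 4, n_units = 8, base_rate_hz = 5)
  dur <- max(sch$blocks$end_s, sch$interblock$end_s)
  emp <- vapply(gu$units$spike_times_s, length, numeric(1)) / dur
  # each unit within 4 SD of its own drawn base rate
  for (u in seq_len(8)) {
    lam <- gu$truth$base_rate_hz[u] * dur
    expect_lt(abs(length(gu$units$spike_times_s[[u]]) - lam), 4 * sqrt(lam))
  }
})

test_that("expected spike count over a session matches the rate integral", {
  p <- session_params(n_channels = 5, fs = 1000, n_blocks_per_condition = 1,
                      block_s = 10, interblock_s = 2)
  sch <- generate_schedule(p, seed = 9)
  counts <- vapply(1:50, function(i) {
    gu <- generate_units(p, sch, seed = 1000 + i, n_units = 1,
                         base_rate_hz = 8)
    length(gu$units$spike_times_s[[1]]) / gu$truth$base_rate_hz[1]
  }, numeric(1))
  # integral of rate/base over the session: dur + sum of kernel integrals
  dur <- max(sch$blocks$end_s, sch$interblock$end_s)
  kE <- dlamr:::kernel_early_spk(0:299)
  kL <- dlamr:::kernel_late_spk(0:299)
  per_event <- vapply(sch$events$block_id, function(b) {
    cond <- sch$blocks$condition[sch$blocks$block_id == b]
    (p$g_early[[cond]] * sum(kE) + p$g_late[[cond]] * sum(kL)) / 1000
  }, numeric(1))
  expected <- dur + sum(per_event)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("generated templates classify to their true class", {
  p <- session_params(n_channels = 5, fs = 1000, n_blocks_per_condition = 1,
                      block_s = 5, interblock_s = 2)
  sch <- generate_schedule(p, seed = 8)
  gu <- generate_units(p, sch, seed = 8, n_units = 30, rs_fraction = 0.5)
  cls <- classify_units(gu$units)
  expect_identical(cls$cls, gu$units$cls_true)
})

test_that("calcium generator with zero spikes and zero noise yields dF/F of 0", {
  gc <- generate_calcium(seed = 1, n_roi = 4, base_rate_hz = 0,
                         shot_noise_sd = 0, n_blocks_per_condition = 2)
  out <- suppressMessages(analyze_calcium_session(gc$traces, min_rois = 1))
  expect_lt(max(abs(out$dff)), 1e-12)
})

test_that("neuropil correction with alpha_mix = 0 subtracts exactly 0.7 of the neuropil trace", {
  gc <- generate_calcium(seed = 2, n_roi = 3, alpha_mix = 0,
                         shot_noise_sd = 0, n_blocks_per_condition = 2)
  corrected <- neuropil_correct(gc$traces$F_roi, gc$traces$F_np)
  expect_equal(corrected, gc$traces$F_roi - 0.7 * gc$traces$F_np)
  expect_equal(corrected, gc$truth$F_true - 0.7 * gc$traces$F_np)
})

test_that("a 2:1 condition rate ratio survives the dF/F pipeline in order", {
  gains <- c(monocular = 1, concordant = 2, phase_offset = 1, orthogonal = 1)
  gc <- generate_calcium(seed = 3, n_roi = 40, gains = gains,
                         n_blocks_per_condition = 8)
  out <- suppressMessages(analyze_calcium_session(gc$traces, min_rois = 1))
  pop <- out$population
  expect_gt(pop$mean_dff[pop$condition == "concordant"],
            pop$mean_dff[pop$condition == "monocular"])
})
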