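test_that("trial extraction aligns one row per event and drops tail events", {
  sch <- tiny_schedule(events_hz = 2)
  n <- 36 * 1000  # recording ends 1 s after the last block
  x <- matrix(rnorm(n), 1)
  lfp <- dlamr:::as_lfp_trace(x, 1000, 0)
  tr <- extract_trials(lfp, sch, "monocular", 1, T_trial_ms = 400)
  expect_equal(nrow(tr), 20)
  expect_equal(ncol(tr), 400)
  # shorten the recording so the last events cannot fit a 500 ms window
  lfp_short <- dlamr:::as_lfp_trace(x[, 1:29800, drop = FALSE], 1000, 0)
  expect_message(tr2 <- extract_trials(lfp_short, sch, "concordant", 1,
                                       T_trial_ms = 500),
                 "dropped")
  expect_lt(nrow(tr2), 20)
  expect_error(extract_trials(lfp, sch, "orthogonal", 1),
               class = "dlamr_validation_error")
})

test_that("normalization zeroes constant offsets and averaging is consistent", {
  trials <- matrix(5, nrow = 4, ncol = 200)
  wf <- normalize_and_smooth(trials, fs = 1000)
  expect_lt(max(abs(wf$voltage)), 1e-12)
  expect_lt(abs(mean(wf$voltage[1:10])), 1e-12)

  set.seed(3)
  one <- matrix(rnorm(300), 1)
  two <- rbind(one, one)
  expect_equal(normalize_and_smooth(two, fs = 1000)$voltage,
               normalize_and_smooth(one, fs = 1000)$voltage)
  expect_error(normalize_and_smooth(matrix(1, 1, 5), fs = 1000),
               class = "dlamr_validation_error")
})

test_that("Gaussian smoothing spreads a delta and preserves its area", {
  x <- rep(0, 400)
  x[200] <- 1
  sm <- dlamr:::smooth_gaussian(x, 10)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  k <- dlamr:::gaussian_kernel(10)
  half <- (length(k) - 1) / 2
  expect_equal(sm[(200 - half):(200 + half)], k, tolerance = 1e-12)
})

test_that("component measurement does the stated arithmetic", {
  t_ms <- 0:399
  v <- rep(0, 400)
  v[61] <- -50e-6   # negativity at 60 ms
  v[121] <- 70e-6   # positivity at 120 ms
  wf <- structure(list(voltage = v, time_ms = t_ms, fs = 1000,
                       n_trials = 1, condition = "x"),
                  class = "vep_waveform")
  comp <- measure_components(wf)
  expect_equal(comp$negativity_V, -50e-6)
  expect_equal(comp$negativity_latency_ms, 60)
  expect_equal(comp$positivity_V, 70e-6)
  expect_equal(comp$magnitude_V, 120e-6)
  expect_lt(comp$negativity_latency_ms, comp$positivity_latency_ms)

  zero <- structure(list(voltage = rep(0, 400), time_ms = t_ms, fs = 1000,
                         n_trials = 1, condition = "x"),
                    class = "vep_waveform")
  expect_equal(measure_components(zero)$magnitude_V, 0)
})

test_that("components recover generator amplitudes within 5% (noise off)", {
  sim <- small_session(seed = 3, n_channels = 32, sink = 16, noise = FALSE,
                       block_s = 20)
  lfp <- preprocess_lfp(sim$session)
  tr <- extract_trials(lfp, sim$schedule, "monocular", 16, 300)
  wf <- normalize_and_smooth(tr)
  comp <- measure_components(wf, pos_window_ms = c(60, 250))
  # analytic expectation from the forward model
  prof <- dlamr:::csd_depth_profile(32, 16, 3)
  phi <- dlamr:::potential_from_csd(prof, 20)
  t_ms <- wf$time_ms
  g <- sim$truth$g_early[["monocular"]]
  gl <- sim$truth$g_late[["monocular"]]
  exp_v <- 150e-6 * phi[16] * (g * dlamr:::kernel_early_lfp(t_ms) +
                                 gl * dlamr:::kernel_late_lfp(t_ms))
  exp_v <- dlamr:::smooth_gaussian(exp_v - mean(exp_v[1:10]), 10)
  expect_gt(cor(wf$voltage, exp_v), 0.99)
  expect_lt(abs(comp$negativity_V / min(exp_v) - 1), 0.05)
})

test_that("component measurement ignores constant offsets added before normalization", {
  sim <- small_session(seed = 4, n_channels = 16, sink = 8, noise = FALSE)
  lfp <- preprocess_lfp(sim$session)
  tr <- extract_trials(lfp, sim$schedule, "monocular", 8, 300)
  c1 <- measure_components(normalize_and_smooth(tr),
                           pos_window_ms = c(60, 250))
  c2 <- measure_components(normalize_and_smooth(tr + 3e-4),
                           pos_window_ms = c(60, 250))
  expect_equal(c1$magnitude_V, c2$magnitude_V, tolerance = 1e-12)
})

test_that("phase-offset suppression shows up as a smaller negativity than monocular", {
  sim <- small_session(seed = 5, n_channels = 24, sink = 12, noise = FALSE,
                       block_s = 20)
  lfp <- preprocess_lfp(sim$session)
  comps <- lapply(c("monocular", "phase_offset"), function(cc) {
    measure_components(
      normalize_and_smooth(extract_trials(lfp, sim$schedule, cc, 12, 300)),
      pos_window_ms = c(60, 250))
  })
  expect_lt(abs(comps[[2]]$negativity_V), abs(comps[[1]]$negativity_V))
})

test_that("normalization to a reference level behaves and is order invariant", {
  tb <- tibble::tibble(level = c(0, 10, 20),
                       magnitude_V = c(50e-6, 100e-6, 25e-6))
  out <- normalize_to_reference(tb, 0)
  expect_equal(out$magnitude_norm, c(1, 2, 0.5))
  out2 <- normalize_to_reference(tb[c(3, 1, 2), ], 0)
  expect_equal(out2$magnitude_norm[order(out2$level)],
               out$magnitude_norm[order(out$level)])
  expect_error(normalize_to_reference(tibble::tibble(level = 0,
                                                     magnitude_V = 0), 0),
               class = "dlamr_validation_error")
})
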