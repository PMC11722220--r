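test_that("trough-to-peak latency is the stated sample arithmetic", {
  w <- rep(0, 60)
  w[21] <- -1
  w[31] <- 0.5
  expect_equal(trough_to_peak_ms(w, fs = 25000), 0.4)
  # constructed biphasic template with 0.32 ms separation (8 samples at 25 kHz)
  tmpl <- spike_template(0.32)
  expect_equal(trough_to_peak_ms(tmpl), 0.32, tolerance = 0.02)
  expect_error(trough_to_peak_ms(seq(1, 0, length.out = 10)),
               class = "dlamr_validation_error")
})

test_that("RS/FS classification respects the 0.4 ms boundary convention", {
  expect_identical(classify_unit(0.35), "FS")
  expect_identical(classify_unit(0.50), "RS")
  expect_warning(cls <- classify_unit(0.40), "boundary")
  expect_identical(cls, "RS")
  expect_error(classify_unit(-0.1), class = "dlamr_validation_error")
})

test_that("classification is perfect across the 0.2-0.8 ms template range", {
  t2ps <- setdiff(seq(0.2, 0.8, by = 0.04), 0.4)  # boundary tested separately
  measured <- vapply(t2ps, function(t2p) {
    trough_to_peak_ms(spike_template(t2p))
  }, numeric(1))
  cls <- vapply(measured, classify_unit, character(1))
  expect_identical(cls, ifelse(t2ps < 0.4, "FS", "RS"))
})

test_that("the PSTH obeys the 500-trial x2 scaling rule", {
  blocks <- data.frame(block_id = 1, condition = "monocular",
                       start_s = 10, end_s = 510)
  ev <- seq(10, 509, by = 1)
  sch <- stimulus_schedule(blocks, data.frame(block_id = 1, time_s = ev))
  expect_equal(length(ev), 500)
  spikes <- ev + 0.0505          # one spike in the 50 ms bin, every trial
  p <- compute_psth(spikes, sch, "monocular", T_trial_ms = 300)
  expect_equal(p$rate_hz[51], 1000)        # 500 spikes / (500 * 0.001 s)
  expect_equal(p$rate_hz[51], 500 * 2)     # the x2 rule at 500 trials
  expect_equal(sum(p$rate_hz[-51]), 0)

  none <- compute_psth(numeric(0), sch, "monocular", T_trial_ms = 300)
  expect_true(all(none$rate_hz == 0))
})

test_that("PSTH conserves spike count and recovers a homogeneous rate", {
  blocks <- data.frame(block_id = 1, condition = "monocular",
                       start_s = 0, end_s = 200)
  ev <- seq(0, 199, by = 1)
  sch <- stimulus_schedule(blocks, data.frame(block_id = 1, time_s = ev))
  set.seed(21)
  spikes <- sort(runif(rpois(1, 10 * 200), 0, 200))  # 10 Hz homogeneous
  p <- compute_psth(spikes, sch, "monocular", T_trial_ms = 500)
  in_win <- sum(vapply(ev, function(t0) {
    sum(spikes >= t0 & spikes < t0 + 0.5)
  }, numeric(1)))
  expect_equal(sum(p$rate_hz) * p$bin_ms / 1000, in_win / p$n_trials,
               tolerance = 1e-12)
  expect_equal(mean(p$rate_hz), 10,
               tolerance = 4 * sqrt(10 / (0.5 * 200)) / 10)
})

test_that("window rates average the half-open early and late windows", {
  mk <- function(rate) structure(list(rate_hz = rate, time_ms = 0:299,
                                      n_trials = 10, bin_ms = 1,
                                      condition = "x"),
                                 class = "psth")
  flat <- mk(rep(5, 300))
  wr <- window_rates(flat)
  expect_equal(wr$early_rate_hz, 5)
  expect_equal(wr$late_rate_hz, 5)

  early_only <- rep(0, 300)
  early_only[41:80] <- 20                 # bins 40..79 ms
  wr2 <- window_rates(mk(early_only))
  expect_equal(wr2$early_rate_hz, 20)
  expect_equal(wr2$late_rate_hz, 0)
  short <- structure(list(rate_hz = rep(1, 150), time_ms = 0:149,
                          n_trials = 10, bin_ms = 1, condition = "x"),
                     class = "psth")
  expect_error(window_rates(short), class = "dlamr_validation_error")
})

test_that("per-unit z-scores use the interblock baseline and flag silent units", {
  sch <- tiny_schedule()
  set.seed(3)
  spikes <- sort(runif(400, 0, 35))       # active everywhere
  z <- zscore_unit(spikes, sch)
  expect_false(z$excluded)
  expect_equal(z$z, (z$rate_hz - z$mean_hz) / z$sd_hz, tolerance = 1e-12)

  in_block_only <- sort(runif(100, 5.5, 14.5))
  expect_warning(z2 <- zscore_unit(in_block_only, sch), "silent")
  expect_true(z2$excluded)
  expect_null(z2$z)
})

test_that("unit laminar assignment uses the channel boundary table", {
  expect_identical(assign_unit_layer(-100), "L5")
  expect_identical(assign_unit_layer(200), "L2/3")
  expect_identical(assign_unit_layer(-500), "out")
})

test_that("group window rates recover the encoded condition sign pattern", {
  m <- simulate_window_experiment(31, n_subjects = 6, n_units = 15,
                                  block_s = 25)
  early <- colMeans(m$early)
  late <- colMeans(m$late)
  expect_gt(early[["concordant"]], early[["monocular"]])
  expect_gt(early[["monocular"]], early[["phase_offset"]])
  expect_equal(unname(which.max(late)), 4)   # orthogonal highest late
})
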