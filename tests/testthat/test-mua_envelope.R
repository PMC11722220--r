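test_that("common median referencing rejects common-mode and matches a brute-force oracle", {
  x <- matrix(rep(sin(1:500), 4), nrow = 4, byrow = TRUE)
  expect_lt(max(abs(common_median_reference(x))), 1e-12)

  y <- rbind(rep(5, 100), matrix(0, 3, 100))
  out <- common_median_reference(y)
  expect_lt(max(abs(out[1, ])), 1e-12)

  set.seed(12)
  z <- matrix(rnorm(8 * 1000), 8)
  ref <- common_median_reference(z)
  oracle <- z
  for (i in 1:8) oracle[i, ] <- oracle[i, ] - median(oracle[i, ])
  for (j in 1:1000) oracle[, j] <- oracle[, j] - median(oracle[, j])
  expect_equal(ref, oracle, tolerance = 1e-12)

  expect_error(common_median_reference(matrix(1, 1, 10)),
               class = "dlamr_validation_error")
})

test_that("the 60 Hz MUA notch attenuates 60 Hz by >= 10 dB and spares the spike band", {
  nt <- function(x) notch60_iir(matrix(x, 1), 25000)[1, ]
  expect_lte(sine_attenuation_db(nt, 60, 25000, dur_s = 1), -10)
  expect_lt(abs(sine_attenuation_db(nt, 600, 25000, dur_s = 1)), 1)
  expect_lt(abs(sine_attenuation_db(nt, 1000, 25000, dur_s = 1)), 1)
  expect_equal(nt(rep(0, 25000)), rep(0, 25000))
  expect_error(notch60_iir(matrix(0, 1, 100), fs = 1000),
               class = "dlamr_validation_error")
})

test_that("MUAe is nonnegative, zero for silence, and ~linear in spike rate", {
  z <- compute_muae(matrix(0, 2, 25000 * 2))
  expect_equal(max(abs(z$samples)), 0)
  expect_equal(z$fs, 1000)

  set.seed(5)
  env_at_rate <- function(r) {
    st <- sort(runif(r * 10, 0.1, 9.9))
    tr <- insert_template(rep(0, 25000 * 10), st, spike_template(0.6), 25000)
    mean(compute_muae(matrix(tr, 1))$samples)
  }
  m1 <- env_at_rate(10)
  m2 <- env_at_rate(20)
  expect_gt(m2 / m1, 1.8)
  expect_lt(m2 / m1, 2.2)
  expect_true(all(compute_muae(matrix(rnorm(50000, 0, 1e-5), 1))$samples >= 0))
})

test_that("sub-band signals do not leak into the envelope", {
  t <- seq(0, 1 - 1 / 25000, by = 1 / 25000)
  lo <- compute_muae(matrix(sin(2 * pi * 100 * t) * 1e-4, 1))
  inband <- compute_muae(matrix(sin(2 * pi * 1000 * t) * 1e-4, 1))
  mid <- 250:750
  expect_lt(20 * log10(mean(lo$samples[1, mid]) / mean(inband$samples[1, mid])),
            -20)
})

test_that("envelope is invariant to flipping the sign of the wide-band input", {
  set.seed(6)
  x <- matrix(rnorm(25000 * 2, 0, 1e-5), 1)
  a <- compute_muae(x)
  b <- compute_muae(-x)
  expect_equal(a$samples, b$samples, tolerance = 1e-12)
})

test_that("interblock z-scoring standardizes the baseline and is affine invariant", {
  sch <- tiny_schedule()
  set.seed(8)
  env <- matrix(abs(rnorm(2 * 40 * 1000, 1e-5, 2e-6)), 2)
  mu <- structure(list(samples = env, fs = 1000, z = NULL,
                       baseline_mean = NULL, baseline_sd = NULL),
                  class = "muae_trace")
  z1 <- zscore_interblock(mu, sch)
  idx <- dlamr:::interval_indices(sch$interblock, 1000, ncol(env))
  expect_lt(max(abs(rowMeans(z1$z[, idx]))), 1e-6)
  expect_lt(max(abs(apply(z1$z[, idx], 1, sd) - 1)), 1e-6)

  mu2 <- mu
  mu2$samples <- 3.2 * env + 5e-6
  z2 <- zscore_interblock(mu2, sch)
  expect_equal(z2$z, z1$z, tolerance = 1e-9)

  # a sample at mean + 1.96 SD scores exactly the significance bound
  m <- z1$baseline_mean[1]
  s <- z1$baseline_sd[1]
  mu3 <- mu
  probe <- 8 * 1000   # inside the first block, not the gray baseline
  mu3$samples[1, probe] <- m + 1.96 * s
  expect_equal(zscore_interblock(mu3, sch)$z[1, probe], 1.96,
               tolerance = 1e-9)

  flat <- mu
  flat$samples[1, ] <- 1e-5
  expect_error(zscore_interblock(flat, sch), class = "dlamr_validation_error")
})

test_that("condition responses difference to zero for identical conditions", {
  sch <- tiny_schedule(conditions = c("monocular", "concordant"))
  set.seed(9)
  tr <- rnorm(40 * 25000, 0, 5e-6)
  # identical spike trains in both blocks (same offsets within block)
  offs <- sort(runif(60, 0, 10))
  tr <- insert_template(tr, 5 + offs, spike_template(0.6), 25000)
  tr <- insert_template(tr, 20 + offs, spike_template(0.6), 25000)
  mu <- zscore_interblock(compute_muae(matrix(tr, 1)), sch)
  al <- laminar_alignment(1, 1, 20)
  resp <- condition_response(mu, sch, al,
                             conditions = c("monocular", "concordant"),
                             T_trial_ms = 300)
  dz <- resp$diff_vs_reference$dz[resp$diff_vs_reference$condition ==
                                    "concordant"]
  expect_lt(abs(mean(dz)), 0.2)   # no systematic difference
  zm <- resp$z_aligned$monocular[1, ]
  zc <- resp$z_aligned$concordant[1, ]
  expect_gt(cor(zm, zc), 0.8)     # same evoked structure
})

test_that("window means report the early and late windows separately", {
  # constructed response: z steps from 0 to 2 at 90 ms
  t_ms <- 0:299
  za <- matrix(rep(ifelse(t_ms >= 90, 2, 0), each = 2), nrow = 2, byrow = FALSE)
  resp <- structure(list(z_aligned = list(monocular = za),
                         layers = c("L4", "L5"), time_ms = t_ms),
                    class = "condition_response")
  wm <- window_means(resp)
  expect_equal(wm$early, 0)
  expect_equal(wm$late, 2)

  ones <- structure(list(z_aligned = list(monocular = za * 0 + 1),
                         layers = c("L4", "L5"), time_ms = t_ms),
                    class = "condition_response")
  wm1 <- window_means(ones)
  expect_equal(wm1$early, 1)
  expect_equal(wm1$late, 1)
  expect_error(window_means(ones, early_ms = c(400, 440)),
               class = "dlamr_validation_error")
})
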