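# independent Greenhouse-Geisser oracle: the classic elementwise formula on
# the raw condition covariance
gg_epsilon_oracle <- function(x) {
  S <- cov(x)
  k <- ncol(x)
  s_bar <- mean(S)
  d_bar <- mean(diag(S))
  row_bar <- rowMeans(S)
  num <- (k * (d_bar - s_bar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_bar^2) + k^2 * s_bar^2)
  num / den
}

# brute-force within-subject F from explicit sums of squares
rm_f_oracle <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  gm <- mean(x)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(x[, j]) - gm)^2
  ss_err <- 0
  for (i in 1:n) for (j in 1:k) {
    ss_err <- ss_err + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + gm)^2
  }
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

test_that("identical condition values give F = 0 and p = 1", {
  x <- matrix(rep(rnorm(6), 4), nrow = 6)
  fit <- rm_anova_oneway(x)
  expect_equal(fit$F, 0)
  expect_equal(fit$p_value, 1)
})

test_that("F and epsilon match brute-force oracles to 1e-10 on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(40), 10, 4)
    fit <- rm_anova_oneway(x)
    expect_equal(fit$F, rm_f_oracle(x), tolerance = 1e-10)
    expect_equal(fit$epsilon, gg_epsilon_oracle(x), tolerance = 1e-10)
    expect_gte(fit$epsilon, 1 / 3)
    expect_lte(fit$epsilon, 1)
  }
})

test_that("results agree with car's repeated-measures machinery", {
  skip_if_not_installed("car")
  set.seed(9)
  x <- matrix(rnorm(40), 10, 4)
  colnames(x) <- paste0("c", 1:4)
  fit <- rm_anova_oneway(x)
  m <- stats::lm(x ~ 1)
  av <- car::Anova(m, idata = data.frame(cond = factor(colnames(x))),
                   idesign = ~cond, type = 3)
  s <- summary(av, multivariate = FALSE)
  expect_equal(fit$F, unname(s$univariate.tests["cond", "F value"]),
               tolerance = 1e-8)
  expect_equal(fit$epsilon, unname(s$pval.adjustments["cond", "GG eps"]),
               tolerance = 1e-8)
  expect_equal(fit$p_value, unname(s$pval.adjustments["cond", "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("epsilon hits 1 under compound symmetry and its lower bound under rank-1 structure", {
  set.seed(11)
  subj <- rnorm(300)
  x <- outer(subj, rep(1, 4)) + matrix(rnorm(1200), 300)
  expect_gt(rm_anova_oneway(x)$epsilon, 0.95)
  # rank-one deviation: all variance on one contrast attains 1/(k-1)
  z <- rnorm(20)
  y <- outer(z, c(1, -1, 0, 0)) + outer(rnorm(20), rep(1, 4))
  expect_equal(rm_anova_oneway(y)$epsilon, 1 / 3, tolerance = 1e-10)
})

test_that("rm_anova_oneway rejects degenerate designs", {
  expect_error(rm_anova_oneway(matrix(rnorm(4), 4, 1)),
               class = "dlamr_validation_error")
  expect_error(rm_anova_oneway(matrix(rnorm(4), 1, 4)),
               class = "dlamr_validation_error")
  x <- matrix(rnorm(12), 3, 4)
  x[2, 3] <- NA
  expect_error(rm_anova_oneway(x), class = "dlamr_validation_error")
})

test_that("Sidak adjustment matches its closed form and stays monotone", {
  expect_equal(sidak_adjust(0.01, 6), 1 - 0.99^6)
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  expect_equal(sidak_adjust(1, 4), 1)
  set.seed(2)
  p <- sort(runif(20))
  expect_true(all(diff(sidak_adjust(p, 20)) >= 0))
  expect_error(sidak_adjust(1.2, 2), class = "dlamr_validation_error")
})

test_that("paired contrasts handle identity, degeneracy, and match t.test", {
  x <- matrix(rnorm(24), 8, 3)
  colnames(x) <- c("a", "b", "c")
  x[, 2] <- x[, 1]
  out <- suppressWarnings(
    paired_contrasts(x, list(c("a", "b"), c("a", "c"))))
  expect_equal(out$statistic[1], 0)
  expect_equal(out$p.adjusted[1], 1)
  expect_true(out$degenerate[1])
  tt <- t.test(x[, "a"], x[, "c"], paired = TRUE)
  expect_equal(out$statistic[2], unname(tt$statistic))
  expect_equal(out$p.adjusted[2], sidak_adjust(tt$p.value, 2))

  y <- x
  y[, 2] <- y[, 1] + 1        # constant shift, zero within-pair variance
  outd <- suppressWarnings(paired_contrasts(y, list(c("a", "b"))))
  expect_true(outd$degenerate[1])
  expect_true(is.na(outd$p.value[1]))
})

test_that("paired-contrast power at a 1 SD shift matches normal theory", {
  closed <- power.t.test(n = 12, delta = 1, sd = 1, sig.level = 0.05,
                         type = "one.sample")$power
  set.seed(4)
  nrep <- 400
  hits <- 0
  for (i in seq_len(nrep)) {
    d <- rnorm(12, 1, 1)         # within-pair differences ~ N(1, 1)
    x <- cbind(a = d, b = 0)
    out <- paired_contrasts(x, list(c("a", "b")))
    if (out$p.adjusted[1] < 0.05) hits <- hits + 1
  }
  phat <- hits / nrep
  ci <- 1.96 * sqrt(closed * (1 - closed) / nrep)
  expect_lt(abs(phat - closed), ci + 0.02)
})

test_that("type-I error of the RM-ANOVA is calibrated under a Gaussian null", {
  set.seed(5)
  nrep <- 400
  rej <- 0
  for (i in seq_len(nrep)) {
    x <- matrix(rnorm(40), 10, 4)
    if (rm_anova_oneway(x)$p_value < 0.05) rej <- rej + 1
  }
  # GG correction is mildly conservative at n = 10; accept [0.01, 0.07]
  expect_gt(rej / nrep, 0.01)
  expect_lt(rej / nrep, 0.07)
})

test_that("tidy and glance return one-row summaries", {
  x <- matrix(rnorm(40), 10, 4)
  fit <- rm_anova_oneway(x)
  td <- tidy(fit)
  expect_equal(nrow(td), 1)
  expect_named(td, c("term", "statistic", "df", "df_error", "epsilon",
                     "p.value"))
  gl <- glance(fit)
  expect_equal(gl$statistic, fit$F)
  expect_equal(gl$n_subjects, 10)
})
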