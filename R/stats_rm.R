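# One-way repeated-measures ANOVA with Greenhouse-Geisser sphericity
# correction, plus Sidak-adjusted paired contrasts — the inferential stage
# applied to per-subject condition means throughout the package.

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subject decomposition: with `n` subjects and `k`
#' conditions, `SS_cond = n * sum_j (m_.j - m)^2` on `k - 1` df and
#' `SS_err = sum_ij (x_ij - m_i. - m_.j + m)^2` on `(k - 1)(n - 1)` df.
#' The Greenhouse-Geisser epsilon is computed from the double-centered
#' sample covariance `S~` of the condition columns,
#' `eps = tr(S~)^2 / ((k - 1) * tr(S~ %*% S~))`, bounded in
#' `[1/(k - 1), 1]`, and scales both degrees of freedom before the F
#' p-value is taken.
#'
#' @param data numeric subjects x conditions matrix (or data frame), no
#'   missing cells.
#' @return an `rm_anova` object; see [tidy.rm_anova()] and
#'   [glance.rm_anova()].
#' @export
rm_anova_oneway <- function(data) {
  x <- as.matrix(data)
  if (anyNA(x)) {
    abort("Missing cells are not supported; every subject needs every condition.",
          class = "dlamr_validation_error")
  }
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L) abort("Need at least 2 subjects.", class = "dlamr_validation_error")
  if (k < 2L) abort("Need at least 2 conditions.", class = "dlamr_validation_error")
  gm <- mean(x)
  m_subj <- rowMeans(x)
  m_cond <- colMeans(x)
  ss_cond <- n * sum((m_cond - gm)^2)
  resid <- x - outer(m_subj, rep(1, k)) - outer(rep(1, n), m_cond) + gm
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f_stat <- if (ms_err == 0) {
    if (ms_cond == 0) 0 else Inf
  } else ms_cond / ms_err
  # Greenhouse-Geisser epsilon from the double-centered condition covariance
  S <- stats::cov(x)
  Ctr <- diag(k) - 1 / k
  St <- Ctr %*% S %*% Ctr
  tr1 <- sum(diag(St))
  tr2 <- sum(St * St)                   # tr(St %*% St), St symmetric
  eps <- if (tr2 <= 0) 1 else tr1^2 / (df1 * tr2)
  eps <- min(1, max(1 / df1, eps))
  p <- if (!is.finite(f_stat)) 0 else pf(f_stat, eps * df1, eps * df2,
                                         lower.tail = FALSE)
  if (f_stat == 0) p <- 1
  structure(
    list(F = f_stat, df1 = df1, df2 = df2, epsilon = eps,
         df1_corrected = eps * df1, df2_corrected = eps * df2,
         p_value = p, n_subjects = n, k_conditions = k,
         ss_cond = ss_cond, ss_err = ss_err,
         condition_means = m_cond),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("One-way RM-ANOVA: F(%.3g, %.3g) = %.4g, p = %.4g (GG eps = %.3f; n = %d, k = %d)\n",
              x$df1_corrected, x$df2_corrected, x$F, x$p_value,
              x$epsilon, x$n_subjects, x$k_conditions))
  invisible(x)
}

#' Tidy an RM-ANOVA fit
#'
#' @param x an `rm_anova`.
#' @param ... unused.
#' @return one-row tibble of term-level results.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(term = "condition",
         statistic = x$F,
         df = x$df1_corrected,
         df_error = x$df2_corrected,
         epsilon = x$epsilon,
         p.value = x$p_value)
}

#' One-row model summary of an RM-ANOVA fit
#'
#' @param x an `rm_anova`.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(statistic = x$F, p.value = x$p_value, epsilon = x$epsilon,
         df = x$df1_corrected, df_error = x$df2_corrected,
         n_subjects = x$n_subjects, k_conditions = x$k_conditions)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to 1: the exact family-wise correction
#' for `m` independent comparisons.
#'
#' @param p_values raw p values in `[0, 1]`.
#' @param m family size, default the number of p values.
#' @return adjusted p values.
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p values must lie in [0, 1].", class = "dlamr_validation_error")
  }
  if (m < 1) abort("Family size must be >= 1.", class = "dlamr_validation_error")
  pmin(1, 1 - (1 - p_values)^m)
}

#' Paired contrasts with Sidak family-wise adjustment
#'
#' Paired t tests between the requested condition pairs, adjusted over the
#' family of requested comparisons. A pair whose within-subject differences
#' have zero variance is degenerate and returned with `NA` statistics and a
#' `degenerate` flag instead of a fabricated p value.
#'
#' @param data subjects x conditions matrix or data frame with named columns.
#' @param pairs list of length-2 character vectors (condition names) or
#'   2-column matrix of column indices.
#' @return tibble: `contrast`, `estimate` (mean difference), `statistic`,
#'   `df`, `p.value`, `p.adjusted`, `degenerate`.
#' @export
paired_contrasts <- function(data, pairs) {
  x <- as.matrix(data)
  if (is.matrix(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
  m <- length(pairs)
  rows <- purrr::map_dfr(pairs, function(pr) {
    if (length(pr) != 2L || (is.character(pr) && pr[1L] == pr[2L])) {
      abort("Each pair must reference two distinct conditions.",
            class = "dlamr_validation_error")
    }
    a <- x[, pr[1L]]
    b <- x[, pr[2L]]
    d <- a - b
    nm <- if (is.character(pr)) paste(pr, collapse = " - ") else
      paste(pr, collapse = " - ")
    if (sd(d) == 0) {
      warn(sprintf("Contrast %s has zero within-pair variance: degenerate.", nm))
      if (all(d == 0)) {
        # identical columns: no evidence of any difference
        return(tibble(contrast = nm, estimate = 0, statistic = 0,
                      df = length(d) - 1, p.value = 1, degenerate = TRUE))
      }
      return(tibble(contrast = nm, estimate = mean(d), statistic = NA_real_,
                    df = length(d) - 1, p.value = NA_real_, degenerate = TRUE))
    }
    tt <- tryCatch(t.test(a, b, paired = TRUE), error = function(e) NULL)
    if (is.null(tt)) {
      # numerically constant differences: same treatment as zero variance
      warn(sprintf("Contrast %s is numerically degenerate.", nm))
      return(tibble(contrast = nm, estimate = mean(d), statistic = NA_real_,
                    df = length(d) - 1, p.value = NA_real_, degenerate = TRUE))
    }
    tibble(contrast = nm, estimate = unname(tt$estimate),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p.value = tt$p.value, degenerate = FALSE)
  })
  rows$p.adjusted <- ifelse(is.na(rows$p.value), NA_real_,
                            sidak_adjust(ifelse(is.na(rows$p.value), 0,
                                                rows$p.value), m))
  rows
}
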