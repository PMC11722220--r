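# Calcium pipeline: neuropil correction (F_roi - 0.7 * F_np), dF/F relative
# to the average interblock gray fluorescence, the >= 100 ROI session QC
# rule, and per-ROI / population condition aggregates.

#' Neuropil-corrected fluorescence
#'
#' Estimated true somatic fluorescence: the measured ROI fluorescence minus
#' 7/10ths of the surrounding-neuropil fluorescence.
#'
#' @param F_roi ROI trace (vector) or ROIs x frames matrix.
#' @param F_np matching neuropil trace(s).
#' @param coefficient neuropil contamination coefficient, default 0.7.
#' @return corrected trace(s), same shape as the input.
#' @export
neuropil_correct <- function(F_roi, F_np, coefficient = 0.7) {
  if (!identical(dim(F_roi), dim(F_np)) ||
      (is.null(dim(F_roi)) && length(F_roi) != length(F_np))) {
    abort("F_roi and F_np must have the same shape.",
          class = "dlamr_validation_error")
  }
  F_roi - coefficient * F_np
}

#' Fractional fluorescence change relative to interblock gray
#'
#' `(F(t) - F_avg_gray) / F_avg_gray` with `F_avg_gray` the mean
#' fluorescence over all interblock (gray screen) frames of the session.
#'
#' @param F_true corrected trace (vector) or ROIs x frames matrix.
#' @param schedule a `stimulus_schedule` on the imaging clock.
#' @param frame_rate imaging frame rate in Hz.
#' @return dF/F, same shape as the input.
#' @export
dff_vs_gray <- function(F_true, schedule, frame_rate) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (nrow(schedule$interblock) < 1L) {
    abort("Schedule has no interblock (gray) intervals.",
          class = "dlamr_validation_error")
  }
  x <- if (is.null(dim(F_true))) matrix(F_true, nrow = 1L) else F_true
  idx <- interval_indices(schedule$interblock, frame_rate, ncol(x))
  if (!length(idx)) {
    abort("No frames fall inside the interblock intervals.",
          class = "dlamr_validation_error")
  }
  f0 <- rowMeans(x[, idx, drop = FALSE])
  if (any(f0 <= 0)) {
    abort("Nonpositive gray-period baseline fluorescence.",
          class = "dlamr_validation_error")
  }
  out <- (x - f0) / f0
  if (is.null(dim(F_true))) as.numeric(out) else out
}

#' Session-level ROI-count quality control
#'
#' Sessions with fewer than 100 curated ROIs in the field of view indicate
#' excessive noise and are excluded.
#'
#' @param roi_count number of ROIs (>= 0).
#' @param min_rois inclusion threshold, default 100.
#' @return `"include"` or `"exclude"` (decision also emitted as a message).
#' @export
qc_session <- function(roi_count, min_rois = 100) {
  if (roi_count < 0) {
    abort("ROI count cannot be negative.", class = "dlamr_validation_error")
  }
  decision <- if (roi_count < min_rois) "exclude" else "include"
  inform(sprintf("QC: %d ROIs -> %s (threshold %d).",
                 roi_count, decision, min_rois))
  decision
}

#' Per-ROI and population condition responses
#'
#' For every requested condition, the per-ROI mean evoked dF/F is the mean
#' over all in-block frames across all blocks of that condition (blocks are
#' equal length by design, so all blocks weigh equally). The population mean
#' is the mean over ROIs.
#'
#' @param dff ROIs x frames dF/F matrix.
#' @param schedule a `stimulus_schedule`.
#' @param frame_rate imaging frame rate in Hz.
#' @param conditions conditions required, default the four dichoptic ones.
#' @param roi_id optional ROI identifiers.
#' @return list of tibbles: `by_roi` (`roi_id`, `condition`, `mean_dff`),
#'   `population` (`condition`, `mean_dff`, `sem_dff`, `n_roi`), and
#'   `block_timecourse` (`condition`, `time_s`, `mean_dff`) — the average
#'   block-aligned time course over ROIs and blocks.
#' @export
condition_responses <- function(dff, schedule, frame_rate,
                                conditions = c("monocular", "concordant",
                                               "phase_offset", "orthogonal"),
                                roi_id = NULL) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (is.null(dim(dff))) dff <- matrix(dff, nrow = 1L)
  present <- unique(schedule$blocks$condition)
  missing <- setdiff(conditions, present)
  if (length(missing)) {
    abort(sprintf("Condition(s) missing from schedule: %s",
                  paste(missing, collapse = ", ")),
          class = "dlamr_validation_error")
  }
  roi_id <- roi_id %||% paste0("roi", seq_len(nrow(dff)))
  n <- ncol(dff)
  by_roi <- purrr::map_dfr(conditions, function(cond) {
    bl <- schedule$blocks[schedule$blocks$condition == cond, ]
    idx <- interval_indices(bl, frame_rate, n)
    tibble(roi_id = roi_id, condition = cond,
           mean_dff = rowMeans(dff[, idx, drop = FALSE]))
  })
  population <- by_roi |>
    group_by(.data$condition) |>
    summarise(sem_dff = sd(.data$mean_dff) / sqrt(dplyr::n()),
              mean_dff = mean(.data$mean_dff),
              n_roi = dplyr::n(), .groups = "drop") |>
    dplyr::select("condition", "mean_dff", "sem_dff", "n_roi")
  block_len <- min(floor((schedule$blocks$end_s - schedule$blocks$start_s) *
                           frame_rate))
  block_timecourse <- purrr::map_dfr(conditions, function(cond) {
    bl <- schedule$blocks[schedule$blocks$condition == cond, ]
    acc <- numeric(block_len)
    nb <- 0L
    for (i in seq_len(nrow(bl))) {
      a <- floor(bl$start_s[i] * frame_rate) + 1L
      if (a + block_len - 1L <= n) {
        acc <- acc + colMeans(dff[, a:(a + block_len - 1L), drop = FALSE])
        nb <- nb + 1L
      }
    }
    tibble(condition = cond,
           time_s = (seq_len(block_len) - 1L) / frame_rate,
           mean_dff = acc / nb)
  })
  list(by_roi = by_roi, population = population,
       block_timecourse = block_timecourse)
}

#' Full calcium pipeline for one session
#'
#' Neuropil correction, dF/F versus interblock gray, QC, and condition
#' aggregation in one call.
#'
#' @param traces a `roi_trace_set`.
#' @param conditions conditions to aggregate.
#' @param np_coefficient neuropil coefficient, default 0.7.
#' @param min_rois QC threshold, default 100.
#' @return list: `qc` decision, `dff` matrix, and the tibbles of
#'   [condition_responses()] (`NULL` when the session is excluded).
#' @export
analyze_calcium_session <- function(traces,
                                    conditions = c("monocular", "concordant",
                                                   "phase_offset",
                                                   "orthogonal"),
                                    np_coefficient = 0.7, min_rois = 100) {
  stopifnot(inherits(traces, "roi_trace_set"))
  qc <- qc_session(nrow(traces$F_roi), min_rois = min_rois)
  F_true <- neuropil_correct(traces$F_roi, traces$F_np, np_coefficient)
  dff <- dff_vs_gray(F_true, traces$schedule, traces$frame_rate)
  resp <- NULL
  if (qc == "include") {
    resp <- condition_responses(dff, traces$schedule, traces$frame_rate,
                                conditions, roi_id = traces$roi_id)
  }
  c(list(qc = qc, dff = dff), resp)
}
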