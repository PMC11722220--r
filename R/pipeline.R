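# End-to-end orchestration: simulate (or accept) a session, condition the
# LFP, align layers by CSD, measure VEP components, compute MUAe condition
# responses, windowed unit statistics, calcium condition responses, and the
# repeated-measures inference, under a single validated config with a
# recorded hash for reproducibility.

pipeline_config_keys <- c("seed", "params", "n_units", "rs_fraction",
                          "base_rate_hz", "T_trial_ms", "early_ms", "late_ms",
                          "vep_neg_window_ms", "vep_pos_window_ms",
                          "csd_pre_ms", "csd_baseline_ms", "csd_search_ms", "csd_k",
                          "calcium", "run_muae", "run_calcium", "out_dir")

#' Build and validate a pipeline configuration
#'
#' Every tunable of the analysis chain lives here, with the protocol values
#' as defaults. Unknown keys are rejected.
#'
#' @param seed global seed; fans out to per-stream child seeds.
#' @param params generator parameters from [session_params()].
#' @param n_units,rs_fraction,base_rate_hz synthetic unit population.
#' @param T_trial_ms trial window (ms).
#' @param early_ms,late_ms analysis windows (ms).
#' @param vep_neg_window_ms,vep_pos_window_ms VEP component search windows.
#' @param csd_pre_ms pre-reversal stretch included in the CSD trial
#'   average (baseline for sink detection).
#' @param csd_baseline_ms,csd_search_ms,csd_k sink-detection settings.
#' @param calcium list of arguments forwarded to [generate_calcium()].
#' @param run_muae,run_calcium stage switches (MUAe requires 25 kHz data).
#' @param out_dir optional directory for result tables.
#' @param ... rejected: unknown keys are configuration errors.
#' @return a validated `pipeline_config` list with a stable `hash`.
#' @export
pipeline_config <- function(seed = 1, params = session_params(),
                            n_units = 20, rs_fraction = 0.8,
                            base_rate_hz = 5, T_trial_ms = 300,
                            early_ms = c(40, 80), late_ms = c(100, 200),
                            vep_neg_window_ms = c(25, 100),
                            vep_pos_window_ms = c(60, 250),
                            csd_pre_ms = 300, csd_baseline_ms = c(-250, 0),
                            csd_search_ms = c(20, 120), csd_k = 2,
                            calcium = list(), run_muae = TRUE,
                            run_calcium = TRUE, out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(sprintf("Unknown config key(s): %s",
                  paste(names(extra), collapse = ", ")),
          class = "dlamr_validation_error")
  }
  cfg <- mget(pipeline_config_keys, envir = environment())
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, log_env, expr) {
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "dlamr_stage_error")
  })
  log_env$log <- bind_rows(log_env$log,
                           tibble(stage = name, output_hash = rlang::hash(res)))
  res
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Stages: simulate -> LFP preprocessing -> CSD/laminar alignment -> VEP
#' components -> MUAe condition responses -> unit window statistics ->
#' RM-ANOVA + Sidak contrasts -> calcium condition responses. Each stage's
#' output hash is logged; reruns with the same config are bit-identical.
#'
#' @param config a `pipeline_config`.
#' @return list with elements `alignment`, `vep`, `muae_windows`,
#'   `unit_stats`, `anova_early`, `anova_late`, `contrasts_early`,
#'   `contrasts_late`, `calcium`, `truth`, `log`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  lg <- new.env()
  lg$log <- tibble(stage = character(), output_hash = character())
  p <- config$params
  sim <- run_stage("simulate", lg,
                   generate_session(p, seed = config$seed))
  gen_units <- run_stage("simulate_units", lg,
                         generate_units(p, sim$schedule, seed = config$seed,
                                        n_units = config$n_units,
                                        rs_fraction = config$rs_fraction,
                                        base_rate_hz = config$base_rate_hz))
  if (config$run_muae && p$fs == 25000) {
    sim$session <- run_stage("embed_spikes", lg,
                             insert_spike_templates(sim$session,
                                                    gen_units$units,
                                                    sim$truth))
  }
  lfp <- run_stage("lfp_preprocess", lg, preprocess_lfp(sim$session))
  align <- run_stage("csd_alignment", lg, {
    all_events <- sort(sim$schedule$events$time_s)
    pre <- round(config$csd_pre_ms / 1000 * lfp$fs)
    n_samp <- pre + round(config$T_trial_ms / 1000 * lfp$fs)
    avg <- align_average(lfp$samples, lfp$fs, all_events - config$csd_pre_ms / 1000,
                         n_samp)
    csd <- compute_csd(avg, p$spacing_um, fs = lfp$fs,
                       t_start_ms = -config$csd_pre_ms)
    l4 <- find_l4_sink(csd, config$csd_baseline_ms, config$csd_search_ms,
                       config$csd_k)
    laminar_alignment(l4, p$n_channels, p$spacing_um)
  })
  vep <- run_stage("vep", lg, {
    purrr::map_dfr(p$conditions, function(cond) {
      tr <- extract_trials(lfp, sim$schedule, cond, align$l4_channel,
                           config$T_trial_ms)
      wf <- normalize_and_smooth(tr)
      measure_components(wf, config$vep_neg_window_ms,
                         pmin(config$vep_pos_window_ms, config$T_trial_ms))
    })
  })
  muae_windows <- NULL
  if (config$run_muae && p$fs == 25000) {
    muae_windows <- run_stage("muae", lg, {
      ref <- common_median_reference(sim$session$samples)
      ref <- notch60_iir(ref, fs = p$fs)
      mu <- compute_muae(ref, fs = p$fs)
      mu <- zscore_interblock(mu, sim$schedule)
      resp <- condition_response(mu, sim$schedule, align,
                                 conditions = p$conditions,
                                 T_trial_ms = config$T_trial_ms)
      window_means(resp, config$early_ms, config$late_ms)
    })
  }
  unit_stats <- run_stage("unit_stats", lg,
                          unit_condition_stats(gen_units$units, sim$schedule,
                                               conditions = p$conditions,
                                               T_trial_ms = config$T_trial_ms))
  stats_out <- run_stage("stats", lg, {
    wide_e <- tidyr::pivot_wider(unit_stats[c("unit_id", "condition",
                                              "early_rate_hz")],
                                 names_from = "condition",
                                 values_from = "early_rate_hz")
    wide_l <- tidyr::pivot_wider(unit_stats[c("unit_id", "condition",
                                              "late_rate_hz")],
                                 names_from = "condition",
                                 values_from = "late_rate_hz")
    me <- as.matrix(wide_e[p$conditions])
    ml <- as.matrix(wide_l[p$conditions])
    prs <- lapply(setdiff(p$conditions, "monocular"),
                  function(cc) c(cc, "monocular"))
    list(anova_early = rm_anova_oneway(me),
         anova_late = rm_anova_oneway(ml),
         contrasts_early = paired_contrasts(me, prs),
         contrasts_late = paired_contrasts(ml, prs))
  })
  calcium <- NULL
  if (config$run_calcium) {
    calcium <- run_stage("calcium", lg, {
      gc_args <- c(list(seed = config$seed), config$calcium)
      gen <- do.call(generate_calcium, gc_args)
      analyze_calcium_session(gen$traces,
                              conditions = names(gen$truth$gains))
    })
  }
  out <- list(alignment = align, vep = vep, muae_windows = muae_windows,
              unit_stats = unit_stats,
              anova_early = stats_out$anova_early,
              anova_late = stats_out$anova_late,
              contrasts_early = stats_out$contrasts_early,
              contrasts_late = stats_out$contrasts_late,
              calcium = calcium, truth = sim$truth, log = lg$log,
              config_hash = config$hash)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(out$vep, file.path(config$out_dir, "vep_components.csv"))
    write_table(out$unit_stats, file.path(config$out_dir, "unit_stats.csv"))
    if (!is.null(out$muae_windows)) {
      write_table(out$muae_windows,
                  file.path(config$out_dir, "muae_windows.csv"))
    }
    jsonlite::write_json(
      list(l4_channel = align$l4_channel, depth_um = align$depth_um,
           layer = align$layer, config_hash = config$hash,
           seed = config$seed),
      file.path(config$out_dir, "alignment.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}
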