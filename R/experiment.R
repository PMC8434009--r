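#' Full experiment configuration
#'
#' One flat configuration driving the end-to-end simulated experiment:
#' paradigm constants, pipeline parameters, quality-control thresholds,
#' response template, noise model, ERP peak-measurement policy, and the one
#' master seed from which every stage seed is derived.
#'
#' @param paradigm A [paradigm_config()].
#' @param pipeline A [pipeline_config()].
#' @param qc A [qc_config()].
#' @param template An [erp_template()].
#' @param noise A [noise_model()].
#' @param n_training_selections Training selections (one 30-flash-per-button
#'   selection each; targets cycle over the buttons). Seven by default, one
#'   per directional button, the usual calibration volume for this design.
#' @param peak_window_ms P300 search window for the ERP analysis.
#' @param peak_channel Channel policy for peak measurement (default `"Pz"`).
#' @param seed Master integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(paradigm = paradigm_config(),
                       pipeline = pipeline_config(),
                       qc = qc_config(),
                       template = erp_template(),
                       noise = noise_model(),
                       n_training_selections = 7L,
                       peak_window_ms = c(250, 600),
                       peak_channel = "Pz",
                       seed = 1L) {
  structure(list(
    paradigm = paradigm, pipeline = pipeline, qc = qc,
    template = template, noise = noise,
    n_training_selections = as.integer(n_training_selections),
    peak_window_ms = peak_window_ms,
    peak_channel = peak_channel,
    seed = as.integer(seed)
  ), class = "run_config")
}

# Simulate one selection's recording: schedule + noise (+ artifacts).
simulate_selection <- function(config, n_blinks, target, sched_seed, noise_seed,
                               selection_id, environment = "NA") {
  sched <- generate_flash_schedule(config$paradigm, n_blinks, target,
                                   sched_seed, selection_id, environment)
  noise <- config$noise
  noise$seed <- noise_seed
  rec <- synthesize_recording(sched, config$template, noise, config$paradigm)
  inject_artifacts(rec, noise)
}

#' Simulate a training session and train the classifier
#'
#' Simulates `n_training_selections` selections of
#' `paradigm$blinks_training` flashes per button (targets cycling over the
#' buttons), runs the preprocessing pipeline in sliding-average mode (30
#' flashes per button yield 11 averaged exemplars per button per selection),
#' and trains the shrinkage LDA.
#'
#' @param config A [run_config()].
#' @return List with the `bci_lda` `model` and the training `features`.
#' @export
train_session <- function(config) {
  pcfg <- config$pipeline
  pcfg$avg_mode <- "sliding"
  sets <- lapply(seq_len(config$n_training_selections), function(i) {
    rec <- simulate_selection(
      config, config$paradigm$blinks_training,
      target = (i - 1) %% config$paradigm$n_buttons,
      sched_seed = derive_seed(config$seed, i),
      noise_seed = derive_seed(config$seed, 1000 + i),
      selection_id = sprintf("T%02d", i)
    )
    run_pipeline(rec, pcfg)
  })
  features <- bind_epochs(sets)
  list(model = train_lda(features), features = features)
}

# Decode + QC one online recording. Returns the selection result, the QC
# contamination flag, and (optionally) the zero-phase single-flash target
# epochs for ERP analysis.
process_online_selection <- function(rec, model, config, keep_erp = TRUE) {
  pcfg <- config$pipeline
  rec_r <- rereference(rec)
  rec_f <- bandpass(rec_r, pcfg)
  ep <- baseline_correct(extract_epochs(rec_f, pcfg))
  bad <- flag_bad_epochs(ep, config$qc)
  contaminated <- flag_contaminated_selection(bad, config$qc)
  bcfg <- pcfg
  bcfg$avg_mode <- "block"
  feats <- resample_epochs(consecutive_average(ep, bcfg), bcfg)
  sc <- score_epochs(model, feats)
  res <- decide_selection(sc, feats$button,
                          true_button = schedule_target(rec$schedule),
                          n_buttons = config$paradigm$n_buttons)
  erp_targets <- NULL
  if (keep_erp) {
    # zero-phase path for waveform analysis: no filter group delay;
    # amplitude-flagged epochs are excluded from the average, as the
    # rejection rules prescribe for analysis
    zcfg <- pcfg
    zcfg$causal_filtering <- FALSE
    epz <- baseline_correct(extract_epochs(bandpass(rec_r, zcfg), zcfg))
    tsel <- which(epz$is_target & !flag_bad_epochs(epz, config$qc))
    erp_targets <- resample_epochs(
      new_epoch_set(epz$epochs[tsel, , , drop = FALSE], epz$button[tsel],
                    epz$is_target[tsel], epz$selection_id[tsel],
                    epz$environment[tsel], epz$sampling_rate_hz,
                    epz$channel_labels),
      zcfg)
  }
  list(result = res, bad = bad, contaminated = contaminated,
       erp_targets = erp_targets)
}

#' Run the full simulated experiment end to end
#'
#' Simulates a training session, trains the classifier, then simulates
#' `selections_per_env` online selections (20 flashes per button, random
#' targets) in each of the VR and AR environments — the environments differ
#' only through independent noise seeds — decodes every selection by summed
#' discriminant score, applies the three-level quality control, and measures
#' the P300 peak on each environment's 300-flash average ERP. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `summary.json` and
#'   the resolved configuration `config.yaml` there.
#' @return A `bci_experiment` summary: per-environment accuracy, per-selection
#'   results, QC report, ERP peak measures, and the seeds used.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL) {
  tr <- train_session(config)
  envs <- c("VR", "AR")
  env_summ <- list()
  for (k in seq_along(envs)) {
    env <- envs[k]
    results <- list()
    contaminated <- logical(0)
    erp_sets <- list()
    per_sel <- list()
    for (s in seq_len(config$paradigm$selections_per_env)) {
      off <- 10000 * k
      target <- with_seed(derive_seed(config$seed, off + s),
                          sample.int(config$paradigm$n_buttons, 1) - 1L)
      rec <- simulate_selection(
        config, config$paradigm$blinks_online, target,
        sched_seed = derive_seed(config$seed, off + 100 + s),
        noise_seed = derive_seed(config$seed, off + 200 + s),
        selection_id = sprintf("%s%02d", env, s), environment = env)
      pr <- process_online_selection(rec, tr$model, config, keep_erp = TRUE)
      results[[s]] <- pr$result
      contaminated[s] <- pr$contaminated
      erp_sets[[s]] <- pr$erp_targets
      per_sel[[s]] <- data.frame(
        selection_id = sprintf("%s%02d", env, s), environment = env,
        true = pr$result$true_button, predicted = pr$result$predicted_button,
        correct = pr$result$true_button == pr$result$predicted_button,
        n_bad_epochs = sum(pr$bad), contaminated = pr$contaminated,
        stringsAsFactors = FALSE)
    }
    erp <- average_target_erp(bind_epochs(erp_sets), environment = env)
    peak <- find_p300_peak(erp, config$peak_window_ms, config$peak_channel)
    env_summ[[env]] <- list(
      accuracy = evaluate_accuracy(results),
      selections = do.call(rbind, per_sel),
      n_contaminated = sum(contaminated),
      contaminated = contaminated,
      erp = erp,
      peak_latency_ms = peak$latency_ms,
      peak_amplitude_uv = peak$amplitude_uv
    )
  }
  excluded <- should_exclude_subject(
    list(VR = env_summ$VR$contaminated, AR = env_summ$AR$contaminated),
    config$qc)
  out <- structure(list(
    seed = config$seed,
    accuracy_vr = env_summ$VR$accuracy,
    accuracy_ar = env_summ$AR$accuracy,
    peak = list(
      vr = list(latency_ms = env_summ$VR$peak_latency_ms,
                amplitude_uv = env_summ$VR$peak_amplitude_uv),
      ar = list(latency_ms = env_summ$AR$peak_latency_ms,
                amplitude_uv = env_summ$AR$peak_amplitude_uv)),
    qc = list(contaminated_vr = env_summ$VR$n_contaminated,
              contaminated_ar = env_summ$AR$n_contaminated,
              subject_excluded = excluded),
    selections = rbind(env_summ$VR$selections, env_summ$AR$selections),
    erp_vr = env_summ$VR$erp,
    erp_ar = env_summ$AR$erp,
    model = tr$model
  ), class = "bci_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(experiment_summary(out), file.path(out_dir, "summary.json"),
                         digits = NA, auto_unbox = TRUE)
    yaml::write_yaml(config_to_list(config), file.path(out_dir, "config.yaml"))
  }
  out
}

# JSON-friendly scalar summary of an experiment.
experiment_summary <- function(x) {
  list(
    seed = x$seed,
    accuracy_vr = x$accuracy_vr,
    accuracy_ar = x$accuracy_ar,
    peak_latency_ms_vr = x$peak$vr$latency_ms,
    peak_amplitude_uv_vr = x$peak$vr$amplitude_uv,
    peak_latency_ms_ar = x$peak$ar$latency_ms,
    peak_amplitude_uv_ar = x$peak$ar$amplitude_uv,
    contaminated_vr = x$qc$contaminated_vr,
    contaminated_ar = x$qc$contaminated_ar,
    subject_excluded = x$qc$subject_excluded,
    selections = x$selections
  )
}

# Resolved config as plain lists for YAML provenance output.
config_to_list <- function(config) {
  rapply(unclass(config), function(v) v, how = "replace")
}

#' @export
print.bci_experiment <- function(x, ...) {
  cat("Simulated P300 selection experiment (seed", x$seed, ")\n")
  cat(sprintf("  accuracy: VR %.2f%%  AR %.2f%%\n", x$accuracy_vr, x$accuracy_ar))
  cat(sprintf("  P300 peak (VR): %.1f ms, %.2f uV;  (AR): %.1f ms, %.2f uV\n",
              x$peak$vr$latency_ms, x$peak$vr$amplitude_uv,
              x$peak$ar$latency_ms, x$peak$ar$amplitude_uv))
  cat(sprintf("  QC: %d contaminated (VR), %d (AR); excluded: %s\n",
              x$qc$contaminated_vr, x$qc$contaminated_ar, x$qc$subject_excluded))
  invisible(x)
}
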