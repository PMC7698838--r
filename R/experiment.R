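#' @title Config-driven end-to-end experiments
#' @description A run configuration (JSON on disk, a nested list in R)
#'   wires simulate -> preprocess -> leave-one-subject-out training ->
#'   checkpoint-ensembled sequential inference -> optional refinement ->
#'   pooled reporting. Identical config + seed gives identical outputs.
#' @name experiment
NULL

default_run_config <- function() {
  list(
    seed = 1L,
    n_folds = NULL,
    dataset = list(n_subjects = 6L, epochs_per_subject = 300L,
                   sampling_rate = 100, epoch_seconds = 30,
                   channels = list(EEG = "eeg", EOG = "eog", EMG = "emg"),
                   noise_sigma = 0.2,
                   uninformative_channels = character(0),
                   amplitude_jitter = 0.1),
    model = list(blocks = "tiny", fusion = "residual_attention",
                 use_refinement = TRUE, dropout = 0.5),
    training = list(batch_size = 32L, n_epochs = 5L, learning_rate = 1e-3,
                    grad_clip_value = 0.1, checkpoint_fraction = 0.10),
    inference = list(ensemble = TRUE, refinement = "none")
  )
}

validate_section <- function(user, defaults, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s) at ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  out <- defaults
  for (nm in names(user)) out[[nm]] <- user[[nm]]
  out
}

#' Validate and complete a run configuration
#' @param config nested list (possibly partial); unknown keys are rejected
#'   with the offending path.
#' @return Completed `"run_config"` list.
#' @export
run_config <- function(config = list()) {
  d <- default_run_config()
  top <- validate_section(config, d, "<top>")
  for (sec in c("dataset", "model", "training", "inference")) {
    top[[sec]] <- validate_section(
      if (is.null(config[[sec]])) list() else config[[sec]], d[[sec]], sec)
  }
  if (!top$inference$refinement %in% c("none", "rules", "hmm")) {
    stop("inference$refinement must be one of none/rules/hmm")
  }
  structure(top, class = "run_config")
}

#' Load a run configuration from a JSON file
#' @param path JSON file with any subset of the run-config keys.
#' @return A validated `"run_config"`.
#' @export
load_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' The scaled-down reference experiment
#'
#' Six subjects of 300 epochs each at high SNR, tiny backbone widths,
#' leave-one-subject-out limited to 3 folds, 5 training epochs at learning
#' rate 1e-3 — small enough to run in minutes on one CPU while still
#' exercising the full pipeline.
#'
#' @param seed master seed.
#' @return A `"run_config"`.
#' @export
example_run_config <- function(seed = 1L) {
  run_config(list(seed = as.integer(seed), n_folds = 3L))
}

cfg_sim_config <- function(cfg) {
  ds <- cfg$dataset
  sim_config(n_subjects = ds$n_subjects,
             epochs_per_subject = ds$epochs_per_subject,
             sampling_rate = ds$sampling_rate,
             epoch_seconds = ds$epoch_seconds,
             channels = unlist(ds$channels),
             noise_sigma = ds$noise_sigma,
             uninformative_channels = unlist(ds$uninformative_channels),
             amplitude_jitter = ds$amplitude_jitter,
             seed = cfg$seed)
}

cfg_model_config <- function(cfg, input_len, channels, seed) {
  blocks <- cfg$model$blocks
  if (is.character(blocks)) {
    blocks <- switch(blocks, tiny = tiny_blocks(), default = default_blocks(),
                     stop("model$blocks must be 'tiny', 'default' or a list"))
  } else {
    blocks <- lapply(blocks, function(b) as.integer(unlist(b)))
  }
  model_config(input_len = input_len, channels = channels, blocks = blocks,
               fusion = cfg$model$fusion,
               use_refinement = cfg$model$use_refinement,
               dropout = cfg$model$dropout, seed = seed)
}

#' Run a config-driven end-to-end experiment
#'
#' Simulates the dataset, z-scores every recording, plans LOSO folds
#' (optionally limited to the first `n_folds`), trains per fold, ensembles
#' the top checkpoints by validation MF1, optionally refines the pooled
#' test predictions (rules or validation-fitted HMM), and pools everything
#' into a single report. When `outdir` is given, the resolved config,
#' per-fold metrics, predicted hypnograms, attention-weight CSV and the
#' pooled report are written there.
#'
#' @param config a `"run_config"` (see [run_config()], [load_config()]).
#' @param outdir optional output directory.
#' @param verbose print per-fold progress.
#' @return List with `pooled` (metrics report), `stratified`, `folds`
#'   (per-fold truth/pred/history), and `config`.
#' @export
run_experiment <- function(config, outdir = NULL, verbose = FALSE) {
  config <- run_config(unclass(config))
  sc <- cfg_sim_config(config)
  recs <- make_dataset(sc)
  recs <- lapply(recs, zscore_per_channel)
  names(recs) <- vapply(recs, function(r) r$subject_id, character(1))
  splits <- make_loso_splits(names(recs))
  if (!is.null(config$n_folds)) {
    splits <- splits[seq_len(min(config$n_folds, length(splits)))]
  }
  input_len <- dim(recs[[1]]$epochs)[2]
  tc <- train_config(batch_size = config$training$batch_size,
                     n_epochs = config$training$n_epochs,
                     learning_rate = config$training$learning_rate,
                     grad_clip_value = config$training$grad_clip_value,
                     checkpoint_fraction = config$training$checkpoint_fraction,
                     seed = config$seed)
  fold_results <- list()
  for (k in seq_along(splits)) {
    fold <- splits[[k]]
    mc <- cfg_model_config(config, input_len, names(sc$channels),
                           seed = config$seed + 1000L * k)
    tck <- tc
    tck$seed <- config$seed + 1000L * k
    fit <- train_fold(recs[fold$train], recs[[fold$val]], mc, tck,
                      verbose = verbose)
    sel <- select_checkpoints(fit$history, tc$checkpoint_fraction)
    models <- lapply(sel, function(id) {
      m <- fit$model
      m$params <- fit$checkpoints[[id]]
      m
    })
    test_rec <- recs[[fold$test]]
    traces <- lapply(models, function(m) sequential_infer(test_rec, m))
    pred <- if (isTRUE(config$inference$ensemble)) {
      ensemble_predict(traces)
    } else {
      traces[[length(traces)]]$stages
    }
    if (config$inference$refinement == "rules") {
      pred <- apply_rules(pred)
    } else if (config$inference$refinement == "hmm") {
      val_traces <- lapply(models, function(m)
        sequential_infer(recs[[fold$val]], m))
      val_pred <- ensemble_predict(val_traces)
      hmm <- fit_hmm(recs[[fold$val]]$labels, val_pred)
      pred <- viterbi_decode(pred, hmm)
    }
    fold_results[[k]] <- list(
      test_subject = fold$test, truth = test_rec$labels, pred = pred,
      history = fit$history, selected = sel,
      mean_alpha = colMeans(traces[[1]]$alpha))
    if (verbose) {
      message(sprintf("fold %d (test %s): acc %.1f", k, fold$test,
                      compute_metrics(test_rec$labels, pred)$accuracy))
    }
  }
  pooled <- pool_folds(fold_results)
  truth_all <- do.call(c, lapply(fold_results, function(f) f$truth))
  pred_all <- do.call(c, lapply(fold_results, function(f) f$pred))
  strat <- stratified_metrics(truth_all, pred_all)
  res <- list(pooled = pooled, stratified = strat, folds = fold_results,
              config = config)
  if (!is.null(outdir)) write_experiment(res, outdir)
  res
}

write_experiment <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(res$config),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  fold_tab <- do.call(rbind, lapply(seq_along(res$folds), function(k) {
    f <- res$folds[[k]]
    m <- compute_metrics(f$truth, f$pred)
    data.frame(fold = k, test_subject = f$test_subject, n = m$n,
               accuracy = m$accuracy, macro_f1 = m$macro_f1,
               kappa = m$kappa)
  }))
  utils::write.csv(fold_tab, file.path(outdir, "fold_metrics.csv"),
                   row.names = FALSE)
  alpha_tab <- do.call(rbind, lapply(seq_along(res$folds), function(k)
    data.frame(fold = k, channel = seq_along(res$folds[[k]]$mean_alpha),
               mean_alpha = res$folds[[k]]$mean_alpha)))
  utils::write.csv(alpha_tab, file.path(outdir, "attention_weights.csv"),
                   row.names = FALSE)
  for (k in seq_along(res$folds)) {
    write_hypnogram(res$folds[[k]]$pred,
                    file.path(outdir, sprintf("pred_fold%02d.txt", k)))
  }
  pooled <- res$pooled
  jsonlite::write_json(
    list(n = pooled$n, accuracy = pooled$accuracy,
         macro_f1 = pooled$macro_f1, kappa = pooled$kappa,
         transition = list(
           accuracy = res$stratified$transition$accuracy,
           macro_f1 = res$stratified$transition$macro_f1),
         nontransition = list(
           accuracy = res$stratified$nontransition$accuracy,
           macro_f1 = res$stratified$nontransition$macro_f1),
         confusion = pooled$confusion),
    file.path(outdir, "pooled_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
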