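#' Run the full staging pipeline
#'
#' Orchestrates the four stages end to end on a synthetic cohort:
#' simulate RF frames, preprocess (ROI, task labels, class-balancing
#' sliding-window augmentation, normalization, 80/10/10 split), train the
#' 1-D CNN, and evaluate majority-vote frame predictions on the test
#' partition. All randomness derives deterministically from `seed`, so a
#' rerun with identical arguments reproduces the artifacts byte for byte.
#'
#' Artifacts written under `out_dir`: `frames/` (RF binaries + manifest),
#' `split.csv` (window partition assignment), `loss_history.csv`,
#' `checkpoint.rds`, `metrics.json`, and `run_manifest.json` (every seed and
#' configuration value of the run).
#'
#' @param out_dir Run directory (created if missing).
#' @param task Staging task, see [label_task()].
#' @param stage_counts Cases per stage for the simulated cohort
#'   (default [default_stage_counts()]).
#' @param seed Master seed.
#' @param epochs,batch_size,lr Training schedule (defaults 100 / 256 / 1e-3).
#' @param config Architecture ([cnn_config()]).
#' @param sim Simulator configuration ([sim_config()]).
#' @param roi ROI placement ([roi_spec()]).
#' @param ratios Split proportions (default `c(0.8, 0.1, 0.1)`).
#' @param group_by_case,stratify Split options, see [split_dataset()].
#' @param keep_best Restore best-validation epoch (default FALSE).
#' @param verbose Log stage progress to stderr.
#' @return The `metrics_report` of the test partition, invisibly; its JSON
#'   serialization is written to `metrics.json`.
#' @export
run_pipeline <- function(out_dir, task = "geF1",
                         stage_counts = default_stage_counts(), seed = 1L,
                         epochs = 100L, batch_size = 256L, lr = 1e-3,
                         config = cnn_config(), sim = sim_config(),
                         roi = roi_spec(), ratios = c(0.8, 0.1, 0.1),
                         group_by_case = FALSE, stratify = FALSE,
                         keep_best = FALSE, verbose = TRUE) {
  say <- function(...) if (verbose) message("[fibrocnn] ", sprintf(...))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(seed)

  say("simulate: %d cases -> %s", sum(stage_counts), file.path(out_dir, "frames"))
  cohort <- simulate_cohort(stage_counts, sim, seed = seed,
                            out_dir = file.path(out_dir, "frames"))

  say("preprocess: task %s, ROI %dx%d, window %d", task, roi$axial_len,
      roi$line_len, config$input_len)
  ds <- build_task_dataset(cohort, task, roi = roi,
                           window_axial = config$input_len)
  split <- split_dataset(ds$meta$label, ratios = ratios, seed = seed + 1L,
                         case_ids = ds$meta$case_id,
                         group_by_case = group_by_case, stratify = stratify)
  part <- character(nrow(ds$meta))
  part[split$train] <- "train"; part[split$val] <- "val"; part[split$test] <- "test"
  utils::write.csv(cbind(ds$meta, partition = part),
                   file.path(out_dir, "split.csv"), row.names = FALSE)

  tr <- windows_to_segments(ds$windows[split$train])
  va <- windows_to_segments(ds$windows[split$val])
  say("train: %d training segments, %d epochs, batch %d",
      nrow(tr$x), epochs, batch_size)
  fit <- fibrocnn(tr$x, rep(ds$meta$label[split$train],
                            each = ncol(ds$windows[[1]])),
                  x_val = va$x,
                  y_val = rep(ds$meta$label[split$val],
                              each = ncol(ds$windows[[1]])),
                  config = config, epochs = epochs, batch_size = batch_size,
                  lr = lr, init_seed = seed + 2L, train_seed = seed + 3L,
                  keep_best = keep_best)
  utils::write.csv(fit$loss_history, file.path(out_dir, "loss_history.csv"),
                   row.names = FALSE)
  save_checkpoint(fit, file.path(out_dir, "checkpoint.rds"))

  say("evaluate: %d test frames", length(split$test))
  report <- evaluate_windows(fit, ds$windows[split$test],
                             ds$meta$label[split$test],
                             case_ids = ds$meta$case_id[split$test])
  write_metrics_json(report, task, file.path(out_dir, "metrics.json"))
  utils::write.csv(report$frames, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  if (!is.null(report$roc))
    utils::write.csv(report$roc$roc, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)

  manifest <- list(task = task, seed = seed,
                   seeds = list(simulate = seed, split = seed + 1L,
                                init = seed + 2L, train = seed + 3L),
                   stage_counts = as.list(stage_counts),
                   epochs = epochs, batch_size = batch_size, lr = lr,
                   ratios = ratios, group_by_case = group_by_case,
                   stratify = stratify, keep_best = keep_best,
                   roi = unclass(roi),
                   sim = list(n_axial = sim$n_axial, n_lines = sim$n_lines,
                              fs_hz = sim$fs_hz, fc_hz = sim$fc_hz,
                              frac_bandwidth = sim$frac_bandwidth),
                   config = unclass(config),
                   parameter_count = fit$parameter_count)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: metrics in %s", file.path(out_dir, "metrics.json"))
  invisible(report)
}

write_metrics_json <- function(report, task, path) {
  m <- report$metrics
  out <- list(task = task,
              n_frames = sum(report$confusion),
              confusion = as.list(unclass(report$confusion)),
              ACC = unname(m["ACC"]), SEN = unname(m["SEN"]),
              SPE = unname(m["SPE"]),
              AUC = if (is.null(report$roc)) NA else report$roc$auc,
              AUC_ci95 = if (is.null(report$roc)) c(NA, NA)
                         else report$roc$auc_ci95)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
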