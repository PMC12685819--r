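# End-to-end orchestration of the two pipelines (stress classification with
# transfer to activity recognition; ECG-to-VAD regression with diagnostics),
# plus the simulate/evaluate/explain entry points used by the command-line
# wrapper. Every run writes a manifest recording config, seed and versions.

#' Segment a trial set into features and normalized VAD targets
#'
#' The regression front end: each trial's ECG is z-scored per signal,
#' segmented into `window_s`-second windows with the given overlap, each
#' window reduced to the 33-feature vector, and the parent trial's labels
#' inherited by its windows and normalized to `[0, 1]`.
#'
#' @param ts a [trial_set].
#' @param rate_hz sampling rate of the traces (default 128).
#' @param window_s window length in seconds (default 5, i.e. 640 samples).
#' @param overlap fractional overlap between windows (default 0.5).
#' @return list with `x` (n x 33 feature matrix), `y` (n x 3 normalized
#'   targets), and `meta` (subject/trial provenance per row).
#' @export
prepare_vad_dataset <- function(ts, rate_hz = 128, window_s = 5, overlap = 0.5) {
  W <- round(window_s * rate_hz)
  S <- round(W * (1 - overlap))
  xs <- list(); ys <- list(); metas <- list()
  for (tr in ts$trials) {
    segs <- segment_signal(zscore_signal(tr$ecg), W, S)
    labs <- inherit_labels(tr$vad_raw, nrow(segs), tr$subject_id, tr$trial_id)
    xs[[length(xs) + 1L]] <- extract_features_batch(segs)
    ys[[length(ys) + 1L]] <- normalize_vad(as.matrix(
      labs[, c("valence", "arousal", "dominance")]))
    metas[[length(metas) + 1L]] <- labs[, c("subject_id", "trial_id")]
  }
  list(x = do.call(rbind, xs), y = do.call(rbind, ys),
       meta = do.call(rbind, metas))
}

# split an n-row feature/target pair 70/15/15 by shuffled row index
.split_rows <- function(n, seed, fracs = c(0.70, 0.15, 0.15)) {
  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- floor(fracs[1] * n)
  n_val <- floor((n - n_tr) * fracs[2] / (fracs[2] + fracs[3]))
  list(train = perm[seq_len(n_tr)],
       val = perm[n_tr + seq_len(n_val)],
       test = perm[(n_tr + n_val + 1):n])
}

.write_manifest <- function(out_dir, pipeline, config, seed) {
  manifest <- list(
    pipeline = pipeline, seed = seed, config = config,
    package_version = as.character(utils::packageVersion("affectkit")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Run one of the framework pipelines
#'
#' Dispatches on `config$pipeline`:
#' \describe{
#'   \item{simulate}{writes a synthetic dataset (`config$what` one of
#'     `"stress"` (CSV), `"dreamer"` (MAT), `"activity"` (CSV of flattened
#'     windows)) under `config$out_dir`.}
#'   \item{stress}{reads a stress CSV, splits 70/15/15 stratified, fits the
#'     z-scaler on the training part, trains the 1D-CNN, writes the
#'     classification report, history, checkpoint and manifest.}
#'   \item{activity}{loads a pretraining checkpoint, fine-tunes on an
#'     activity CSV (flattened windows), writes report plus a Grad-CAM
#'     heatmap of one test window.}
#'   \item{vad}{reads a DREAMER-style MAT, builds the 33-feature dataset,
#'     trains the conformer, writes regression metrics and the diagnostic
#'     table of the test predictions.}
#'   \item{diagnose}{reads a CSV of normalized VAD triples and writes the
#'     diagnostic table.}
#'   \item{evaluate}{reads prediction/truth CSVs and writes the matching
#'     report.}
#' }
#'
#' @param config named list; see Details in the vignette. Must contain
#'   `pipeline`, `out_dir` and `seed`; path and model options per pipeline.
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  pl <- config$pipeline
  if (is.null(pl)) stopf("config$pipeline is required")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  artifacts <- list(manifest = .write_manifest(out_dir, pl, config, seed))
  epochs <- config$epochs %||% 50L

  if (pl == "simulate") {
    what <- config$what %||% "stress"
    if (what == "stress") {
      tab <- gen_stress_table(config$n %||% 3000L,
                              effect_size = config$effect_size %||% 3,
                              seed = seed)
      artifacts$data <- write_csv_table(tab, file.path(out_dir, "stress.csv"))
    } else if (what == "dreamer") {
      ts <- gen_dreamer_like(config$n_subjects %||% 6L,
                             config$trials_per_subject %||% 10L,
                             config$trial_duration_s %||% 61.25, seed = seed)
      artifacts$data <- file.path(out_dir, "dreamer.mat")
      write_dreamer_mat(ts, artifacts$data)
    } else if (what == "activity") {
      aw <- gen_activity_windows(config$n %||% 800L,
                                 window_samples = config$window_samples %||% 64L,
                                 n_channels = config$n_channels %||% 3L,
                                 effect_size = config$effect_size %||% 3,
                                 seed = seed)
      tab <- feature_table(flatten_windows(aw$windows), aw$labels)
      artifacts$data <- write_csv_table(tab, file.path(out_dir, "activity.csv"))
    } else stopf("unknown simulate target '%s'", what)

  } else if (pl == "stress") {
    if (is.null(config$data)) stopf("stress pipeline needs config$data (CSV)")
    tab <- read_csv_table(config$data)
    sp <- stratified_split(tab, seed = seed)
    zs <- zscore_fit(sp$train$values)
    model <- build_cnn(ncol(tab$values), length(unique(tab$labels)), seed = seed)
    fit <- train_classifier(model, zscore_apply(sp$train$values, zs),
                            sp$train$labels, zscore_apply(sp$val$values, zs),
                            sp$val$labels,
                            train_config(max_epochs = epochs,
                                         class_weights = "balanced", seed = seed))
    pred <- predict_classes(fit$model, zscore_apply(sp$test$values, zs))
    rep <- classification_report(confusion_matrix(sp$test$labels, pred$labels))
    artifacts$report <- file.path(out_dir, "classification_report.csv")
    utils::write.csv(rep$per_class, artifacts$report, row.names = FALSE)
    artifacts$history <- file.path(out_dir, "history.csv")
    utils::write.csv(fit$history, artifacts$history, row.names = FALSE)
    artifacts$checkpoint <- file.path(out_dir, "stress_cnn.ckpt")
    save_checkpoint(model_to_checkpoint(fit$model,
                                        list(source = "stress", seed = seed)),
                    artifacts$checkpoint)
    message(sprintf("stress pipeline: test accuracy %.4f", rep$accuracy))

  } else if (pl == "activity") {
    if (is.null(config$checkpoint))
      stopf("activity pipeline needs config$checkpoint from the stress pretraining step")
    if (is.null(config$data)) stopf("activity pipeline needs config$data (CSV)")
    bundle <- load_checkpoint(config$checkpoint)
    tab <- read_csv_table(config$data)
    sp <- stratified_split(tab, seed = seed)
    zs <- zscore_fit(sp$train$values)
    fit <- fine_tune(bundle, zscore_apply(sp$train$values, zs), sp$train$labels,
                     zscore_apply(sp$val$values, zs), sp$val$labels,
                     n_classes = length(unique(tab$labels)),
                     config = train_config(lr = 1e-4, max_epochs = epochs,
                                           class_weights = "balanced",
                                           seed = seed))
    xte <- zscore_apply(sp$test$values, zs)
    pred <- predict_classes(fit$model, xte)
    rep <- classification_report(confusion_matrix(sp$test$labels, pred$labels))
    artifacts$report <- file.path(out_dir, "classification_report.csv")
    utils::write.csv(rep$per_class, artifacts$report, row.names = FALSE)
    cam <- grad_cam_1d(fit$model, xte[1, ], pred$labels[1])
    artifacts$gradcam <- file.path(out_dir, "gradcam.csv")
    utils::write.csv(data.frame(position = seq_along(cam$values),
                                heat = cam$values),
                     artifacts$gradcam, row.names = FALSE)
    message(sprintf("activity pipeline: test accuracy %.4f, macro recall %.4f",
                    rep$accuracy, rep$macro["recall"]))

  } else if (pl == "vad") {
    if (is.null(config$data)) stopf("vad pipeline needs config$data (MAT)")
    ts <- read_dreamer_mat(config$data)
    ds <- prepare_vad_dataset(ts)
    idx <- .split_rows(nrow(ds$x), seed)
    model <- build_conformer(seed = seed)
    fit <- train_vad_regressor(model, ds$x[idx$train, ], ds$y[idx$train, ],
                               ds$x[idx$val, ], ds$y[idx$val, ],
                               train_config(max_epochs = epochs, seed = seed))
    pred <- predict_vad(fit$model, ds$x[idx$test, ])
    met <- regression_metrics(pred, ds$y[idx$test, ])
    artifacts$metrics <- file.path(out_dir, "regression_metrics.json")
    jsonlite::write_json(met[c("mae", "rmse", "r2", "rounded_accuracy_all",
                               "rounded_accuracy_per_dim", "smooth_l1")],
                         artifacts$metrics, auto_unbox = TRUE, digits = NA)
    diag_tab <- diagnose(pred, seed = seed, display = TRUE)
    artifacts$diagnostics <- file.path(out_dir, "diagnostics.csv")
    utils::write.csv(diag_tab, artifacts$diagnostics, row.names = FALSE)
    message(sprintf("vad pipeline: MAE %.4f, R^2 %.4f", met$mae, met$r2))

  } else if (pl == "diagnose") {
    if (is.null(config$data)) stopf("diagnose pipeline needs config$data (CSV)")
    df <- utils::read.csv(config$data)
    tab <- diagnose(as.matrix(df[, c("valence", "arousal", "dominance")]),
                    k = config$k %||% 4, seed = seed, display = TRUE)
    artifacts$diagnostics <- file.path(out_dir, "diagnostics.csv")
    utils::write.csv(tab, artifacts$diagnostics, row.names = FALSE)

  } else if (pl == "evaluate") {
    task <- config$task %||% "clf"
    pred <- as.matrix(utils::read.csv(config$pred))
    truth <- as.matrix(utils::read.csv(config$truth))
    if (task == "clf") {
      rep <- classification_report(confusion_matrix(as.integer(truth[, 1]),
                                                    as.integer(pred[, 1])))
      artifacts$report <- file.path(out_dir, "classification_report.csv")
      utils::write.csv(rep$per_class, artifacts$report, row.names = FALSE)
    } else {
      met <- regression_metrics(pred, truth)
      artifacts$report <- file.path(out_dir, "regression_metrics.json")
      jsonlite::write_json(met[c("mae", "rmse", "r2", "rounded_accuracy_all",
                                 "rounded_accuracy_per_dim", "smooth_l1")],
                           artifacts$report, auto_unbox = TRUE, digits = NA)
    }
  } else stopf("unknown pipeline '%s'", pl)

  invisible(artifacts)
}
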