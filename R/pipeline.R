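#' Configuration for a full pipeline run
#'
#' Bundles the generator, preprocessing, model and split configurations with
#' an output directory.  Every stage draws its randomness from the seeds
#' recorded here, so a run is reproducible from its config alone.
#'
#' @param synthetic A [synthetic_config()].
#' @param preproc A [preproc_config()].
#' @param model A [cnn_config()].
#' @param split List with `test_fraction`, `val_fraction`, `seed`.
#' @param output_dir Directory for run artifacts (created if missing).
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       preproc = preproc_config(),
                       model = cnn_config(),
                       split = list(test_fraction = 0.1, val_fraction = 0.2,
                                    seed = 1L),
                       output_dir = tempfile("driveact_run_"),
                       log_level = c("info", "quiet")) {
  structure(list(synthetic = synthetic, preproc = preproc, model = model,
                 split = split, output_dir = output_dir,
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' Preprocess a list of recordings into a stacked model-input array
#'
#' @param recordings List of [raw_recording()]s.
#' @param config A [preproc_config()].
#' @return List with `x` (an `(n, L, 7)` array) and `y` (integer codes);
#'   in `windows` mode each window contributes one row.
#' @export
preprocess_dataset <- function(recordings, config = preproc_config()) {
  inputs <- list()
  for (i in seq_along(recordings)) {
    mi <- preprocess_recording(recordings[[i]], config,
                               source_id = as.character(i))
    if (inherits(mi, "model_input")) mi <- list(mi)
    inputs <- c(inputs, mi)
  }
  n <- length(inputs)
  if (n == 0L) stop("no model inputs produced", call. = FALSE)
  L <- nrow(inputs[[1]]$values)
  C <- ncol(inputs[[1]]$values)
  x <- array(NA_real_, c(n, L, C))
  y <- integer(n)
  for (i in seq_len(n)) {
    x[i, , ] <- inputs[[i]]$values
    y[i] <- inputs[[i]]$label$code
  }
  list(x = x, y = y)
}

#' Run the full generate / preprocess / split / train / evaluate pipeline
#'
#' Executes the stage chain with one configuration, writing the dataset
#' manifest, preprocessed inputs, split indices, model checkpoint (with a
#' plain-text hyperparameter sidecar), training history, evaluation report
#' and a provenance record to `config$output_dir`.  The trained model is
#' cached by the hash of the generating configuration: re-running the same
#' config reuses the checkpoint instead of retraining.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `report` ([evaluation_report()]),
#'   the trained `model`, the `splits` and the `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) {
    if (config$log_level == "info") message(sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (partial artifacts in %s)",
                   name, conditionMessage(e), config$output_dir),
           call. = FALSE)
    })
  }
  hash <- config_hash(config[c("synthetic", "preproc", "model", "split")])

  say("generate: %d primary + %d secondary recordings",
      config$synthetic$n_primary, config$synthetic$n_secondary)
  ds <- stage("generate", generate_dataset(config$synthetic))
  utils::write.table(ds$manifest, file.path(config$output_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  say("preprocess: %d recordings", length(ds$recordings))
  pp <- stage("preprocess", preprocess_dataset(ds$recordings, config$preproc))
  saveRDS(pp, file.path(config$output_dir, "inputs.rds"))

  say("split: 9:1 then 8:2")
  splits <- stage("split", split_dataset(pp$y,
                                         config$split$test_fraction,
                                         config$split$val_fraction,
                                         config$split$seed))
  jsonlite::write_json(splits, file.path(config$output_dir, "splits.json"))

  ckpt <- file.path(config$output_dir, "model.rds")
  cached <- file.exists(ckpt) &&
    identical(attr(readRDS(ckpt), "config_hash"), hash)
  if (cached) {
    say("train: reusing cached checkpoint %s", ckpt)
    model <- readRDS(ckpt)
  } else {
    say("train: %d epochs, batch %d, lr %g", config$model$epochs,
        config$model$batch_size, config$model$learning_rate)
    model <- stage("train", {
      m <- build_model(config$model)
      cnn_train(m,
                pp$x[splits$train, , , drop = FALSE], pp$y[splits$train],
                pp$x[splits$validation, , , drop = FALSE],
                pp$y[splits$validation],
                verbose = config$log_level == "info")
    })
    attr(model, "config_hash") <- hash
    saveRDS(model, ckpt)
    jsonlite::write_json(unclass(config$model),
                         file.path(config$output_dir, "model_config.json"),
                         auto_unbox = TRUE, null = "null")
    utils::write.csv(model$history,
                     file.path(config$output_dir, "history.csv"),
                     row.names = FALSE)
  }

  say("evaluate: %d test inputs", length(splits$test))
  report <- stage("evaluate", {
    pred <- predict(model, pp$x[splits$test, , , drop = FALSE])
    evaluation_report(pp$y[splits$test], pred$labels,
                      config$model$n_classes)
  })
  write_report_files(report, config$output_dir)
  provenance <- list(
    config_hash = hash,
    seeds = list(synthetic = config$synthetic$seed,
                 model = config$model$seed, split = config$split$seed),
    package_version = as.character(utils::packageVersion("driveact")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  jsonlite::write_json(provenance,
                       file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(list(report = report, model = model, splits = splits,
                 manifest = ds$manifest))
}

config_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(obj, tmp, version = 2)  # canonical serialization of the config
  unname(tools::md5sum(tmp))
}

write_report_files <- function(report, dir) {
  utils::write.csv(report$per_class, file.path(dir, "per_class_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(report$type_level)) {
    utils::write.csv(report$type_level, file.path(dir, "type_level_metrics.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(report$confusion),
                   file.path(dir, "confusion_matrix.csv"), row.names = TRUE)
  jsonlite::write_json(
    list(overall_accuracy = report$overall_accuracy,
         weighted = as.list(report$weighted),
         binary_primary_secondary_accuracy =
           report$binary_primary_secondary_accuracy),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
}

#' Scaled-down end-to-end benchmark
#'
#' Runs the whole pipeline at desk scale: `n_per_class` recordings per class
#' (default 20, i.e. 320 in total) at the generator's default noise, model
#' inputs resampled to `input_len` (default 600), the standard architecture
#' trained for `epochs` epochs (batch 32, learning rate 2e-4), 72/18/10
#' split.  Used by the acceptance checks.
#'
#' @param seed Master seed for generation, split and training.
#' @param n_per_class Recordings per class.
#' @param input_len Model input length after resampling.
#' @param epochs Training epochs (kept at or below 30).
#' @param output_dir Where artifacts go (temporary by default).
#' @return List with `accuracy` (16-class test accuracy, percent),
#'   `binary_accuracy` (primary/secondary, percent), `n_test` and the full
#'   `report`.
#' @export
run_scaled_benchmark <- function(seed = 1L, n_per_class = 20L,
                                 input_len = 600L, epochs = 30L,
                                 output_dir = tempfile("driveact_bench_")) {
  stopifnot(epochs <= 30L)
  cfg <- run_config(
    synthetic = synthetic_config(n_primary = 12L * n_per_class,
                                 n_secondary = 4L * n_per_class,
                                 seed = seed),
    preproc = preproc_config(model_input_len = input_len),
    model = cnn_config(input_len = input_len, epochs = epochs, seed = seed),
    split = list(test_fraction = 0.1, val_fraction = 0.2, seed = seed),
    output_dir = output_dir, log_level = "quiet"
  )
  res <- run_pipeline(cfg)
  list(accuracy = res$report$overall_accuracy,
       binary_accuracy = res$report$binary_primary_secondary_accuracy,
       n_test = sum(res$report$confusion),
       report = res$report)
}
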