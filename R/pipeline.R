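# End-to-end orchestration: simulate or ingest -> featurize -> random
# split for model selection -> chronological split for testing ->
# windowed evaluation -> reports. A run directory plus its config
# snapshot reproduces every output byte-for-byte.

#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected up front, before any computation.
#'
#' @param simulation `NULL`, or a list of [simulation_config()] arguments
#'   (a synthetic dataset is generated instead of reading files).
#' @param input `NULL`, or CSV path(s)/directory for [read_daily_csv()].
#' @param seed master integer seed for the run.
#' @param split regime of the final evaluation split: `"chronological"`
#'   (default; windowed statistics are meaningful) or `"random"`.
#' @param train_fraction fraction of samples used for training, (0, 1).
#' @param models character vector of model names to run; `NULL` = all nine.
#' @param windows integer window lengths for the hit statistics.
#' @param low_tp_fraction threshold of the model-exclusion rule.
#' @param fp_denominator `"per_occurrence"` or `"per_prediction"`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(simulation = NULL, input = NULL, seed = 1L,
                       split = "chronological", train_fraction = 0.75,
                       models = NULL, windows = c(1, 3, 5),
                       low_tp_fraction = 0.5,
                       fp_denominator = "per_occurrence") {
  cfg <- list(simulation = simulation, input = input,
              seed = as.integer(seed), split = split,
              train_fraction = train_fraction, models = models,
              windows = windows, low_tp_fraction = low_tp_fraction,
              fp_denominator = fp_denominator)
  if (is.null(cfg$simulation) && is.null(cfg$input))
    stop("run config needs either 'simulation' or 'input'", call. = FALSE)
  if (!is.null(cfg$simulation)) {
    unknown <- setdiff(names(cfg$simulation),
                       names(formals(simulation_config)))
    if (length(unknown))
      stop("unknown simulation key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  if (!cfg$split %in% c("chronological", "random"))
    stop("split must be 'chronological' or 'random'", call. = FALSE)
  if (!is.numeric(cfg$train_fraction) || cfg$train_fraction <= 0 ||
      cfg$train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(cfg$windows) || any(cfg$windows < 1))
    stop("windows must be integers >= 1", call. = FALSE)
  if (!cfg$fp_denominator %in% c("per_occurrence", "per_prediction"))
    stop("fp_denominator must be 'per_occurrence' or 'per_prediction'",
         call. = FALSE)
  all_names <- vapply(list_models(), `[[`, "", "name")
  if (!is.null(cfg$models)) {
    bad <- setdiff(cfg$models, all_names)
    if (length(bad))
      stop("unknown model name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(run_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$simulation$seasons))
    raw$simulation$seasons <- lapply(raw$simulation$seasons, unlist)
  do.call(run_config, raw)
}

#' Execute a full pipeline run
#'
#' Stages: obtain daily data (simulate or read), build the 21-variable
#' lagged features, randomly split 75/25 for model validation, train the
#' requested bank, apply the model-exclusion rule, then re-train the
#' retained models on the chronological training window and score the
#' held-out chronological test window with confusion-matrix and windowed
#' hit statistics. All outputs (resolved config snapshot, validation
#' table, per-model prediction CSVs, report CSV/JSON, run log, and a
#' human-readable summary) are written into `out_dir` and are
#' byte-reproducible from (config, seed).
#'
#' @param config a `run_config` (or list acceptable to [run_config()]).
#' @param out_dir run directory, created if needed.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the evaluation `report`, the `selection`
#'   outcome, the `validation` table and the run directory.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE))
    stop("pipeline stage 'setup': cannot create ", out_dir, call. = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }

  # -- data ---------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- do.call(simulation_config,
                   c(config$simulation,
                     if (is.null(config$simulation$seed))
                       list(seed = config$seed)))
    gen <- generate_dataset(sim, output_path = NULL)
    bundle <- gen$bundle
    say("stage data: simulated ", nrow(bundle), " day-records over ",
        length(unique(bundle$location_id)), " locations")
  } else {
    bundle <- tryCatch(read_daily_csv(config$input), error = function(e)
      stop("pipeline stage 'data': ", conditionMessage(e), call. = FALSE))
    say("stage data: read ", nrow(bundle), " day-records")
  }

  # -- features -----------------------------------------------------------
  features <- build_lagged_features(bundle)
  prevalence <- mean(features$label)
  say("stage features: ", nrow(features), " samples, prevalence ",
      sprintf("%.1f%%", 100 * prevalence))

  specs <- list_models(seed = config$seed)
  if (!is.null(config$models))
    specs <- Filter(function(s) s$name %in% config$models, specs)

  # -- validation (random split) & model selection ------------------------
  rs <- random_split(features, config$train_fraction, seed = config$seed)
  val_rows <- lapply(specs, function(spec) {
    model <- train_model(spec, rs$train)
    cm <- confusion_matrix(predict(model, rs$validation))
    say("stage validation: ", spec$name, " TN=", cm$TN, " FP=", cm$FP,
        " FN=", cm$FN, " TP=", cm$TP)
    data.frame(model = spec$name, TN = cm$TN, FP = cm$FP, FN = cm$FN,
               TP = cm$TP, stringsAsFactors = FALSE)
  })
  validation <- do.call(rbind, val_rows)
  validation$accuracy <- (validation$TN + validation$TP) /
    rowSums(validation[, c("TN", "FP", "FN", "TP")])
  selection <- select_models(validation, config$low_tp_fraction)
  say("stage selection: retained ",
      paste(selection$retained, collapse = ", "))
  if (nrow(selection$excluded))
    say("stage selection: excluded ",
        paste(paste0(selection$excluded$model, " (",
                     selection$excluded$reason, ")"), collapse = "; "))
  retained_specs <- Filter(function(s) s$name %in% selection$retained,
                           specs)
  if (!length(retained_specs))
    stop("pipeline stage 'selection': no model survived the exclusion rule",
         call. = FALSE)

  # -- final split & evaluation -------------------------------------------
  if (config$split == "chronological") {
    cs <- chronological_split(features, config$train_fraction)
    eval_train <- cs$train
    eval_test <- cs$test
  } else {
    eval_train <- rs$train
    eval_test <- rs$validation
  }
  say("stage evaluation: ", nrow(eval_train), " train / ",
      nrow(eval_test), " test samples (", config$split, " split), ",
      sum(eval_test$label), " occurrence days in test")
  report <- evaluate_models(retained_specs, eval_train, eval_test,
                            windows = config$windows,
                            denominator_mode = config$fp_denominator)

  # -- outputs ------------------------------------------------------------
  snapshot <- unclass(config)
  snapshot$simulation <- if (!is.null(config$simulation))
    lapply(unclass(do.call(simulation_config,
                           c(config$simulation,
                             if (is.null(config$simulation$seed))
                               list(seed = config$seed)))),
           function(v) if (is.list(v)) lapply(v, as.numeric) else v)
  yaml::write_yaml(snapshot, file.path(out_dir, "config.yaml"))
  write_report(report, out_dir)
  write_validation_csv(validation, file.path(out_dir, "validation.csv"))
  preds <- attr(report, "predictions")
  for (nm in names(preds))
    write_prediction_csv(preds[[nm]],
                         file.path(out_dir, paste0("predictions_",
                                                   slug(nm), ".csv")))
  writeLines(format_summary(report, validation, selection, prevalence),
             file.path(out_dir, "summary.txt"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(report = report, selection = selection,
                 validation = validation, out_dir = out_dir))
}

slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

write_prediction_csv <- function(series, path) {
  lines <- c("location_id,date,actual,predicted",
             paste(series$location_id, format(series$date, "%Y-%m-%d"),
                   series$actual, series$predicted, sep = ","))
  con <- file(path, "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

write_validation_csv <- function(validation, path) {
  lines <- c("model,TN,FP,FN,TP,accuracy",
             paste(validation$model, validation$TN, validation$FP,
                   validation$FN, validation$TP,
                   num_chr(validation$accuracy), sep = ","))
  con <- file(path, "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

# Table-style run summary: accuracy and confusion counts per model, then
# the windowed hit statistics.
format_summary <- function(report, validation, selection, prevalence) {
  df <- as.data.frame(report)
  w1 <- df[df$w == min(df$w), ]
  out <- c("Model evaluation summary",
           sprintf("sample prevalence: %.1f%%", 100 * prevalence),
           "",
           "validation (random split):",
           sprintf("  %-20s %8s %6s %6s %6s %6s", "ML Model", "Accuracy",
                   "TN", "FP", "FN", "TP"),
           sprintf("  %-20s %7.1f%% %6d %6d %6d %6d", validation$model,
                   100 * validation$accuracy, validation$TN, validation$FP,
                   validation$FN, validation$TP),
           "",
           paste0("retained after exclusion rule: ",
                  paste(selection$retained, collapse = ", ")),
           "",
           "test (final split):",
           sprintf("  %-20s %8s %6s %6s %6s %6s", "ML Model", "Accuracy",
                   "TN", "FP", "FN", "TP"),
           sprintf("  %-20s %7.1f%% %6d %6d %6d %6d", w1$model,
                   100 * w1$accuracy, w1$TN, w1$FP, w1$FN, w1$TP),
           "",
           "windowed hit statistics:",
           sprintf("  %-20s %2s %9s %6s %8s %10s", "ML Model", "w",
                   "hits", "false", "AD_HA_w", "false_rate"),
           sprintf("  %-20s %2d %9d %6d %7.1f%% %9.1f%%", df$model, df$w,
                   df$numD_HA_w, df$FP_w, 100 * df$AD_HA_w,
                   100 * df$false_rate))
  out
}

#' Generate the packaged miniature fixture dataset
#'
#' A deterministic two-location, 60-day season (fixed seed 42) written in
#' the daily CSV schema, plus a full pipeline run over it whose report
#' serves as a regression snapshot.
#'
#' @param out_dir directory for the fixture tree (`data/` and `run/`).
#' @return invisibly, list with `data_dir`, `run_dir` and the run result.
#' @export
make_fixtures <- function(out_dir) {
  data_dir <- file.path(out_dir, "data")
  run_dir <- file.path(out_dir, "run")
  sim_args <- list(n_locations = 2,
                   seasons = list(c(2019, 152, 211)),
                   beta0 = -78, beta_t = 2.5, beta_rh = 0.25,
                   seed = 42L)
  sim <- do.call(simulation_config, sim_args)
  generate_dataset(sim, data_dir)
  cfg <- run_config(simulation = sim_args, seed = 42L,
                    models = c("K-Nearest Neighbors", "Decision Tree",
                               "AdaBoost", "G Naive Bayes"))
  res <- run_pipeline(cfg, run_dir, quiet = TRUE)
  invisible(list(data_dir = data_dir, run_dir = run_dir, result = res))
}
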