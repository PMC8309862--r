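# Forecast verification: confusion-matrix metrics plus the time-tolerant
# windowed hit / false-prediction statistics.
#
# A predicted-positive day d is credited as a hit at window length w if a
# real occurrence falls on any of days d..d+w-1 of the same
# location-season series. Windows are forward-only, truncate at the end
# of each series, and never cross series boundaries. Each
# predicted-positive day is judged independently, so several predicted
# days may be credited to the same occurrence day and the windowed hit
# accuracy can exceed 1; it is reported as computed, never clipped.

as_prediction_series <- function(x) {
  df <- as.data.frame(x)
  need <- c("location_id", "date", "actual", "predicted")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("prediction series lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(df$actual) != length(df$predicted))
    stop("predicted and actual labels have different lengths",
         call. = FALSE)
  if (any(!(df$actual %in% c(0, 1))) || any(!(df$predicted %in% c(0, 1))))
    stop("labels must be 0 or 1", call. = FALSE)
  if (is.null(df$series_id)) {
    df <- df[order(df$location_id, df$date), , drop = FALSE]
    df$series_id <- segment_ids(df)
  }
  key <- paste(df$location_id, df$date)
  if (anyDuplicated(key))
    stop("duplicate (location_id, date) in prediction series",
         call. = FALSE)
  class(df) <- c("prediction_series", "data.frame")
  df
}

#' Confusion matrix of a prediction series
#'
#' Counts true negatives, false positives, false negatives and true
#' positives under the actual-by-predicted convention (rows: actual
#' negative/positive; columns: predicted negative/positive).
#'
#' @param series a `prediction_series` (columns `actual`, `predicted`).
#' @return a `confusion_counts` object with fields `TN`, `FP`, `FN`, `TP`.
#' @export
confusion_matrix <- function(series) {
  s <- as_prediction_series(series)
  counts <- list(TN = sum(s$actual == 0 & s$predicted == 0),
                 FP = sum(s$actual == 0 & s$predicted == 1),
                 FN = sum(s$actual == 1 & s$predicted == 0),
                 TP = sum(s$actual == 1 & s$predicted == 1))
  structure(counts, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TN, x$FP, x$FN, x$TP), 2, 2, byrow = TRUE,
              dimnames = list(c("Actual Negative", "Actual Positive"),
                              c("Predicted Negative", "Predicted Positive")))
  print(m)
  invisible(x)
}

#' Construct confusion counts directly
#'
#' For scoring published or externally supplied confusion matrices without
#' the underlying prediction series.
#'
#' @param TN,FP,FN,TP non-negative counts.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(TN, FP, FN, TP) {
  counts <- list(TN = TN, FP = FP, FN = FN, TP = TP)
  if (any(unlist(counts) < 0)) stop("negative confusion count", call. = FALSE)
  structure(counts, class = "confusion_counts")
}

#' Classification accuracy from confusion counts
#'
#' `(TN + TP) / (TN + FP + FN + TP)`. Identical to the label-wise mean of
#' the agreement indicator ([accuracy_score()]) on the same series.
#'
#' @param counts a `confusion_counts` object (or list with TN/FP/FN/TP).
#' @return accuracy in \[0, 1\].
#' @export
accuracy <- function(counts) {
  n <- counts$TN + counts$FP + counts$FN + counts$TP
  if (n == 0) stop("accuracy is undefined for an empty series", call. = FALSE)
  (counts$TN + counts$TP) / n
}

#' Label-wise accuracy score
#'
#' Mean of the indicator that predicted and actual labels agree:
#' the sample-level definition of accuracy, cross-checked against
#' [accuracy()] of the confusion counts.
#'
#' @param series a `prediction_series`.
#' @return accuracy in \[0, 1\].
#' @export
accuracy_score <- function(series) {
  s <- as_prediction_series(series)
  if (nrow(s) == 0) stop("accuracy is undefined for an empty series",
                         call. = FALSE)
  mean(s$predicted == s$actual)
}

#' Precision, recall and F1 from confusion counts
#'
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
#' `F1 = 2*Precision*Recall/(Precision+Recall)`. Degenerate denominators
#' follow the usual conventions: precision (recall) is 0 when no positive
#' was predicted (observed), and F1 is 0 when precision + recall = 0.
#'
#' @param counts a `confusion_counts` object.
#' @return named list with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  precision <- if (counts$TP + counts$FP == 0) 0 else
    counts$TP / (counts$TP + counts$FP)
  recall <- if (counts$TP + counts$FN == 0) 0 else
    counts$TP / (counts$TP + counts$FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Windowed hit and false-prediction counts
#'
#' For every predicted-positive day d, credits a hit if a real occurrence
#' falls on day d or within the following `w - 1` days of the same
#' location-season series (forward-only window, truncated at the series
#' end). At `w = 1` the hit count equals TP and the false count equals FP
#' of the confusion matrix.
#'
#' @param series a chronological `prediction_series`.
#' @param w window length in days (>= 1).
#' @return a `windowed_result` with fields `w`, `numD_HA_w` (credited
#'   hits), `FP_w` (uncredited predicted-positive days), `numR_HA`
#'   (actual occurrence days), `TP`, `FP`.
#' @export
windowed_hits <- function(series, w) {
  if (!is.numeric(w) || length(w) != 1 || w < 1 || w != round(w))
    stop("window length w must be an integer >= 1", call. = FALSE)
  s <- as_prediction_series(series)
  hits <- 0L
  false_w <- 0L
  for (part in split(s, s$series_id)) {
    if (is.unsorted(part$date, strictly = TRUE))
      stop("dates must be strictly increasing within a series",
           call. = FALSE)
    n <- nrow(part)
    cs <- c(0, cumsum(part$actual))
    hi <- pmin(seq_len(n) + w - 1, n)
    any_real <- (cs[hi + 1] - cs[seq_len(n)]) > 0
    hits <- hits + sum(part$predicted == 1 & any_real)
    false_w <- false_w + sum(part$predicted == 1 & !any_real)
  }
  cm <- confusion_matrix(s)
  structure(list(w = as.integer(w), numD_HA_w = hits, FP_w = false_w,
                 numR_HA = sum(s$actual == 1), TP = cm$TP, FP = cm$FP),
            class = "windowed_result")
}

#' Windowed hit accuracy
#'
#' Credited hits divided by the number of actual occurrence days. May
#' exceed 1 when several predicted days are credited to one occurrence
#' day; reported as computed. `NA` (not applicable) when the series
#' contains no occurrence day.
#'
#' @param result a `windowed_result` from [windowed_hits()].
#' @return hit accuracy, or `NA_real_` when undefined.
#' @export
windowed_accuracy <- function(result) {
  stopifnot(inherits(result, "windowed_result"))
  if (result$numR_HA == 0) return(NA_real_)
  result$numD_HA_w / result$numR_HA
}

#' Windowed false-prediction rate
#'
#' Uncredited predicted-positive days, expressed either per actual
#' occurrence day (`per_occurrence`, default) or per predicted-positive
#' day (`per_prediction`).
#'
#' @param result a `windowed_result`.
#' @param denominator_mode `"per_occurrence"` (`FP_w / numR_HA`) or
#'   `"per_prediction"` (`FP_w / (FP_w + numD_HA_w)`).
#' @return the rate, or `NA_real_` when the denominator is zero.
#' @export
false_prediction_rate <- function(result,
                                  denominator_mode = c("per_occurrence",
                                                       "per_prediction")) {
  stopifnot(inherits(result, "windowed_result"))
  denominator_mode <- match.arg(denominator_mode)
  denom <- switch(denominator_mode,
                  per_occurrence = result$numR_HA,
                  per_prediction = result$FP_w + result$numD_HA_w)
  if (denom == 0) return(NA_real_)
  result$FP_w / denom
}

#' Evaluate a set of models on a chronological test set
#'
#' Trains each spec on `train`, predicts `test`, and reports confusion
#' counts, accuracy, precision/recall/F1, and the windowed hit and
#' false-prediction statistics for every requested window length.
#'
#' @param specs list of `model_spec` objects (or already fitted
#'   `pest_model`s).
#' @param train training `feature_matrix` (ignored when `specs` are
#'   already fitted).
#' @param test chronological test `feature_matrix`.
#' @param windows integer window lengths; default `c(1, 3, 5)`.
#' @param denominator_mode passed to [false_prediction_rate()].
#' @return an `evaluation_report` data frame, one row per model and
#'   window, with columns `model, w, TN, FP, FN, TP, accuracy, precision,
#'   recall, f1, numD_HA_w, FP_w, numR_HA, AD_HA_w, false_rate`. The
#'   prediction series are attached as the `predictions` attribute.
#' @export
evaluate_models <- function(specs, train, test, windows = c(1, 3, 5),
                            denominator_mode = "per_occurrence") {
  if (inherits(specs, "model_spec") || inherits(specs, "pest_model"))
    specs <- list(specs)
  rows <- list()
  preds <- list()
  for (spec in specs) {
    model <- if (inherits(spec, "pest_model")) spec else
      train_model(spec, train)
    series <- predict(model, test)
    preds[[model$spec$name]] <- series
    cm <- confusion_matrix(series)
    prf <- precision_recall_f1(cm)
    acc <- accuracy(cm)
    for (w in sort(windows)) {
      wr <- windowed_hits(series, w)
      rows[[length(rows) + 1L]] <- data.frame(
        model = model$spec$name, w = as.integer(w),
        TN = cm$TN, FP = cm$FP, FN = cm$FN, TP = cm$TP,
        accuracy = acc, precision = prf$precision, recall = prf$recall,
        f1 = prf$f1, numD_HA_w = wr$numD_HA_w, FP_w = wr$FP_w,
        numR_HA = wr$numR_HA, AD_HA_w = windowed_accuracy(wr),
        false_rate = false_prediction_rate(wr, denominator_mode),
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "denominator_mode") <- denominator_mode
  attr(report, "predictions") <- preds
  class(report) <- c("evaluation_report", "data.frame")
  report
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @return paths of the two files, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE))
    stop("cannot create report directory: ", dir, call. = FALSE)
  df <- as.data.frame(report)
  csv <- file.path(dir, "report.csv")
  chr_cols <- lapply(df, function(col)
    if (is.numeric(col)) num_chr(col) else as.character(col))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(chr_cols, sep = ",")))
  con <- file(csv, "wb")
  writeLines(lines, con)
  close(con)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(df, json, dataframe = "rows", na = "null",
                       digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = json))
}
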