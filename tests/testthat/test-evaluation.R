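# Evaluation mathematics: confusion counts, the two accuracy definitions,
# precision/recall/F1, and the windowed hit statistics with their
# reduction, conservation and monotonicity laws.

series_from <- function(P, R, start = as.Date("2020-06-01")) {
  data.frame(location_id = "locA", series_id = 1L,
             date = start + seq_along(P) - 1,
             actual = as.integer(R), predicted = as.integer(P))
}

test_that("confusion counting follows the actual-by-predicted convention", {
  cm <- confusion_matrix(series_from(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(unclass(cm)[c("TN", "FP", "FN", "TP")],
               list(TN = 1L, FP = 0L, FN = 0L, TP = 2L))
  R <- c(1, 0, 1, 1, 0)
  cm2 <- confusion_matrix(series_from(1 - R, R))
  expect_equal(cm2$TP + cm2$TN, 0)
})

test_that("confusion counts equal a naive per-element oracle", {
  for (seed in 1:6) {
    s <- random_prediction_series(seed, n = 200)
    cm <- confusion_matrix(s)
    expect_equal(unclass(cm)[c("TN", "FP", "FN", "TP")],
                 oracle_confusion(s), ignore_attr = TRUE)
  }
})

test_that("the reported test-set confusion matrices reproduce the printed accuracies", {
  ref <- reference_test_counts()
  for (i in seq_len(nrow(ref))) {
    acc <- accuracy(confusion_counts(ref$TN[i], ref$FP[i], ref$FN[i],
                                     ref$TP[i]))
    expect_equal(round(100 * acc, 1), ref$accuracy_pct[i],
                 info = ref$model[i])
  }
})

test_that("confusion-matrix accuracy equals the label-wise mean definition", {
  for (seed in 1:8) {
    s <- random_prediction_series(seed, n = 150)
    expect_equal(accuracy(confusion_matrix(s)), accuracy_score(s))
  }
  expect_equal(accuracy(confusion_counts(0, 0, 0, 7)), 1.0)
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)), "empty")
})

test_that("precision, recall and F1 follow their formulas and conventions", {
  prf <- precision_recall_f1(confusion_counts(10, 1, 1, 1))
  expect_equal(prf, list(precision = 0.5, recall = 0.5, f1 = 0.5))
  knn <- precision_recall_f1(confusion_counts(1536, 243, 67, 116))
  expect_equal(knn$precision, 116 / 359)
  expect_equal(knn$recall, 116 / 183)
  expect_equal(round(knn$f1, 3), 0.428)
  degenerate <- precision_recall_f1(confusion_counts(10, 3, 4, 0))
  expect_equal(degenerate$f1, 0)
  expect_equal(precision_recall_f1(confusion_counts(10, 0, 0, 0))$precision,
               0)
})

test_that("windowed crediting matches the three-day rule, forward only", {
  hit <- windowed_hits(series_from(c(1, 0, 0), c(0, 0, 1)), w = 3)
  expect_equal(hit$numD_HA_w, 1)
  expect_equal(hit$FP_w, 0)
  backward <- windowed_hits(series_from(c(0, 0, 1), c(1, 0, 0)), w = 3)
  expect_equal(backward$numD_HA_w, 0)
  expect_equal(backward$FP_w, 1)
  # window truncates at the series end
  tail_pred <- windowed_hits(series_from(c(0, 0, 1), c(0, 0, 0)), w = 5)
  expect_equal(tail_pred$FP_w, 1)
  expect_error(windowed_hits(series_from(1, 1), w = 0), "w must be")
})

test_that("windows never credit across series boundaries", {
  s <- rbind(series_from(c(0, 0, 1), c(0, 0, 0)),
             data.frame(location_id = "locB", series_id = 2L,
                        date = as.Date("2020-06-04") + 0:2,
                        actual = c(1L, 0L, 0L), predicted = c(0L, 0L, 0L)))
  res <- windowed_hits(s, w = 3)
  expect_equal(res$numD_HA_w, 0)
  expect_equal(res$FP_w, 1)
})

test_that("windowed counts equal the brute-force double-loop oracle", {
  for (seed in 1:20) {
    s <- random_prediction_series(seed, n = 60, n_series = 2)
    for (w in c(1, 3, 5)) {
      got <- windowed_hits(s, w)
      want <- oracle_windowed(s, w)
      expect_equal(got$numD_HA_w, want$hits)
      expect_equal(got$FP_w, want$falses)
      expect_equal(got$numR_HA, want$num_real)
    }
  }
})

test_that("w = 1 reduces exactly to (TP, FP) and conservation holds at all w", {
  for (seed in 1:10) {
    s <- random_prediction_series(seed, n = 80)
    cm <- confusion_matrix(s)
    one <- windowed_hits(s, 1)
    expect_equal(one$numD_HA_w, cm$TP)
    expect_equal(one$FP_w, cm$FP)
    for (w in c(1, 3, 5))
      expect_equal(with(windowed_hits(s, w), numD_HA_w + FP_w),
                   cm$TP + cm$FP)
  }
})

test_that("hits grow and false predictions shrink with the window length", {
  for (seed in 1:10) {
    s <- random_prediction_series(seed, n = 100, p_pred = 0.4)
    res <- lapply(c(1, 3, 5), function(w) windowed_hits(s, w))
    hits <- vapply(res, `[[`, 0L, "numD_HA_w")
    falses <- vapply(res, `[[`, 0L, "FP_w")
    expect_true(all(diff(hits) >= 0))
    expect_true(all(diff(falses) <= 0))
  }
})

test_that("same-day hit accuracy matches its confusion-count form", {
  # worked example from the reported test set: the tree's TP = 146 of
  # numR_HA = 183 occurrence days gives 79.8% same-day hit accuracy
  dt <- confusion_counts(1553, 226, 37, 146)
  expect_equal(round(100 * dt$TP / (dt$TP + dt$FN), 1), 79.8)
  for (seed in 1:5) {
    s <- random_prediction_series(seed, n = 90)
    one <- windowed_hits(s, 1)
    cm <- confusion_matrix(s)
    expect_equal(windowed_accuracy(one), cm$TP / (cm$TP + cm$FN))
  }
  none <- windowed_hits(series_from(c(1, 0), c(0, 0)), 1)
  expect_true(is.na(windowed_accuracy(none)))
  zero <- windowed_hits(series_from(c(0, 0), c(1, 0)), 1)
  expect_equal(windowed_accuracy(zero), 0)
})

test_that("false-prediction rates follow both denominator modes", {
  res <- structure(list(w = 5L, numD_HA_w = 0L, FP_w = 20L,
                        numR_HA = 183L, TP = 0L, FP = 20L),
                   class = "windowed_result")
  expect_equal(false_prediction_rate(res, "per_occurrence"), 20 / 183)
  expect_equal(false_prediction_rate(res, "per_prediction"), 1.0)
  clean <- structure(list(w = 3L, numD_HA_w = 4L, FP_w = 0L,
                          numR_HA = 10L, TP = 4L, FP = 0L),
                     class = "windowed_result")
  expect_equal(false_prediction_rate(clean, "per_occurrence"), 0)
  expect_equal(false_prediction_rate(clean, "per_prediction"), 0)
})

test_that("evaluate_models reports perfect and all-negative predictors correctly", {
  fm <- build_lagged_features(
    make_bundle(temperature = round(runif(60, 5, 30), 1),
                occurrence = rep(c(0L, 0L, 0L, 1L), 15)))
  cs <- chronological_split(fm)
  # emulate degenerate predictors through prediction series directly
  s_perf <- data.frame(location_id = cs$test$location_id,
                       series_id = cs$test$series_id,
                       date = cs$test$date, actual = cs$test$label,
                       predicted = cs$test$label)
  expect_equal(accuracy(confusion_matrix(s_perf)), 1)
  expect_equal(windowed_accuracy(windowed_hits(s_perf, 5)), 1)
  expect_equal(windowed_hits(s_perf, 5)$FP_w, 0)
  s_zero <- transform(s_perf, predicted = 0L)
  expect_equal(accuracy(confusion_matrix(s_zero)),
               1 - mean(s_zero$actual))
  expect_equal(windowed_accuracy(windowed_hits(s_zero, 3)), 0)
})

test_that("the evaluation report is internally consistent at w = 1", {
  fm <- toy_matrix(n = 150, seed = 41L, threshold = 18)
  cs <- chronological_split(fm)
  specs <- Filter(function(s) s$name %in% c("Decision Tree", "AdaBoost"),
                  list_models())
  report <- evaluate_models(specs, cs$train, cs$test)
  w1 <- report[report$w == 1, ]
  expect_equal(w1$numD_HA_w, w1$TP)
  expect_equal(w1$FP_w, w1$FP)
  expect_equal(w1$numR_HA, w1$TP + w1$FN)
  expect_equal(w1$accuracy, (w1$TN + w1$TP) /
                 (w1$TN + w1$FP + w1$FN + w1$TP))
  # monotone in w within each model
  for (m in unique(report$model)) {
    sub <- report[report$model == m, ]
    expect_true(all(diff(sub$AD_HA_w[order(sub$w)]) >= 0))
  }
})
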