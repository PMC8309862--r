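# Shared fixture builders and independent brute-force oracles.
# The oracles deliberately use naive per-element loops so they share no
# code path with the package implementations they check.

make_bundle <- function(location_id = "locA",
                        start = as.Date("2019-06-01"),
                        temperature = rep(20, 30),
                        humidity = rep(60, length(temperature)),
                        occurrence = rep(0L, length(temperature))) {
  n <- length(temperature)
  df <- data.frame(location_id = location_id,
                   date = start + seq_len(n) - 1,
                   temperature_c = temperature,
                   relative_humidity_pct = humidity,
                   occurrence = as.integer(occurrence),
                   stringsAsFactors = FALSE)
  validate_bundle(df)
  df
}

random_bundle <- function(seed, n_locations = 2, n_days = 25) {
  withr::with_seed(seed, {
    parts <- lapply(seq_len(n_locations), function(i) {
      make_bundle(location_id = sprintf("L%02d", i),
                  start = as.Date("2020-05-01") + sample(0:30, 1),
                  temperature = round(stats::runif(n_days, 5, 30), 2),
                  humidity = round(stats::runif(n_days, 20, 95), 2),
                  occurrence = stats::rbinom(n_days, 1, 0.2))
    })
    do.call(rbind, parts)
  })
}

# a chronological prediction series over one or more contiguous runs
random_prediction_series <- function(seed, n = 30, n_series = 1,
                                     p_pred = 0.3, p_real = 0.2) {
  withr::with_seed(seed, {
    parts <- lapply(seq_len(n_series), function(i) {
      data.frame(location_id = sprintf("S%02d", i),
                 series_id = i,
                 date = as.Date("2020-04-01") + seq_len(n) - 1,
                 actual = stats::rbinom(n, 1, p_real),
                 predicted = stats::rbinom(n, 1, p_pred))
    })
    do.call(rbind, parts)
  })
}

# naive element-by-element confusion counting
oracle_confusion <- function(series) {
  tn <- fp <- fn <- tp <- 0L
  for (i in seq_len(nrow(series))) {
    a <- series$actual[i]
    p <- series$predicted[i]
    if (a == 0 && p == 0) tn <- tn + 1L
    if (a == 0 && p == 1) fp <- fp + 1L
    if (a == 1 && p == 0) fn <- fn + 1L
    if (a == 1 && p == 1) tp <- tp + 1L
  }
  list(TN = tn, FP = fp, FN = fn, TP = tp)
}

# double-loop windowed scan: for each predicted-positive day, walk the
# next w days of the same series looking for a real occurrence
oracle_windowed <- function(series, w) {
  hits <- falses <- 0L
  for (sid in unique(series$series_id)) {
    part <- series[series$series_id == sid, ]
    part <- part[order(part$date), ]
    n <- nrow(part)
    for (d in seq_len(n)) {
      if (part$predicted[d] != 1) next
      found <- FALSE
      for (k in 0:(w - 1)) {
        if (d + k > n) break
        if (part$actual[d + k] == 1) { found <- TRUE; break }
      }
      if (found) hits <- hits + 1L else falses <- falses + 1L
    }
  }
  list(hits = hits, falses = falses, num_real = sum(series$actual))
}

# confusion counts reported for the study's held-out test set, used as a
# worked example of the evaluation formulas
reference_test_counts <- function() {
  data.frame(
    model = c("K-Nearest Neighbors", "Poly SVM", "Decision Tree",
              "Neural Net", "AdaBoost"),
    TN = c(1536, 1589, 1553, 1587, 1569),
    FP = c(243, 190, 226, 192, 210),
    FN = c(67, 59, 37, 61, 43),
    TP = c(116, 124, 146, 122, 140),
    accuracy_pct = c(84.2, 87.3, 86.6, 87.1, 87.1),
    stringsAsFactors = FALSE)
}

toy_matrix <- function(n = 120, seed = 31L, threshold = 17) {
  # separable toy problem: label = (current-day temperature > threshold)
  b <- withr::with_seed(seed,
    make_bundle(temperature = round(runif(n + 9, 5, 30), 1)))
  b$occurrence <- as.integer(b$temperature_c > threshold)
  build_lagged_features(b)
}

strong_signal_config <- function(seed = 7L, n_locations = 20) {
  simulation_config(n_locations = n_locations, beta0 = -76.7,
                    beta_t = 2.5, beta_rh = 0.25, seed = seed)
}

no_signal_config <- function(seed = 11L) {
  # hazard independent of weather, prevalence fixed at plogis(-1.4) ~ 0.20
  simulation_config(n_locations = 6,
                    seasons = list(c(2019, 150, 259)),
                    beta0 = -1.4, beta_t = 0, beta_rh = 0, seed = seed)
}
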