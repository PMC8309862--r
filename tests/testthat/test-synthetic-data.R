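# Weather/occurrence simulator: degenerate closed forms, AR(1) stationary
# variance, Monte-Carlo hazard checks, determinism and stream isolation.

test_that("noiseless degenerate configs collapse to their constants", {
  cfg <- simulation_config(n_locations = 1,
                           seasons = list(c(2019, 100, 150)),
                           temp_amplitude = 0, temp_noise_sd = 0,
                           temp_ar1 = 0, rh_noise_sd = 0,
                           rh_temp_slope = 0, seed = 3L)
  w <- simulate_weather(cfg, 1)
  expect_equal(w$temperature_c, rep(cfg$temp_mean, nrow(w)))
  expect_equal(w$relative_humidity_pct, rep(cfg$rh_base, nrow(w)))
})

test_that("detrended residual SD matches the stationary AR(1) closed form", {
  # 40 seasons x 250 days = 10,000 simulated days
  seasons <- lapply(1961:2000, function(y) c(y, 1, 250))
  cfg <- simulation_config(n_locations = 1, seasons = seasons,
                           temp_amplitude = 0, temp_noise_sd = 1,
                           temp_ar1 = 0.6, seed = 5L)
  w <- simulate_weather(cfg, 1)
  resid <- w$temperature_c - cfg$temp_mean
  stat_sd <- cfg$temp_noise_sd / sqrt(1 - cfg$temp_ar1^2)
  expect_equal(stats::sd(resid), stat_sd, tolerance = 0.05)
})

test_that("weather generation is deterministic and per-location streams are isolated", {
  cfg3 <- simulation_config(n_locations = 3, seed = 9L)
  cfg5 <- simulation_config(n_locations = 5, seed = 9L)
  w_a <- simulate_weather(cfg3, 2)
  w_b <- simulate_weather(cfg3, 2)
  expect_identical(w_a, w_b)
  # adding locations must not perturb existing series
  expect_identical(as.data.frame(simulate_weather(cfg5, 2)),
                   as.data.frame(w_a))
  # distinct locations get distinct noise
  expect_false(identical(simulate_weather(cfg3, 1)$temperature_c,
                         w_a$temperature_c))
})

test_that("humidity stays in [0, 100] under extreme noise", {
  cfg <- simulation_config(n_locations = 1, rh_noise_sd = 60, seed = 2L)
  w <- simulate_weather(cfg, 1)
  expect_true(all(w$relative_humidity_pct >= 0))
  expect_true(all(w$relative_humidity_pct <= 100))
})

test_that("invalid config fields are rejected by name", {
  expect_error(simulation_config(temp_ar1 = 1), "temp_ar1")
  expect_error(simulation_config(temp_noise_sd = -1), "temp_noise_sd")
  expect_error(simulation_config(n_locations = 0), "n_locations")
  expect_error(simulation_config(seasons = list(c(2019, 200, 100))),
               "seasons")
})

test_that("beta0 = -Inf yields no occurrences at all", {
  cfg <- simulation_config(n_locations = 1, beta0 = -Inf, seed = 4L)
  s <- simulate_occurrence(simulate_weather(cfg, 1), cfg)
  expect_true(all(s$occurrence == 0))
  expect_true(all(s$hazard == 0))
})

test_that("constant hazard 1/2 gives empirical frequency near 0.5", {
  cfg <- simulation_config(n_locations = 4, beta0 = 0, beta_t = 0,
                           beta_rh = 0, seed = 6L)
  b <- generate_dataset(cfg)$bundle
  eligible <- b$hazard > 0
  n <- sum(eligible)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(b$occurrence[eligible]) - 0.5), 3 * se)
})

test_that("empirical positive rate matches the mean analytic hazard (Monte Carlo)", {
  # 122 locations x 2 seasons x 205 eligible days ~ 50,000 eligible days
  cfg <- simulation_config(n_locations = 122, seed = 8L)
  b <- generate_dataset(cfg)$bundle
  segs <- unlist(lapply(split(b$date, b$location_id),
                        function(d) cumsum(c(TRUE, diff(d) != 1))))
  eligible <- unlist(lapply(split(seq_len(nrow(b)),
                                  paste(b$location_id, segs)),
                            function(ix) ix[-(1:9)]))
  h <- b$hazard[eligible]
  se <- sqrt(sum(h * (1 - h))) / length(h)
  expect_gt(length(h), 49000)
  expect_lt(abs(mean(b$occurrence[eligible]) - mean(h)), 3 * se)
})

test_that("occurrence prevalence is monotone in the hazard intercept", {
  prev <- vapply(c(-85, -81.6, -78), function(b0) {
    cfg <- simulation_config(n_locations = 4, beta0 = b0, seed = 10L)
    mean(generate_dataset(cfg)$bundle$occurrence)
  }, 0)
  expect_true(all(diff(prev) > 0))
})

test_that("generate_dataset writes one CSV per location-season plus truth", {
  out <- withr::local_tempdir()
  cfg <- simulation_config(n_locations = 17, seed = 12L)
  gen <- generate_dataset(cfg, out)
  series_files <- grep("series_", gen$files, value = TRUE)
  expect_length(series_files, 34)
  expect_true(file.exists(file.path(out, "truth.csv")))
  # byte-identical regeneration
  out2 <- withr::local_tempdir()
  gen2 <- generate_dataset(cfg, out2)
  for (i in seq_along(gen$files))
    expect_identical(readLines(gen$files[i]), readLines(gen2$files[i]))
})

test_that("the trap-network-scale config hits the intended class imbalance", {
  # 17 locations, one 125-day season: 1,972 eligible days; hazard
  # intercept calibrated so the mean analytic hazard of this weather
  # realization is 9.3% (the residual check is pure label noise)
  cfg <- simulation_config(n_locations = 17,
                           seasons = list(c(2019, 91, 215)),
                           beta0 = -81.727, seed = 13L)
  b <- generate_dataset(cfg)$bundle
  fm <- build_lagged_features(b)
  expect_equal(nrow(fm), 17 * 116)
  p <- mean(fm$label)
  se <- sqrt(0.093 * 0.907 / nrow(fm))
  expect_lt(abs(p - 0.093), 2 * se)
})

test_that("bayes_rate returns the closed-form answers in degenerate cases", {
  none <- data.frame(hazard = rep(0, 50), occurrence = rep(0L, 50))
  expect_equal(bayes_rate(none)$expected, 1.0)
  coin <- data.frame(hazard = rep(0.5, 50),
                     occurrence = rep(c(0L, 1L), 25))
  expect_equal(bayes_rate(coin)$expected, 0.5)
  expect_error(bayes_rate(data.frame(occurrence = 1L)), "hazard")
})

test_that("realized Bayes accuracy sits within sampling error of its expectation", {
  cfg <- strong_signal_config(seed = 14L, n_locations = 6)
  b <- generate_dataset(cfg)$bundle
  br <- bayes_rate(b)
  acc <- pmax(b$hazard, 1 - b$hazard)
  se <- sqrt(sum(acc * (1 - acc))) / nrow(b)
  expect_lt(abs(br$realized - br$expected), 3 * se)
})
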