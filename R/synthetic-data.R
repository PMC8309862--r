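# Seasonal weather + occurrence simulator with known logistic hazards.
# Ground truth (per-day hazard) is carried alongside the labels so that
# classifier accuracy can be benchmarked against the Bayes rate.

#' Simulation configuration for synthetic trap/weather data
#'
#' Builds and validates the parameter set that drives the synthetic daily
#' weather and insect-occurrence generator. Temperature follows a seasonal
#' sinusoid plus AR(1) noise; relative humidity is negatively coupled to
#' temperature with independent Gaussian noise, clipped to \[0, 100\];
#' occurrence on day d is Bernoulli with a logistic hazard in the 10-day
#' trailing means of temperature and humidity, so the generative signal
#' lives exactly in the lag window the feature extractor reads.
#'
#' Defaults emulate a two-year, 17-location monitoring network over
#' April--October growing seasons in a temperate climate, with the hazard
#' intercept calibrated so that roughly 9\% of eligible days are occurrence
#' days (strong class imbalance, as trap data typically show).
#'
#' @param n_locations number of monitored locations.
#' @param seasons list of numeric triples `c(year, start_doy, end_doy)`;
#'   each location is simulated over every season.
#' @param temp_mean annual mean air temperature, degrees C.
#' @param temp_amplitude seasonal half-range of the temperature cycle,
#'   degrees C.
#' @param temp_phase day-of-year at which the seasonal cycle peaks.
#' @param temp_noise_sd innovation SD of the AR(1) temperature noise,
#'   degrees C.
#' @param temp_ar1 AR(1) coefficient of the temperature noise, in \[0, 1).
#' @param rh_base relative humidity, percent, at `temp_mean`.
#' @param rh_temp_slope change in humidity per degree C above `temp_mean`
#'   (typically negative).
#' @param rh_noise_sd SD of the independent humidity noise, percent.
#' @param beta0,beta_t,beta_rh logistic hazard coefficients: intercept,
#'   per degree C of 10-day mean temperature, per percent of 10-day mean
#'   humidity. `beta0 = -Inf` disables occurrence entirely.
#' @param seed master integer seed; one independent stream per
#'   (location, season) is derived from it, so adding locations never
#'   perturbs existing series.
#'
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_locations = 17,
                              seasons = list(c(2019, 91, 304),
                                             c(2020, 91, 304)),
                              temp_mean = 17,
                              temp_amplitude = 9,
                              temp_phase = 199,
                              temp_noise_sd = 2.5,
                              temp_ar1 = 0.6,
                              rh_base = 70,
                              rh_temp_slope = -1.5,
                              rh_noise_sd = 8,
                              beta0 = -81.6,
                              beta_t = 2.5,
                              beta_rh = 0.25,
                              seed = 1L) {
  cfg <- list(n_locations = n_locations, seasons = seasons,
              temp_mean = temp_mean, temp_amplitude = temp_amplitude,
              temp_phase = temp_phase, temp_noise_sd = temp_noise_sd,
              temp_ar1 = temp_ar1, rh_base = rh_base,
              rh_temp_slope = rh_temp_slope, rh_noise_sd = rh_noise_sd,
              beta0 = beta0, beta_t = beta_t, beta_rh = beta_rh,
              seed = as.integer(seed))

  check_num <- function(x, field, len = 1L) {
    if (!is.numeric(x) || length(x) != len || anyNA(x))
      stop("invalid simulation config: field '", field, "' must be numeric",
           call. = FALSE)
  }
  check_num(cfg$n_locations, "n_locations")
  if (cfg$n_locations < 1 || cfg$n_locations != round(cfg$n_locations))
    stop("invalid simulation config: field 'n_locations' must be a positive integer",
         call. = FALSE)
  if (!is.list(cfg$seasons) || length(cfg$seasons) == 0)
    stop("invalid simulation config: field 'seasons' must be a non-empty list",
         call. = FALSE)
  for (s in cfg$seasons) {
    if (!is.numeric(s) || length(s) != 3)
      stop("invalid simulation config: field 'seasons' entries must be c(year, start_doy, end_doy)",
           call. = FALSE)
    if (!(1 <= s[2] && s[2] < s[3] && s[3] <= 366))
      stop("invalid simulation config: field 'seasons' requires 1 <= start < end <= 366",
           call. = FALSE)
  }
  for (f in c("temp_mean", "temp_amplitude", "temp_phase", "temp_noise_sd",
              "temp_ar1", "rh_base", "rh_temp_slope", "rh_noise_sd",
              "beta_t", "beta_rh"))
    check_num(cfg[[f]], f)
  if (!is.numeric(cfg$beta0) || length(cfg$beta0) != 1 || is.na(cfg$beta0))
    stop("invalid simulation config: field 'beta0' must be numeric (may be -Inf)",
         call. = FALSE)
  if (cfg$temp_ar1 < 0 || cfg$temp_ar1 >= 1)
    stop("invalid simulation config: field 'temp_ar1' must lie in [0, 1)",
         call. = FALSE)
  if (cfg$temp_noise_sd < 0)
    stop("invalid simulation config: field 'temp_noise_sd' must be >= 0",
         call. = FALSE)
  if (cfg$rh_noise_sd < 0)
    stop("invalid simulation config: field 'rh_noise_sd' must be >= 0",
         call. = FALSE)
  if (is.na(cfg$seed))
    stop("invalid simulation config: field 'seed' must be an integer",
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Independent, reproducible sub-stream seed per (location, season, purpose).
# Kept below 2^31 - 1 so set.seed() always accepts it.
derive_stream_seed <- function(seed, location_index, season_index, salt = 0) {
  as.integer((abs(as.numeric(seed)) * 48271 +
                location_index * 100003 +
                season_index * 7919 +
                salt * 433) %% 2147483647)
}

season_dates <- function(season) {
  origin <- as.Date(sprintf("%d-01-01", season[1]))
  origin + (seq(season[2], season[3]) - 1)
}

#' Simulate daily weather for one location
#'
#' Generates temperature and relative humidity for every season in the
#' configuration, one contiguous block of consecutive days per season.
#' Temperature on day t is
#' `temp_mean + temp_amplitude * sin(2*pi*(t - temp_phase)/365.25 + pi/2) + e_t`
#' with `e_t` an AR(1) process (coefficient `temp_ar1`, innovation SD
#' `temp_noise_sd`) started from its stationary distribution. Humidity is
#' `rh_base + rh_temp_slope * (T - temp_mean)` plus independent Gaussian
#' noise, clipped to \[0, 100\]. Values are rounded to 0.001 (finer than any
#' field sensor) so the CSV round trip is exact.
#'
#' @param config a [simulation_config()].
#' @param location_index 1-based location index, at most `n_locations`.
#' @return a `daily_bundle` data frame with `occurrence` missing (`NA`).
#' @export
simulate_weather <- function(config, location_index) {
  stopifnot(inherits(config, "sim_config"))
  if (location_index < 1 || location_index > config$n_locations)
    stop("location_index must lie in 1..n_locations", call. = FALSE)

  out <- lapply(seq_along(config$seasons), function(j) {
    season <- config$seasons[[j]]
    dates <- season_dates(season)
    doy <- as.integer(strftime(dates, "%j"))
    n <- length(dates)
    stream <- derive_stream_seed(config$seed, location_index, j, salt = 0)
    withr::with_seed(stream, {
      e <- numeric(n)
      stat_sd <- if (config$temp_noise_sd == 0) 0 else
        config$temp_noise_sd / sqrt(1 - config$temp_ar1^2)
      e[1] <- stats::rnorm(1, 0, stat_sd)
      if (n > 1) {
        innov <- stats::rnorm(n - 1, 0, config$temp_noise_sd)
        for (t in 2:n) e[t] <- config$temp_ar1 * e[t - 1] + innov[t - 1]
      }
      temp <- config$temp_mean +
        config$temp_amplitude *
          sin(2 * pi * (doy - config$temp_phase) / 365.25 + pi / 2) + e
      rh <- config$rh_base +
        config$rh_temp_slope * (temp - config$temp_mean) +
        stats::rnorm(n, 0, config$rh_noise_sd)
    })
    rh <- pmin(pmax(rh, 0), 100)
    data.frame(location_id = sprintf("loc%02d", location_index),
               date = dates,
               temperature_c = round(temp, 3),
               relative_humidity_pct = round(rh, 3),
               occurrence = NA_integer_,
               stringsAsFactors = FALSE)
  })
  new_daily_bundle(do.call(rbind, out))
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Fill in weather-driven occurrence labels
#'
#' For each day with at least 9 observed predecessors in its contiguous
#' season, the occurrence label is Bernoulli with hazard
#' `plogis(beta0 + beta_t * mean(T, 10 days) + beta_rh * mean(RH, 10 days))`.
#' The first 9 days of each season are labelled 0 (they are never emitted
#' as model samples, since the lag window cannot be formed) and carry
#' hazard 0. The per-day hazard is returned in a `hazard` column as ground
#' truth for recovery tests; [write_daily_csv()] drops it.
#'
#' @param series a `daily_bundle` with complete weather fields.
#' @param config a [simulation_config()] supplying the hazard coefficients
#'   and seed.
#' @return the bundle with `occurrence` filled and a `hazard` column added.
#' @export
simulate_occurrence <- function(series, config) {
  stopifnot(inherits(config, "sim_config"))
  series <- as_daily_bundle(series)
  bad <- is.na(series$temperature_c) | is.na(series$relative_humidity_pct)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("missing weather value on ", series$date[i], " at location ",
         series$location_id[i], call. = FALSE)
  }
  segs <- segment_ids(series)
  parts <- split(series, segs)
  keys <- split(seq_len(nrow(series)), segs)
  # season ordinal within each location, so streams do not depend on how
  # many locations share the bundle
  loc_of <- vapply(parts, function(p) as.character(p$location_id[1]), "")
  ordinal <- stats::ave(seq_along(parts), loc_of, FUN = seq_along)
  for (k in seq_along(parts)) {
    part <- parts[[k]]
    n <- nrow(part)
    if (n < 10)
      stop("season segment for location ", part$location_id[1],
           " has fewer than 10 consecutive days", call. = FALSE)
    tbar <- trailing_mean(part$temperature_c, 10)
    rhbar <- trailing_mean(part$relative_humidity_pct, 10)
    eta <- config$beta0 + config$beta_t * tbar + config$beta_rh * rhbar
    hazard <- ifelse(is.na(tbar), 0, logistic(eta))
    hazard[is.nan(hazard)] <- 0  # beta0 = -Inf
    chars <- utf8ToInt(as.character(part$location_id[1]))
    loc_code <- sum(chars * seq_along(chars))
    stream <- derive_stream_seed(config$seed, loc_code, ordinal[k], salt = 1)
    occ <- withr::with_seed(stream,
                            stats::rbinom(n, 1, hazard))
    series$occurrence[keys[[k]]] <- as.integer(occ)
    series$hazard[keys[[k]]] <- hazard
  }
  new_daily_bundle(series)
}

trailing_mean <- function(x, k) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 1))
}

#' Generate and write a full synthetic dataset
#'
#' Simulates weather and occurrence for every (location, season) pair and
#' writes one CSV series per pair in the daily schema, plus a sidecar
#' `truth.csv` (`location_id,date,hazard`) recording the per-day hazard
#' probabilities for oracle tests.
#'
#' @param config a [simulation_config()].
#' @param output_path directory to write into (created if needed); `NULL`
#'   skips writing and only returns the bundle.
#' @return invisibly, a list with the combined `bundle` (including the
#'   `hazard` column) and the vector of written `files`.
#' @export
generate_dataset <- function(config, output_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bundles <- lapply(seq_len(config$n_locations), function(i)
    simulate_occurrence(simulate_weather(config, i), config))
  bundle <- new_daily_bundle(do.call(rbind, bundles))
  files <- character(0)
  if (!is.null(output_path)) {
    if (!dir.exists(output_path) &&
        !dir.create(output_path, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", output_path, call. = FALSE)
    for (i in seq_len(config$n_locations)) {
      for (j in seq_along(config$seasons)) {
        season <- config$seasons[[j]]
        dates <- season_dates(season)
        sub <- bundle[bundle$location_id == sprintf("loc%02d", i) &
                        bundle$date %in% dates, , drop = FALSE]
        path <- file.path(output_path,
                          sprintf("series_loc%02d_%d.csv", i, season[1]))
        write_daily_csv(new_daily_bundle(sub), path)
        files <- c(files, path)
      }
    }
    truth <- bundle[, c("location_id", "date", "hazard")]
    tpath <- file.path(output_path, "truth.csv")
    lines <- c("location_id,date,hazard",
               paste(truth$location_id, format(truth$date, "%Y-%m-%d"),
                     num_chr(truth$hazard), sep = ","))
    writeLines(lines, tpath)
    files <- c(files, tpath)
  }
  invisible(list(bundle = bundle, files = files))
}

#' Bayes-optimal accuracy of the simulated occurrence process
#'
#' Given per-day true hazards p and realized labels, computes the accuracy
#' of the Bayes classifier (predict 1 iff p > 0.5) against the realized
#' labels, and the expected accuracy `mean(max(p, 1 - p))`. The expected
#' value is the ceiling no classifier trained on the weather features can
#' beat in the long run; recovery tests compare fitted models against it.
#'
#' @param series_with_truth data frame with `hazard` and `occurrence`
#'   columns (e.g. the bundle from [generate_dataset()]).
#' @return list with elements `realized` and `expected`, both in \[0, 1\].
#' @export
bayes_rate <- function(series_with_truth) {
  h <- series_with_truth$hazard
  y <- series_with_truth$occurrence
  if (is.null(h) || anyNA(h))
    stop("per-day hazards are missing; generate data with simulate_occurrence()",
         call. = FALSE)
  pred <- as.integer(h > 0.5)
  list(realized = mean(pred == y), expected = mean(pmax(h, 1 - h)))
}
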