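# 21-variable lagged feature construction and the two split regimes.
#
# Each model sample for day d carries day-of-year plus the temperature and
# relative humidity of days d, d-1, ..., d-9 (columns t_0..t_9, rh_0..rh_9,
# lag 0 = the day itself). A day is eligible only if its 9 predecessors
# were observed within the same contiguous segment of the series.

feature_cols <- function() {
  c("doy", paste0("t_", 0:9), paste0("rh_", 0:9))
}

new_feature_matrix <- function(df, ordering_mode) {
  rownames(df) <- NULL
  attr(df, "ordering_mode") <- ordering_mode
  class(df) <- c("feature_matrix", "data.frame")
  df
}

#' Build the 21-variable lagged feature matrix
#'
#' Emits one sample per day with at least 9 observed predecessors in its
#' contiguous location-season segment: day-of-year plus the 10-day
#' temperature and humidity histories (current day first), with the binary
#' occurrence label. Samples from all locations are pooled in calendar
#' order (chronological mode). Gaps in a series split it into segments; a
#' lag window never spans a gap.
#'
#' @param bundle a labelled `daily_bundle` (occurrence present everywhere).
#' @param forecast_lag non-negative integer; shifts the whole lag window
#'   this many days into the past for ex-ante forecasting. Default 0: the
#'   predicted day's own weather is the first feature.
#' @return a `feature_matrix` data frame with columns `location_id`,
#'   `series_id`, `date`, `doy`, `t_0`..`t_9`, `rh_0`..`rh_9`, `label`.
#' @export
build_lagged_features <- function(bundle, forecast_lag = 0) {
  bundle <- validate_bundle(bundle)
  if (forecast_lag < 0 || forecast_lag != round(forecast_lag))
    stop("forecast_lag must be a non-negative integer", call. = FALSE)
  segs <- segment_ids(bundle)
  parts <- split(as.data.frame(bundle), segs)
  need <- 10 + forecast_lag
  rows <- lapply(seq_along(parts), function(k) {
    part <- parts[[k]]
    m <- nrow(part)
    if (m < need) {
      warning("segment of ", m, " day(s) for location ", part$location_id[1],
              " is shorter than ", need, " days; skipped", call. = FALSE)
      return(NULL)
    }
    if (anyNA(part$occurrence))
      stop("missing occurrence label on ",
           part$date[which(is.na(part$occurrence))[1]], " at location ",
           part$location_id[1], call. = FALSE)
    idx <- seq(need, m)                       # predicted days
    tl <- stats::embed(part$temperature_c, 10) # row i: x[i+9], ..., x[i]
    rl <- stats::embed(part$relative_humidity_pct, 10)
    # window for day d ends at d - forecast_lag, i.e. embed row d - lag - 9
    keep <- seq(1, m - need + 1)
    dates <- part$date[idx]
    out <- data.frame(location_id = part$location_id[idx],
                      series_id = k,
                      date = dates,
                      doy = as.integer(strftime(dates, "%j")),
                      stringsAsFactors = FALSE)
    out <- cbind(out,
                 stats::setNames(as.data.frame(tl[keep, , drop = FALSE]),
                                 paste0("t_", 0:9)),
                 stats::setNames(as.data.frame(rl[keep, , drop = FALSE]),
                                 paste0("rh_", 0:9)))
    out$label <- as.integer(part$occurrence[idx])
    out
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    stop("no segment long enough to form a lag window", call. = FALSE)
  new_feature_matrix(do.call(rbind, rows), "chronological")
}

#' Random train/validation split
#'
#' Shuffles the pooled samples and assigns `round(train_fraction * n)` of
#' them to training, the rest to validation: a disjoint, exhaustive
#' partition reproducible from the seed. Both halves are in shuffled mode
#' (calendar order is destroyed, so windowed statistics do not apply).
#'
#' @param matrix a `feature_matrix`.
#' @param train_fraction fraction for training, in (0, 1); default 0.75.
#' @param seed integer seed for the permutation.
#' @return list with elements `train` and `validation`.
#' @export
random_split <- function(matrix, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  n <- nrow(matrix)
  if (n < 4) stop("need at least 4 samples to split", call. = FALSE)
  n_train <- round(train_fraction * n)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  list(train = new_feature_matrix(matrix[perm[seq_len(n_train)], ,
                                         drop = FALSE], "shuffled"),
       validation = new_feature_matrix(matrix[perm[-seq_len(n_train)], ,
                                              drop = FALSE], "shuffled"))
}

#' Chronological train/test split
#'
#' Within each location-season series, the first `ceiling(train_fraction *
#' m)` samples (by date) go to training and the remainder to test, so every
#' test day follows every training day of its series and calendar order is
#' preserved in both halves. This is the split under which the windowed
#' hit statistics are meaningful.
#'
#' @param matrix a `feature_matrix` in chronological mode.
#' @param train_fraction fraction for training, in (0, 1); default 0.75.
#' @return list with elements `train` and `test`.
#' @export
chronological_split <- function(matrix, train_fraction = 0.75) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!identical(attr(matrix, "ordering_mode"), "chronological"))
    stop("chronological split needs a chronological feature matrix; ",
         "this one has been shuffled and its order information is lost",
         call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  in_train <- unlist(lapply(split(seq_len(nrow(matrix)), matrix$series_id),
                            function(ix) {
                              m <- length(ix)
                              k <- ceiling(train_fraction * m)
                              ix <= ix[min(k, m)]
                            }), use.names = FALSE)
  idx <- unlist(split(seq_len(nrow(matrix)), matrix$series_id),
                use.names = FALSE)
  flag <- logical(nrow(matrix))
  flag[idx] <- in_train
  list(train = new_feature_matrix(matrix[flag, , drop = FALSE],
                                  "chronological"),
       test = new_feature_matrix(matrix[!flag, , drop = FALSE],
                                 "chronological"))
}

#' Export a feature matrix to CSV
#'
#' Header: `location_id,date,doy,t_0..t_9,rh_0..rh_9,label`.
#'
#' @param matrix a `feature_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  cols <- c("location_id", "date", "doy", feature_cols()[-1], "label")
  df <- as.data.frame(matrix)[, cols]
  df$date <- format(df$date, "%Y-%m-%d")
  for (cc in setdiff(cols, c("location_id", "date")))
    df[[cc]] <- num_chr(df[[cc]])
  lines <- c(paste(cols, collapse = ","),
             do.call(paste, c(unname(as.list(df)), sep = ",")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
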