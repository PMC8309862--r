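# Fixed daily CSV schema shared by the simulator, the feature extractor
# and the pipeline:
#   location_id,date,temperature_c,relative_humidity_pct,occurrence
# Dates are ISO-8601 (YYYY-MM-DD). Occurrence is 0/1 or empty (missing).

daily_schema <- c("location_id", "date", "temperature_c",
                  "relative_humidity_pct", "occurrence")

new_daily_bundle <- function(df, provenance = NULL) {
  rownames(df) <- NULL
  df <- df[order(df$location_id, df$date), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(provenance)) attr(df, "provenance") <- provenance
  class(df) <- c("daily_bundle", "data.frame")
  df
}

as_daily_bundle <- function(x) {
  if (inherits(x, "daily_bundle")) return(x)
  missing_cols <- setdiff(daily_schema, names(x))
  if (length(missing_cols))
    stop("not a daily bundle: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  new_daily_bundle(as.data.frame(x))
}

#' Validate a daily series bundle
#'
#' Checks the schema invariants: no duplicate (location_id, date) pairs,
#' humidity within \[0, 100\], occurrence in \{0, 1, NA\} and finite
#' temperatures. Called by the readers and writers; exported so external
#' data frames can be checked before use.
#'
#' @param bundle a data frame in the daily schema.
#' @return the validated bundle, invisibly.
#' @export
validate_bundle <- function(bundle) {
  bundle <- as_daily_bundle(bundle)
  key <- paste(bundle$location_id, bundle$date)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (location_id, date) pair: ", d, call. = FALSE)
  }
  rh <- bundle$relative_humidity_pct
  if (any(!is.na(rh) & (rh < 0 | rh > 100)))
    stop("relative humidity outside [0, 100]", call. = FALSE)
  tt <- bundle$temperature_c
  if (any(!is.na(tt) & !is.finite(tt)))
    stop("non-finite temperature value", call. = FALSE)
  occ <- bundle$occurrence
  if (any(!is.na(occ) & !(occ %in% c(0L, 1L))))
    stop("occurrence values must be 0, 1 or missing", call. = FALSE)
  invisible(bundle)
}

# numeric -> character that survives a read round trip (up to 15 significant
# digits; simulated values are rounded well below that)
num_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE,
                                 trim = TRUE)
  }, "")
  out
}

#' Read daily weather/occurrence series from CSV
#'
#' Parses one or more files in the daily schema
#' `location_id,date,temperature_c,relative_humidity_pct,occurrence`,
#' validates every row, and returns a single bundle sorted by location and
#' date. Malformed rows are reported with their file and line number;
#' duplicate (location, date) pairs across all files are an error.
#'
#' @param path one or more CSV file paths, or a single directory (all
#'   `*.csv` files inside, `truth.csv` excluded, are read).
#' @return a `daily_bundle` data frame; the `provenance` attribute maps
#'   each source file to its row count.
#' @export
read_daily_csv <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    path <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    path <- path[basename(path) != "truth.csv"]
  }
  if (!length(path)) stop("no CSV files to read", call. = FALSE)
  parts <- lapply(path, read_one_daily_csv)
  bundle <- do.call(rbind, parts)
  prov <- stats::setNames(vapply(parts, nrow, 0L), path)
  validate_bundle(new_daily_bundle(bundle, provenance = prov))
  new_daily_bundle(bundle, provenance = prov)
}

read_one_daily_csv <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  raw <- utils::read.csv(file, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!identical(names(raw), daily_schema))
    stop("schema error in ", file, ": expected header '",
         paste(daily_schema, collapse = ","), "', found '",
         paste(names(raw), collapse = ","), "'", call. = FALSE)
  if (nrow(raw) == 0)
    return(data.frame(location_id = character(0),
                      date = as.Date(character(0)),
                      temperature_c = numeric(0),
                      relative_humidity_pct = numeric(0),
                      occurrence = integer(0)))
  # header is line 1, so data row i sits on line i + 1
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  fail_rows <- function(bad, what) {
    if (any(bad))
      stop("row-level error in ", file, ": unparseable ", what,
           " on line(s) ", paste(which(bad) + 1L, collapse = ", "),
           call. = FALSE)
  }
  fail_rows(is.na(date), "date")
  temp <- suppressWarnings(as.numeric(raw$temperature_c))
  fail_rows(is.na(temp) & nzchar(raw$temperature_c) |
              !nzchar(raw$temperature_c), "temperature")
  rh <- suppressWarnings(as.numeric(raw$relative_humidity_pct))
  fail_rows(is.na(rh) & nzchar(raw$relative_humidity_pct) |
              !nzchar(raw$relative_humidity_pct), "relative humidity")
  occ_chr <- raw$occurrence
  occ <- rep(NA_integer_, length(occ_chr))
  has <- nzchar(occ_chr)
  occ_num <- suppressWarnings(as.numeric(occ_chr[has]))
  if (any(is.na(occ_num) | !(occ_num %in% c(0, 1))))
    stop("row-level error in ", file, ": occurrence must be 0, 1 or empty",
         " on line(s) ",
         paste(which(has)[is.na(occ_num) | !(occ_num %in% c(0, 1))] + 1L,
               collapse = ", "), call. = FALSE)
  occ[has] <- as.integer(occ_num)
  data.frame(location_id = raw$location_id, date = date,
             temperature_c = temp, relative_humidity_pct = rh,
             occurrence = occ, stringsAsFactors = FALSE)
}

#' Write a bundle to the daily CSV schema
#'
#' Rows are ordered by location then date, dates are ISO-8601, numbers are
#' written with up to 15 significant digits, and missing occurrence is an
#' empty field, so writing is deterministic and `read(write(x)) == x`.
#'
#' @param bundle a valid `daily_bundle`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(bundle, path) {
  bundle <- validate_bundle(bundle)
  occ <- ifelse(is.na(bundle$occurrence), "",
                as.character(bundle$occurrence))
  lines <- c(paste(daily_schema, collapse = ","),
             paste(bundle$location_id,
                   format(bundle$date, "%Y-%m-%d"),
                   num_chr(bundle$temperature_c),
                   num_chr(bundle$relative_humidity_pct),
                   occ, sep = ","))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("I/O error opening ", path, ": ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Merge a weather bundle with trap occurrence counts
#'
#' Inner join on (location_id, date). Trap counts of one or more insects
#' collapse to occurrence label 1 (an appearance day); zero stays 0.
#' Locations present in only one input are dropped with a warning; within
#' shared locations, unmatched dates are dropped and reported via the
#' `unmatched` attribute.
#'
#' @param weather_bundle a `daily_bundle` (occurrence ignored).
#' @param occurrence_bundle data frame with columns `location_id`, `date`
#'   and `count` (non-negative trap counts) or `occurrence` (already 0/1).
#' @return a merged `daily_bundle` with binary occurrence labels.
#' @export
merge_weather_occurrence <- function(weather_bundle, occurrence_bundle) {
  weather_bundle <- validate_bundle(weather_bundle)
  ob <- as.data.frame(occurrence_bundle)
  if (!all(c("location_id", "date") %in% names(ob)))
    stop("occurrence bundle needs location_id and date columns",
         call. = FALSE)
  if ("count" %in% names(ob)) {
    if (any(is.na(ob$count) | ob$count < 0))
      stop("occurrence counts must be non-negative", call. = FALSE)
    ob$occurrence <- as.integer(ob$count >= 1)
  } else if (!("occurrence" %in% names(ob))) {
    stop("occurrence bundle needs a count or occurrence column",
         call. = FALSE)
  }
  w_locs <- unique(weather_bundle$location_id)
  o_locs <- unique(ob$location_id)
  only <- c(setdiff(w_locs, o_locs), setdiff(o_locs, w_locs))
  if (length(only))
    warning("location(s) present in one bundle only, excluded: ",
            paste(only, collapse = ", "), call. = FALSE)
  wk <- paste(weather_bundle$location_id, weather_bundle$date)
  ok <- paste(ob$location_id, ob$date)
  if (anyDuplicated(ok))
    stop("duplicate (location_id, date) pair in occurrence bundle",
         call. = FALSE)
  keep <- wk %in% ok
  merged <- weather_bundle[keep, , drop = FALSE]
  merged$occurrence <- ob$occurrence[match(wk[keep], ok)]
  unmatched <- c(wk[!keep & weather_bundle$location_id %in% o_locs],
                 ok[!(ok %in% wk) & ob$location_id %in% w_locs])
  out <- new_daily_bundle(merged)
  attr(out, "unmatched") <- unmatched
  out
}

# contiguous-run ids within each location (a gap in the date sequence
# starts a new segment; lag features must never span unobserved days)
segment_ids <- function(bundle) {
  if (nrow(bundle) == 0) return(integer(0))
  ord <- order(bundle$location_id, bundle$date)
  stopifnot(identical(ord, seq_len(nrow(bundle))))
  new_loc <- c(TRUE, bundle$location_id[-1] != bundle$location_id[-nrow(bundle)])
  gap <- c(TRUE, as.numeric(diff(bundle$date)) != 1)
  cumsum(new_loc | gap)
}
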