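#' Sonde time series
#'
#' Constructs a validated sonde series: ordered in-situ records of
#' temperature (deg C), salinity (dimensionless, practical scale) and
#' chlorophyll (ug/L) at one site, on either a 15-minute or a calendar-day
#' grid. Any measurement may be missing (`NA`); zero is a legal value and
#' never means missing.
#'
#' @param timestamp `POSIXct` (15-min cadence) or `Date` (daily cadence),
#'   strictly increasing.
#' @param temperature,salinity,chlorophyll Numeric vectors, `NA` allowed.
#' @param site Site identifier.
#' @param cadence `"15-min"` or `"daily"`.
#' @return A `sonde_series` data frame.
#' @export
sonde_series <- function(timestamp, temperature = NA_real_,
                         salinity = NA_real_, chlorophyll = NA_real_,
                         site = "site", cadence = c("15-min", "daily")) {
  cadence <- match.arg(cadence)
  n <- length(timestamp)
  x <- data.frame(timestamp = timestamp,
                  temperature = rep_len(as.numeric(temperature), n),
                  salinity = rep_len(as.numeric(salinity), n),
                  chlorophyll = rep_len(as.numeric(chlorophyll), n))
  if (n == 0) cv_stop("sonde series needs at least one record", "validation")
  if (anyNA(x$timestamp))
    cv_stop("missing timestamps are not allowed", "validation")
  d <- diff(as.numeric(x$timestamp))
  if (any(d <= 0))
    cv_stop(paste0("timestamps must be strictly increasing (violation at row ",
                   which(d <= 0)[1] + 1, ")"), "validation")
  if (cadence == "15-min") {
    if (!inherits(x$timestamp, "POSIXct"))
      cv_stop("15-min cadence requires POSIXct timestamps", "validation")
    if (any(as.numeric(x$timestamp) %% 900 != 0))
      cv_stop("15-min cadence requires timestamps on a 15-minute grid",
              "validation")
  } else {
    if (!inherits(x$timestamp, "Date"))
      cv_stop("daily cadence requires Date timestamps", "validation")
  }
  if (any(x$chlorophyll < 0, na.rm = TRUE))
    cv_stop("chlorophyll must be >= 0", "validation")
  structure(x, site = site, cadence = cadence,
            class = c("sonde_series", "data.frame"))
}

#' Read a sonde CSV
#'
#' Expects columns `timestamp`, `temperature`, `salinity`, `chlorophyll`
#' (plus an optional `site` column). Timestamps are ISO-8601:
#' `YYYY-MM-DDTHH:MM` for 15-minute records, `YYYY-MM-DD` for daily ones,
#' interpreted as naive local time (no daylight-saving arithmetic). Empty
#' cells are preserved as missing, never zero-filled.
#'
#' @param path CSV file path.
#' @param cadence `"15-min"` or `"daily"`.
#' @param site Site identifier used when the file has no `site` column.
#' @return A [sonde_series()].
#' @export
read_sonde_csv <- function(path, cadence = c("15-min", "daily"),
                           site = NULL) {
  cadence <- match.arg(cadence)
  raw <- read_csv_checked(path,
                          c("timestamp", "temperature", "salinity",
                            "chlorophyll"))
  ts <- parse_timestamps(raw$timestamp, cadence, path)
  if (is.null(site))
    site <- if ("site" %in% names(raw)) as.character(raw$site[1]) else "site"
  sonde_series(ts,
               temperature = as_num(raw$temperature, "temperature", path),
               salinity = as_num(raw$salinity, "salinity", path),
               chlorophyll = as_num(raw$chlorophyll, "chlorophyll", path),
               site = site, cadence = cadence)
}

#' Write a sonde series to CSV
#'
#' Round-trips with [read_sonde_csv()]: full printed precision, missing
#' values as empty cells.
#'
#' @param series A `sonde_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sonde_csv <- function(series, path) {
  out <- as.data.frame(series)
  out$timestamp <- format_timestamp(series$timestamp,
                                    attr(series, "cadence"))
  out$site <- attr(series, "site")
  utils::write.csv(out[c("timestamp", "site", "temperature", "salinity",
                         "chlorophyll")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Meteorological daily series
#'
#' One record per calendar date: average and maximum (2-minute sustained)
#' daily wind speed (m/s) and daily rain (mm).
#'
#' @param date `Date` vector, one per calendar date, strictly increasing.
#' @param wind_avg,wind_max,rain Numeric vectors; `wind_max >= wind_avg >= 0`
#'   and `rain >= 0` wherever observed.
#' @return A `met_series` data frame.
#' @export
met_series <- function(date, wind_avg = NA_real_, wind_max = NA_real_,
                       rain = NA_real_) {
  n <- length(date)
  x <- data.frame(date = date,
                  wind_avg = rep_len(as.numeric(wind_avg), n),
                  wind_max = rep_len(as.numeric(wind_max), n),
                  rain = rep_len(as.numeric(rain), n))
  if (!inherits(x$date, "Date"))
    cv_stop("met series requires Date dates", "validation")
  if (anyDuplicated(x$date))
    cv_stop("met series must have one record per calendar date", "validation")
  if (is.unsorted(x$date, strictly = TRUE))
    cv_stop("met dates must be strictly increasing", "validation")
  if (any(x$wind_avg < 0, na.rm = TRUE) || any(x$wind_max < 0, na.rm = TRUE))
    cv_stop("wind speeds must be >= 0", "validation")
  bad <- which(!is.na(x$wind_max) & !is.na(x$wind_avg) &
                 x$wind_max < x$wind_avg)
  if (length(bad))
    cv_stop(paste0("wind_max < wind_avg at row ", bad[1]), "validation")
  if (any(x$rain < 0, na.rm = TRUE))
    cv_stop("rain must be >= 0", "validation")
  structure(x, class = c("met_series", "data.frame"))
}

#' Read a meteorology CSV
#'
#' Expects columns `date`, `wind_avg`, `wind_max`, `rain`, one row per date.
#'
#' @param path CSV file path.
#' @return A [met_series()].
#' @export
read_met_csv <- function(path) {
  raw <- read_csv_checked(path, c("date", "wind_avg", "wind_max", "rain"))
  d <- parse_timestamps(raw$date, "daily", path)
  met_series(d,
             wind_avg = as_num(raw$wind_avg, "wind_avg", path),
             wind_max = as_num(raw$wind_max, "wind_max", path),
             rain = as_num(raw$rain, "rain", path))
}

#' @rdname read_met_csv
#' @param series A `met_series`.
#' @export
write_met_csv <- function(series, path) {
  out <- as.data.frame(series)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Average rain over stations
#'
#' Combines per-station daily rain into a single series by taking, for each
#' date, the arithmetic mean over the stations that report that date. A date
#' reported by no station stays missing.
#'
#' @param stations A list of data frames with columns `date` and `rain`
#'   (a `met_series` works).
#' @return Data frame with columns `date` and `rain`, one row per date seen
#'   at any station.
#' @export
average_rain_stations <- function(stations) {
  if (!length(stations))
    cv_stop("need at least one rain station", "validation")
  long <- do.call(rbind, lapply(stations, function(s)
    data.frame(date = s$date, rain = s$rain)))
  dates <- sort(unique(long$date))
  rain <- vapply(dates, function(d) {
    v <- long$rain[long$date == d]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(date = dates, rain = rain)
}

#' Daily series
#'
#' Daily-resolution record of temperature, salinity and chlorophyll at one
#' site, with per-variable provenance (`observed_complete`, `gap_filled`, or
#' `omitted`) when produced by the QC step.
#'
#' @param date `Date` vector, one per calendar date, strictly increasing.
#' @param temperature,salinity,chlorophyll Numeric, `NA` for missing.
#' @param site Site identifier.
#' @param provenance Optional data frame of per-variable provenance codes.
#' @return A `daily_series` data frame.
#' @export
daily_series <- function(date, temperature = NA_real_, salinity = NA_real_,
                         chlorophyll = NA_real_, site = "site",
                         provenance = NULL) {
  n <- length(date)
  x <- data.frame(date = date,
                  temperature = rep_len(as.numeric(temperature), n),
                  salinity = rep_len(as.numeric(salinity), n),
                  chlorophyll = rep_len(as.numeric(chlorophyll), n))
  if (!inherits(x$date, "Date"))
    cv_stop("daily series requires Date dates", "validation")
  if (anyDuplicated(x$date) || is.unsorted(x$date, strictly = TRUE))
    cv_stop("daily series needs one strictly increasing record per date",
            "validation")
  if (any(x$chlorophyll < 0, na.rm = TRUE))
    cv_stop("chlorophyll must be >= 0", "validation")
  structure(x, site = site, provenance = provenance,
            class = c("daily_series", "data.frame"))
}

#' Read / write daily CSVs
#'
#' Daily CSVs carry columns `date`, `temperature`, `salinity`, `chlorophyll`
#' (and optionally `site`).
#'
#' @param path CSV file path.
#' @param site Site identifier used when the file has no `site` column.
#' @return A [daily_series()].
#' @export
read_daily_csv <- function(path, site = NULL) {
  raw <- read_csv_checked(path, c("date", "temperature", "salinity",
                                  "chlorophyll"))
  d <- parse_timestamps(raw$date, "daily", path)
  if (is.null(site))
    site <- if ("site" %in% names(raw)) as.character(raw$site[1]) else "site"
  daily_series(d,
               temperature = as_num(raw$temperature, "temperature", path),
               salinity = as_num(raw$salinity, "salinity", path),
               chlorophyll = as_num(raw$chlorophyll, "chlorophyll", path),
               site = site)
}

#' @rdname read_daily_csv
#' @param series A `daily_series`.
#' @export
write_daily_csv <- function(series, path) {
  out <- as.data.frame(series)
  out$date <- format(out$date, "%Y-%m-%d")
  out$site <- attr(series, "site")
  utils::write.csv(out[c("date", "site", "temperature", "salinity",
                         "chlorophyll")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a run-metadata record
#'
#' Serialises the configuration, seed and package version next to any
#' analysis output so a run can be reproduced.
#'
#' @param config A [pipeline_config()].
#' @param path Output JSON path.
#' @param extra Optional named list merged into the record.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path, extra = list()) {
  rec <- c(list(package = "chlorovar",
                version = as.character(utils::packageVersion("chlorovar")),
                r_version = as.character(getRversion()),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                config = unclass(config)),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- internal parsing helpers -----------------------------------------------

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) cv_stop(paste0("no such file: ", path), "io")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    cv_stop(paste0(path, ": missing column(s) ",
                   paste(missing_cols, collapse = ", ")), "parse")
  raw
}

parse_timestamps <- function(x, cadence, path) {
  if (cadence == "15-min") {
    out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  } else {
    out <- as.Date(x, format = "%Y-%m-%d")
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    cv_stop(paste0(path, ": malformed timestamp '", x[bad[1]], "' at row ",
                   bad[1]), "parse")
  if (anyNA(out))
    cv_stop(paste0(path, ": empty timestamp at row ", which(is.na(out))[1]),
            "parse")
  out
}

as_num <- function(x, name, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    cv_stop(paste0(path, ": non-numeric ", name, " '", x[bad[1]],
                   "' at row ", bad[1]), "parse")
  out
}

format_timestamp <- function(ts, cadence) {
  if (cadence == "15-min") format(ts, "%Y-%m-%dT%H:%M", tz = "UTC")
  else format(ts, "%Y-%m-%d")
}

#' @export
print.sonde_series <- function(x, ...) {
  cat(sprintf("<sonde_series> site %s, cadence %s, %d records (%s to %s)\n",
              attr(x, "site"), attr(x, "cadence"), nrow(x),
              format_timestamp(x$timestamp[1], attr(x, "cadence")),
              format_timestamp(x$timestamp[nrow(x)], attr(x, "cadence"))))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> site %s, %d days (%s to %s)\n",
              attr(x, "site"), nrow(x), format(x$date[1]),
              format(x$date[nrow(x)])))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
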