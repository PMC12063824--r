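#' Fill internal gaps in a 15-minute record by linear interpolation
#'
#' Regularises the series onto its full 15-minute grid (absent rows become
#' missing slots) and replaces every internal missing run of the chosen
#' variable with values on the straight line between the bracketing
#' observations. Gaps before the first or after the last observation are left
#' missing: interpolation never extrapolates across deployment boundaries.
#' Observed points are returned unchanged, so the operation is idempotent.
#'
#' @param series A 15-minute [sonde_series()].
#' @param variable One of `"temperature"`, `"salinity"`, `"chlorophyll"`, or
#'   `"all"` to fill every variable.
#' @return A `sonde_series` on the complete grid with internal gaps filled.
#' @export
fill_gaps_linear <- function(series, variable = "all") {
  vars <- check_variable(series, variable)
  reg <- regularize_15min(series)
  for (v in vars) {
    y <- reg[[v]]
    obs <- which(!is.na(y))
    if (length(obs) >= 2 && anyNA(y[obs[1]:obs[length(obs)]])) {
      t <- as.numeric(reg$timestamp)
      filled <- stats::approx(t[obs], y[obs], xout = t, method = "linear",
                              rule = 1)$y
      interior <- seq(obs[1], obs[length(obs)])
      y[interior] <- filled[interior]
      reg[[v]] <- y
    }
  }
  reg
}

#' Convert a 15-minute record to daily averages
#'
#' Applies the QC rule for one variable: gaps are assessed on the raw
#' (pre-interpolation) record, and a day is omitted when the longest run of
#' consecutive missing 15-minute points within that 24-hour window strictly
#' exceeds `qc_max_gap` minutes (with the default 60 min, a 60-minute run is
#' retained and a 75-minute run is not). Retained days are averaged over the
#' daily grid after linear interpolation; partial days at the deployment
#' boundaries are retained only when they span at least 23 hours of the grid.
#'
#' @param series A 15-minute [sonde_series()].
#' @param variable `"temperature"`, `"salinity"` or `"chlorophyll"`.
#' @param qc_max_gap Longest tolerated missing run, minutes. Default 60.
#' @return A data frame (class `daily_qc`) with one row per calendar day:
#'   `date`, `value`, `n_obs` (raw points present), `longest_gap_min`, and
#'   `provenance` (`observed_complete`, `gap_filled` or `omitted`).
#' @export
daily_average <- function(series, variable, qc_max_gap = 60) {
  variable <- check_variable(series, variable, allow_all = FALSE)
  raw <- regularize_15min(series)
  filled <- fill_gaps_linear(series, variable)
  day <- as.Date(raw$timestamp, tz = "UTC")
  days <- unique(day)
  res <- lapply(days, function(d) {
    idx <- which(day == d)
    miss <- is.na(raw[[variable]][idx])
    longest <- longest_run(miss) * 15
    n_slots <- length(idx)
    if (longest > qc_max_gap || n_slots < 92) {
      data.frame(date = d, value = NA_real_, n_obs = sum(!miss),
                 longest_gap_min = longest, provenance = "omitted")
    } else {
      prov <- if (any(miss)) "gap_filled" else "observed_complete"
      data.frame(date = d,
                 value = mean(filled[[variable]][idx], na.rm = TRUE),
                 n_obs = sum(!miss), longest_gap_min = longest,
                 provenance = prov)
    }
  })
  out <- do.call(rbind, res)
  class(out) <- c("daily_qc", "data.frame")
  out
}

#' Convert a 15-minute sonde record to a QC'd daily series
#'
#' Runs [daily_average()] for temperature, salinity and chlorophyll and
#' assembles the result into a [daily_series()]; the per-variable QC report
#' is attached as the `qc` attribute and the per-variable provenance as the
#' `provenance` attribute.
#'
#' @param series A 15-minute [sonde_series()].
#' @param qc_max_gap Longest tolerated missing run, minutes.
#' @return A `daily_series`.
#' @export
sonde_to_daily <- function(series, qc_max_gap = 60) {
  vars <- c("temperature", "salinity", "chlorophyll")
  per <- lapply(vars, daily_average, series = series,
                qc_max_gap = qc_max_gap)
  names(per) <- vars
  prov <- data.frame(date = per[[1]]$date,
                     temperature = per$temperature$provenance,
                     salinity = per$salinity$provenance,
                     chlorophyll = per$chlorophyll$provenance)
  out <- daily_series(per[[1]]$date,
                      temperature = per$temperature$value,
                      salinity = per$salinity$value,
                      chlorophyll = per$chlorophyll$value,
                      site = attr(series, "site"),
                      provenance = prov)
  attr(out, "qc") <- per
  out
}

# ---- internals --------------------------------------------------------------

# Expand a 15-min series onto its complete grid; absent rows become NA slots.
regularize_15min <- function(series) {
  if (attr(series, "cadence") != "15-min")
    cv_stop("a 15-minute series is required", "validation")
  grid <- seq(series$timestamp[1], series$timestamp[nrow(series)], by = 900)
  idx <- match(as.numeric(grid), as.numeric(series$timestamp))
  out <- data.frame(timestamp = grid,
                    temperature = series$temperature[idx],
                    salinity = series$salinity[idx],
                    chlorophyll = series$chlorophyll[idx])
  structure(out, site = attr(series, "site"), cadence = "15-min",
            class = c("sonde_series", "data.frame"))
}

check_variable <- function(series, variable, allow_all = TRUE) {
  vars <- c("temperature", "salinity", "chlorophyll")
  if (allow_all && identical(variable, "all")) return(vars)
  if (!variable %in% vars)
    cv_stop(paste0("unknown variable: ", variable), "validation")
  variable
}

longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}
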