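#' Detect bloom trigger pairs on a daily chlorophyll series
#'
#' Enumerates every ordered pair of observed days `(t1, t2)` with
#' `1 <= t2 - t1 <= window - 1` calendar days (so with the default 4-day
#' window the endpoints lie at most 3 days apart, a 4-day inclusive span)
#' whose chlorophyll rise `chl(t2) - chl(t1)` is at least `delta`. The
#' comparison is inclusive: a rise of exactly `delta` triggers. Pairs may
#' bridge omitted days as long as both endpoints are observed. Because all
#' ordered pairs within the span are enumerated, an endpoint-to-endpoint and
#' a min-to-max criterion coincide: the (argmin, argmax) pair of any window
#' is itself enumerated.
#'
#' @param daily A [daily_series()] (or data frame with `date`,
#'   `chlorophyll`).
#' @param delta Minimum rise, ug/L. Default 50.
#' @param window Span in days, inclusive of both endpoints. Default 4.
#' @return Data frame of trigger pairs sorted by `end_date`: `start_date`,
#'   `end_date`, `chl_start`, `chl_end`, `rise`.
#' @export
detect_rises <- function(daily, delta = 50, window = 4) {
  obs <- daily[!is.na(daily$chlorophyll), c("date", "chlorophyll")]
  n <- nrow(obs)
  out <- list()
  for (i in seq_len(n)) {
    j <- i + 1
    while (j <= n && as.numeric(obs$date[j] - obs$date[i]) <= window - 1) {
      rise <- obs$chlorophyll[j] - obs$chlorophyll[i]
      if (rise >= delta)
        out[[length(out) + 1]] <- data.frame(
          start_date = obs$date[i], end_date = obs$date[j],
          chl_start = obs$chlorophyll[i], chl_end = obs$chlorophyll[j],
          rise = rise)
      j <- j + 1
    }
  }
  if (!length(out))
    return(data.frame(start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      chl_start = numeric(), chl_end = numeric(),
                      rise = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$end_date, res$start_date), ]
  rownames(res) <- NULL
  res
}

#' Merge trigger pairs into bloom events and cut analysis windows
#'
#' Clusters trigger pairs by single linkage on their end dates (a gap of at
#' most `merge_window` days joins two pairs), so multiple rises within the
#' merge window are analysed as one event. Each cluster's peak day (day 0)
#' is the maximum observed chlorophyll over the cluster span extended by the
#' context window, ties broken by the earliest date; the analysis window is
#' `[peak - context, peak + context]` trimmed to the extent of the record
#' ("up to" `context` days each side). A final consolidation pass re-merges
#' any events whose peaks end up within `merge_window` of each other, so
#' merged events are always separated by more than `merge_window` days
#' peak-to-peak and the operation is idempotent.
#'
#' @param pairs Trigger pairs from [detect_rises()].
#' @param daily The [daily_series()] the pairs came from.
#' @param merge_window Merge distance, days. Default 14.
#' @param context Context days either side of the peak. Default 14.
#' @return A `bloom_events` data frame: `site`, `peak_date`, `peak_chl`,
#'   `window_start`, `window_end`, `n_days` (observed chlorophyll days in
#'   the window), `n_triggers`; the trigger pairs of each event are kept in
#'   the `triggers` list column.
#' @export
merge_events <- function(pairs, daily, merge_window = 14, context = 14) {
  site <- attr(daily, "site")
  if (is.null(site)) site <- "site"
  empty <- data.frame(site = character(), peak_date = as.Date(character()),
                      peak_chl = numeric(),
                      window_start = as.Date(character()),
                      window_end = as.Date(character()),
                      n_days = integer(), n_triggers = integer())
  if (is.null(pairs) || !nrow(pairs)) {
    empty$triggers <- list()
    class(empty) <- c("bloom_events", "data.frame")
    return(empty)
  }
  pairs <- pairs[order(pairs$end_date, pairs$start_date), ]
  gap <- c(0, diff(as.numeric(pairs$end_date)))
  cluster <- cumsum(gap > merge_window)

  obs <- daily[!is.na(daily$chlorophyll), c("date", "chlorophyll")]
  rec_start <- min(obs$date)
  rec_end <- max(obs$date)

  make_event <- function(p) {
    span_lo <- min(p$start_date) - context
    span_hi <- max(p$end_date) + context
    in_span <- obs$date >= span_lo & obs$date <= span_hi
    cand <- obs[in_span, ]
    peak_i <- which.max(cand$chlorophyll)   # first max: earliest-date tie-break
    peak <- cand$date[peak_i]
    w_lo <- max(peak - context, rec_start)
    w_hi <- min(peak + context, rec_end)
    data.frame(site = site, peak_date = peak,
               peak_chl = cand$chlorophyll[peak_i],
               window_start = w_lo, window_end = w_hi,
               n_days = sum(obs$date >= w_lo & obs$date <= w_hi),
               n_triggers = nrow(p))
  }

  groups <- split(pairs, cluster)
  ev <- do.call(rbind, lapply(groups, make_event))
  ev$triggers <- unname(groups)

  # consolidation: peaks must be > merge_window apart after merging
  repeat {
    ev <- ev[order(ev$peak_date), ]
    sep <- diff(as.numeric(ev$peak_date))
    if (!length(sep) || all(sep > merge_window)) break
    k <- which(sep <= merge_window)[1]
    merged_pairs <- rbind(ev$triggers[[k]], ev$triggers[[k + 1]])
    newev <- make_event(merged_pairs)
    newev$triggers <- list(merged_pairs)
    ev <- rbind(ev[-c(k, k + 1), ], newev)
  }
  rownames(ev) <- NULL
  class(ev) <- c("bloom_events", "data.frame")
  ev
}

#' Detect, merge and window bloom events in one call
#'
#' @param daily A [daily_series()].
#' @param config A [pipeline_config()].
#' @return A `bloom_events` data frame (see [merge_events()]).
#' @export
detect_blooms <- function(daily, config = pipeline_config()) {
  pairs <- detect_rises(daily, delta = config$bloom_delta,
                        window = config$bloom_window)
  merge_events(pairs, daily, merge_window = config$merge_window,
               context = config$event_context)
}

#' Write detected events to CSV
#'
#' @param events A `bloom_events` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  out <- as.data.frame(events[setdiff(names(events), "triggers")])
  out$peak_date <- format(out$peak_date, "%Y-%m-%d")
  out$window_start <- format(out$window_start, "%Y-%m-%d")
  out$window_end <- format(out$window_end, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
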