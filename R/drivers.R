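#' Assemble the regression frame for one bloom event
#'
#' Joins the daily sonde record and the meteorology over the event window
#' into one frame with the response (chlorophyll, ug/L) and the candidate
#' drivers: average wind speed, its one-day lag, maximum wind speed,
#' temperature, and rain. Lag-1 values are the previous calendar day's
#' meteorology. The event is flagged not analyzable when the meteorology
#' does not cover the window (including the lag day) completely — this is
#' the coverage filter that decides which detected events can be modelled.
#' Candidates with zero variance over the window (for example rain during a
#' rain-free event) are dropped with a message. Complete-case rows are fixed
#' here, once, so every candidate model downstream is fitted on identical
#' data.
#'
#' @param event One row of a `bloom_events` frame (or any list with
#'   `window_start`, `window_end`).
#' @param daily The [daily_series()].
#' @param met A [met_series()].
#' @return An `event_frame` list: `data` (rows with complete response and
#'   candidates), `response`, `candidates`, `dropped` (zero-variance),
#'   `analyzable`, `n`.
#' @export
build_event_frame <- function(event, daily, met) {
  dates <- seq(as.Date(event$window_start), as.Date(event$window_end),
               by = "day")
  need <- c(dates[1] - 1, dates)      # lag-1 needs the day before the window
  mi <- match(need, met$date)
  met_ok <- !anyNA(mi) &&
    !anyNA(met$wind_avg[mi]) && !anyNA(met$wind_max[mi]) &&
    !anyNA(met$rain[mi])
  if (!met_ok) {
    return(structure(list(data = NULL, response = "chlorophyll",
                          candidates = character(), dropped = character(),
                          analyzable = FALSE, n = 0L),
                     class = "event_frame"))
  }
  di <- match(dates, daily$date)
  mw <- match(dates, met$date)
  mlag <- match(dates - 1, met$date)
  df <- data.frame(date = dates,
                   chlorophyll = if (all(is.na(di))) NA_real_ else
                     daily$chlorophyll[di],
                   wind_avg = met$wind_avg[mw],
                   wind_avg_lag1 = met$wind_avg[mlag],
                   wind_max = met$wind_max[mw],
                   temperature = if (all(is.na(di))) NA_real_ else
                     daily$temperature[di],
                   rain = met$rain[mw])
  candidates <- c("wind_avg", "wind_avg_lag1", "wind_max", "temperature",
                  "rain")
  df <- df[stats::complete.cases(df[c("chlorophyll", candidates)]), ]
  keep <- vapply(candidates,
                 function(v) stats::sd(df[[v]]) > 0, logical(1))
  dropped <- candidates[!keep]
  if (length(dropped))
    message("dropping zero-variance candidate(s): ",
            paste(dropped, collapse = ", "))
  structure(list(data = df, response = "chlorophyll",
                 candidates = candidates[keep], dropped = dropped,
                 analyzable = TRUE, n = nrow(df)),
            class = "event_frame")
}

#' Cross-correlation screening of a one-day lagged predictor
#'
#' Computes the Pearson cross-correlation between the response and a
#' predictor at lag 0 and at lag 1 (predictor leading the response by one
#' day) and decides whether the lag-1 variant belongs in the candidate set:
#' it is included when `|r(lag 1)|` reaches the white-noise bound
#' `bound_mult / sqrt(n)`, with `n` the number of lag-1 pairs.
#'
#' @param chl Response values, in time order.
#' @param predictor Predictor values on the same dates.
#' @param max_lag Largest lag screened (only 1 is supported). Default 1.
#' @param bound_mult Bound multiplier. Default 1.96.
#' @return List: `r_lag0`, `r_lag1`, `n`, `bound`, `include_lag1`.
#' @export
ccf_screen <- function(chl, predictor, max_lag = 1, bound_mult = 1.96) {
  stopifnot(length(chl) == length(predictor), max_lag == 1)
  ok <- stats::complete.cases(chl, predictor)
  chl <- chl[ok]; predictor <- predictor[ok]
  n_all <- length(chl)
  if (n_all < 6)
    cv_stop("cross-correlation screening needs at least 6 paired values",
            "validation")
  if (stats::sd(chl) == 0 || stats::sd(predictor) == 0) {
    warning("constant input: lag-1 term excluded")
    return(list(r_lag0 = NA_real_, r_lag1 = NA_real_, n = n_all - 1L,
                bound = bound_mult / sqrt(n_all - 1), include_lag1 = FALSE))
  }
  r0 <- stats::cor(chl, predictor)
  x_lead <- predictor[-n_all]
  y <- chl[-1]
  n1 <- n_all - 1L
  r1 <- if (stats::sd(x_lead) == 0 || stats::sd(y) == 0) 0 else
    stats::cor(y, x_lead)
  bound <- bound_mult / sqrt(n1)
  list(r_lag0 = r0, r_lag1 = r1, n = n1, bound = bound,
       include_lag1 = abs(r1) >= bound)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = n log(rss/n) + 2k + 2k(k+1)/(n - k - 1)`, with `k` counting the
#' intercept, the slopes and the residual variance (`k = terms + 2`), the
#' convention of standard information-criterion model-selection tooling.
#' Lower is better when models share the data.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of rows.
#' @param k Number of estimated parameters.
#' @return The AICc value, or `NA` when `n - k - 1 < 1` (model not
#'   comparable).
#' @export
aicc <- function(rss, n, k) {
  if (rss <= 0) cv_stop("aicc requires rss > 0", "validation")
  if (n - k - 1 < 1) return(NA_real_)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Enumerate all additive model subsets ranked by AICc
#'
#' Fits every subset of the candidate predictors (including the
#' intercept-only model) by ordinary least squares on the frame's fixed
#' complete-case rows and ranks the subsets by ascending AICc. Subsets whose
#' small-sample correction is undefined (`n - k - 1 <= 0`) are skipped.
#'
#' @param frame An [build_event_frame()] result (analyzable).
#' @param candidates Candidate predictors; defaults to the frame's.
#' @return Data frame sorted by `aicc`: `terms` (`+`-joined, `"1"` for
#'   intercept-only), `k`, `rss`, `aicc`, `adj_r2`.
#' @export
enumerate_models <- function(frame, candidates = frame$candidates) {
  stopifnot(inherits(frame, "event_frame"), frame$analyzable)
  p <- length(candidates)
  if (p > 12)
    cv_stop("refusing to enumerate more than 2^12 model subsets", "validation")
  df <- frame$data
  n <- nrow(df)
  rows <- lapply(seq_len(2^p) - 1, function(code) {
    terms <- candidates[bitwAnd(code, 2^(seq_len(p) - 1)) > 0]
    k <- length(terms) + 2
    if (n - k - 1 <= 0) return(NULL)
    fit <- ols_fit(df, frame$response, terms)
    data.frame(terms = if (length(terms)) paste(terms, collapse = "+") else "1",
               k = k, rss = fit$rss, aicc = aicc(fit$rss, n, k),
               adj_r2 = fit$adj_r2)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    cv_stop("no model subset is estimable on this frame", "validation")
  out <- out[order(out$aicc), ]
  rownames(out) <- NULL
  out
}

#' Prune collinear candidate predictors
#'
#' While any candidate pair has absolute pairwise Pearson correlation at or
#' above the threshold, drops the member less correlated (in absolute value)
#' with the response. The pair with the largest absolute correlation is
#' resolved first; ties fall back to candidate order, so the procedure is
#' deterministic.
#'
#' @param frame An [build_event_frame()] result.
#' @param r_threshold Absolute correlation threshold. Default 0.7.
#' @return The frame with its `candidates` reduced; dropped names appended
#'   to `dropped`.
#' @export
prune_collinear <- function(frame, r_threshold = 0.7) {
  stopifnot(inherits(frame, "event_frame"), frame$analyzable)
  cand <- frame$candidates
  df <- frame$data
  repeat {
    if (length(cand) < 2) break
    cm <- abs(stats::cor(df[cand]))
    diag(cm) <- 0
    if (max(cm) < r_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    pair <- cand[sort(idx)]
    rcor <- abs(vapply(pair, function(v)
      stats::cor(df[[v]], df[[frame$response]]), numeric(1)))
    drop <- if (rcor[1] < rcor[2]) pair[1] else pair[2]
    frame$dropped <- c(frame$dropped, drop)
    cand <- setdiff(cand, drop)
  }
  frame$candidates <- cand
  frame
}

#' Backward elimination to an all-significant model
#'
#' Starting from a term set (typically the AICc-best subset), iteratively
#' refits after removing the largest-p term while any term has `p > alpha`.
#' If every term is eliminated the intercept-only model is returned, flagged
#' as having no significant driver.
#'
#' @param terms Character vector of starting terms (may be `"1"` or empty).
#' @param frame An [build_event_frame()] result.
#' @param alpha Significance level. Default 0.05.
#' @return A `driver_model_fit` list: `terms`, `coefficients` (incl.
#'   intercept), `p_values` (per term), `adj_r2`, `model_p` (overall
#'   F-test), `aicc`, `n`, `significant`.
#' @export
backward_eliminate <- function(terms, frame, alpha = 0.05) {
  stopifnot(inherits(frame, "event_frame"), frame$analyzable)
  if (length(terms) == 1 && terms == "1") terms <- character()
  if (length(terms) > 1 && any(grepl("\\+", terms)))
    cv_stop("pass terms as a character vector, not a formula string",
            "validation")
  if (length(terms) == 1 && grepl("\\+", terms))
    terms <- strsplit(terms, "\\+")[[1]]
  df <- frame$data
  repeat {
    fit <- lm_fit(df, frame$response, terms)
    if (!length(terms)) break
    pv <- fit$p_values
    if (all(pv <= alpha)) break
    terms <- setdiff(terms, names(pv)[which.max(pv)])
  }
  structure(list(terms = terms, coefficients = fit$coefficients,
                 p_values = fit$p_values, adj_r2 = fit$adj_r2,
                 model_p = fit$model_p,
                 aicc = aicc(fit$rss, nrow(df), length(terms) + 2),
                 n = nrow(df), significant = length(terms) > 0),
            class = "driver_model_fit")
}

#' Select the driver model for one bloom event
#'
#' The per-event pipeline: build the frame; screen the one-day
#' lagged wind term by cross-correlation (it stays in the candidate set only
#' if it passes); prune collinear candidates; enumerate all additive
#' subsets ranked by AICc; backward-eliminate the best subset to an
#' all-significant model.
#'
#' @param event One row of a `bloom_events` frame.
#' @param daily The [daily_series()].
#' @param met A [met_series()].
#' @param config A [pipeline_config()].
#' @return A `driver_model_fit` (with the frame attached as `frame`), or a
#'   not-analyzable marker when meteorology coverage is incomplete.
#' @export
fit_event_drivers <- function(event, daily, met,
                              config = pipeline_config()) {
  frame <- build_event_frame(event, daily, met)
  if (!frame$analyzable)
    return(structure(list(analyzable = FALSE, terms = character(),
                          significant = FALSE),
                     class = "driver_model_fit"))
  if ("wind_avg_lag1" %in% frame$candidates) {
    scr <- ccf_screen(frame$data$chlorophyll, frame$data$wind_avg,
                      bound_mult = config$ccf_bound)
    if (!scr$include_lag1) {
      frame$candidates <- setdiff(frame$candidates, "wind_avg_lag1")
      frame$dropped <- c(frame$dropped, "wind_avg_lag1")
    }
  }
  frame <- prune_collinear(frame, r_threshold = config$collinearity_r)
  ranked <- enumerate_models(frame)
  best <- if (ranked$terms[1] == "1") character() else
    strsplit(ranked$terms[1], "\\+")[[1]]
  fit <- backward_eliminate(best, frame, alpha = config$alpha)
  fit$analyzable <- TRUE
  fit$frame <- frame
  fit$ranked <- ranked
  fit
}

#' Tabulate driver-model fits across events
#'
#' One row per event and term (plus the intercept), with the per-event
#' adjusted r-squared, overall model p-value, AICc and n — the machine
#' equivalent of a per-event driver table.
#'
#' @param fits Named list of `driver_model_fit` objects (names = event ids).
#' @return A data frame.
#' @export
drivers_table <- function(fits) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    if (!isTRUE(f$analyzable))
      return(data.frame(event = id, term = NA_character_,
                        coefficient = NA_real_, p_value = NA_real_,
                        adj_r2 = NA_real_, model_p = NA_real_,
                        aicc = NA_real_, n = NA_integer_,
                        note = "not analyzable (met coverage)"))
    terms <- c("(Intercept)", f$terms)
    data.frame(event = id, term = terms,
               coefficient = unname(f$coefficients[terms]),
               p_value = c(NA_real_, unname(f$p_values[f$terms])),
               adj_r2 = f$adj_r2, model_p = f$model_p, aicc = f$aicc,
               n = f$n,
               note = if (f$significant) "" else "no significant model")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.driver_model_fit <- function(x, ...) {
  if (!isTRUE(x$analyzable)) {
    cat("<driver_model_fit> not analyzable (incomplete met coverage)\n")
    return(invisible(x))
  }
  if (!x$significant) {
    cat("<driver_model_fit> no significant driver model (intercept only)\n")
    return(invisible(x))
  }
  cat(sprintf("<driver_model_fit> n = %d, adj r2 = %.2f, model p = %.3g, AICc = %.1f\n",
              x$n, x$adj_r2, x$model_p, x$aicc))
  for (t in x$terms)
    cat(sprintf("  %-16s %8.3f  (p = %.3g)\n", t, x$coefficients[t],
                x$p_values[t]))
  invisible(x)
}

# ---- internal OLS helpers ---------------------------------------------------

# Minimal OLS wrapper used by enumeration: rss and adjusted r2 only.
ols_fit <- function(df, response, terms) {
  f <- stats::as.formula(paste(response, "~",
                               if (length(terms))
                                 paste(terms, collapse = "+") else "1"))
  m <- stats::lm(f, data = df)
  r <- stats::residuals(m)
  rss <- sum(r^2)
  n <- nrow(df)
  p <- length(terms)
  tss <- sum((df[[response]] - mean(df[[response]]))^2)
  adj <- if (n - p - 1 > 0) 1 - (rss / (n - p - 1)) / (tss / (n - 1)) else
    NA_real_
  list(rss = rss, adj_r2 = adj, model = m)
}

# Full fit: per-term p-values and overall F-test for elimination/reporting.
lm_fit <- function(df, response, terms) {
  base <- ols_fit(df, response, terms)
  sm <- summary(base$model)
  coefs <- stats::coef(base$model)
  pv <- if (length(terms)) sm$coefficients[terms, "Pr(>|t|)"] else numeric()
  if (length(terms)) names(pv) <- terms
  model_p <- if (length(terms)) {
    fs <- sm$fstatistic
    unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  } else NA_real_
  list(coefficients = coefs, p_values = pv, adj_r2 = base$adj_r2,
       model_p = model_p, rss = base$rss)
}
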