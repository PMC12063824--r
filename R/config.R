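#' Pipeline configuration
#'
#' Bundles the tunable constants of the whole pipeline: the bloom rise
#' threshold and window, the event merge and context windows, the significance
#' level for backward elimination, the number of monitoring-frequency
#' simulations, the QC gap tolerance, the collinearity threshold and the
#' white-noise bound multiplier used in cross-correlation screening.
#'
#' @param bloom_delta Minimum chlorophyll rise (ug/L) that defines a bloom
#'   trigger. Default 50.
#' @param bloom_window Span (days, inclusive of both endpoints) within which
#'   the rise must occur. Default 4, i.e. endpoints at most 3 days apart.
#' @param merge_window Events closer than this (days) are combined. Default 14.
#' @param event_context Days of context kept on either side of an event peak.
#'   Default 14.
#' @param alpha Significance level for backward elimination. Default 0.05.
#' @param n_sims Number of resampling simulations. Default 1000.
#' @param rng_seed Integer seed for all stochastic steps.
#' @param qc_max_gap Longest tolerated run of missing 15-minute points within a
#'   day, in minutes; a day with a strictly longer run is omitted. Default 60.
#' @param collinearity_r Absolute pairwise Pearson correlation at or above
#'   which one of two predictors is dropped. Default 0.7.
#' @param ccf_bound Multiplier of the white-noise standard error used as the
#'   cross-correlation inclusion bound. Default 1.96.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bloom_delta = 50, bloom_window = 4,
                            merge_window = 14, event_context = 14,
                            alpha = 0.05, n_sims = 1000, rng_seed = 1L,
                            qc_max_gap = 60, collinearity_r = 0.7,
                            ccf_bound = 1.96) {
  cfg <- list(bloom_delta = as.numeric(bloom_delta),
              bloom_window = as.numeric(bloom_window),
              merge_window = as.numeric(merge_window),
              event_context = as.numeric(event_context),
              alpha = as.numeric(alpha),
              n_sims = as.integer(n_sims),
              rng_seed = as.integer(rng_seed),
              qc_max_gap = as.numeric(qc_max_gap),
              collinearity_r = as.numeric(collinearity_r),
              ccf_bound = as.numeric(ccf_bound))
  if (cfg$bloom_window < 1 || cfg$merge_window < 1 || cfg$event_context < 1)
    cv_stop("all windows must be >= 1 day", "config")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    cv_stop("alpha must lie strictly between 0 and 1", "config")
  if (cfg$n_sims < 1)
    cv_stop("n_sims must be >= 1", "config")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (or JSON, a YAML subset) key-value file; keys map onto the
#' arguments of [pipeline_config()]. Unknown keys are an error so typos never
#' pass silently.
#'
#' @param path Path to the configuration file.
#' @param ... Overrides applied on top of the file (e.g. from CLI flags).
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) cv_stop(paste0("no such config file: ", path), "io")
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) cv_stop("config file must be a key-value mapping", "config")
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    cv_stop(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
            "config")
  do.call(pipeline_config, vals)
}

# Typed condition helper: every validation failure carries a
# chlorovar_<class>_error class so callers can branch on error kind.
cv_stop <- function(msg, class) {
  stop(structure(class = c(paste0("chlorovar_", class, "_error"),
                           "chlorovar_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
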