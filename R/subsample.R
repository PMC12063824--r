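#' Partition a daily record into contiguous blocks
#'
#' Splits `n_days` into `n_blocks` contiguous blocks in temporal order with
#' lengths differing by at most one day; the first `n_days %% n_blocks`
#' blocks carry the extra day. A 171-day record gives quarters of
#' 43/43/43/42 days (mean 42.75) and months of three 15s and nine 14s
#' (mean 14.25).
#'
#' @param n_days Number of days in the record.
#' @param n_blocks Number of blocks (4 = quarterly, 12 = monthly).
#' @return Integer vector of block lengths summing to `n_days`.
#' @export
partition_blocks <- function(n_days, n_blocks) {
  n_days <- as.integer(n_days); n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1 || n_blocks > n_days)
    cv_stop("need 1 <= n_blocks <= n_days", "validation")
  base <- n_days %/% n_blocks
  extra <- n_days %% n_blocks
  base + as.integer(seq_len(n_blocks) <= extra)
}

#' Simulate reduced-frequency sampling of a daily record
#'
#' Treats the supplied record as one "year", partitions it into contiguous
#' blocks, and runs `n_sims` simulations in which one day is drawn uniformly
#' at random from each block; each simulation's annual mean, minimum and
#' maximum are recorded and averaged across simulations next to the raw
#' record's statistics. Draws are independent across blocks and across
#' simulations; each simulation uses its own counter-derived random
#' substream, so results do not depend on execution order.
#'
#' @param values Daily chlorophyll values (ug/L), no missing entries: supply
#'   only the useable days.
#' @param n_blocks Number of blocks (4 = quarterly, 12 = monthly).
#' @param n_sims Number of simulations. Default 1000.
#' @param seed Integer seed.
#' @return A `subsampling_result` list: `frequency`, `n_sims`, `per_sim`
#'   (data frame of per-simulation mean/min/max), `avg_mean`, `avg_min`,
#'   `avg_max`, `raw_mean`, `raw_min`, `raw_max`.
#' @export
simulate_sampling <- function(values, n_blocks, n_sims = 1000, seed = 1L) {
  if (anyNA(values))
    cv_stop("values must be free of missing entries", "validation")
  if (n_sims < 1) cv_stop("n_sims must be >= 1", "validation")
  lens <- partition_blocks(length(values), n_blocks)
  if (any(lens < 1)) cv_stop("empty block", "validation")
  starts <- cumsum(c(1L, lens[-length(lens)]))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  per <- matrix(NA_real_, nrow = n_sims, ncol = 3,
                dimnames = list(NULL, c("mean", "min", "max")))
  for (i in seq_len(n_sims)) {
    set.seed(sub_seeds[i])
    idx <- starts + vapply(lens, sample.int, integer(1), size = 1) - 1L
    v <- values[idx]
    per[i, ] <- c(mean(v), min(v), max(v))
  }
  per <- as.data.frame(per)
  structure(list(frequency = frequency_label(n_blocks),
                 n_blocks = n_blocks, n_sims = n_sims, per_sim = per,
                 avg_mean = mean(per$mean), avg_min = mean(per$min),
                 avg_max = mean(per$max),
                 raw_mean = mean(values), raw_min = min(values),
                 raw_max = max(values)),
            class = "subsampling_result")
}

#' Wrap published summary statistics as a subsampling result
#'
#' Builds a `subsampling_result` from already-computed average and raw
#' statistics (for example a published summary table) so they can flow
#' through [frequency_report()] without the per-simulation detail.
#'
#' @param frequency Label, e.g. `"quarterly"`.
#' @param avg_mean,avg_min,avg_max Across-simulation averages (ug/L).
#' @param raw_mean,raw_min,raw_max Raw-record statistics (ug/L).
#' @return A `subsampling_result` with `per_sim = NULL`.
#' @export
subsampling_summary <- function(frequency, avg_mean, avg_min, avg_max,
                                raw_mean, raw_min, raw_max) {
  structure(list(frequency = frequency, n_blocks = NA_integer_,
                 n_sims = NA_integer_, per_sim = NULL,
                 avg_mean = avg_mean, avg_min = avg_min, avg_max = avg_max,
                 raw_mean = raw_mean, raw_min = raw_min, raw_max = raw_max),
            class = "subsampling_result")
}

#' Compare sampling frequencies against the raw record
#'
#' Tabulates, per frequency, the across-simulation average annual mean,
#' minimum and maximum next to the raw record's statistics, and derives what
#' reduced sampling loses: the maximum deficit (`raw_max - avg_max`), the
#' minimum excess (`avg_min - raw_min`) and the percent reduction of the
#' captured maximum (`100 (raw_max - avg_max)/raw_max`).
#'
#' @param results List of `subsampling_result` objects sharing one raw
#'   record.
#' @return Data frame, one row per frequency.
#' @export
frequency_report <- function(results) {
  if (inherits(results, "subsampling_result")) results <- list(results)
  raw <- vapply(results, function(r)
    c(r$raw_mean, r$raw_min, r$raw_max), numeric(3))
  if (length(results) > 1 &&
      any(apply(raw, 1, function(v) diff(range(v))) > 1e-8))
    cv_stop("all results must share the same raw record", "validation")
  rows <- lapply(results, function(r) {
    data.frame(frequency = r$frequency, n_sims = r$n_sims,
               avg_mean = r$avg_mean, avg_min = r$avg_min,
               avg_max = r$avg_max, raw_mean = r$raw_mean,
               raw_min = r$raw_min, raw_max = r$raw_max,
               max_deficit = r$raw_max - r$avg_max,
               min_excess = r$avg_min - r$raw_min,
               pct_reduction_max = 100 * (r$raw_max - r$avg_max) / r$raw_max)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.subsampling_result <- function(x, ...) {
  cat(sprintf("<subsampling_result> %s, %s sims\n", x$frequency,
              format(x$n_sims)))
  cat(sprintf("  avg mean %.1f, avg min %.1f, avg max %.1f (raw: %.1f / %.1f / %.1f)\n",
              x$avg_mean, x$avg_min, x$avg_max, x$raw_mean, x$raw_min,
              x$raw_max))
  invisible(x)
}

frequency_label <- function(n_blocks) {
  switch(as.character(n_blocks), "4" = "quarterly", "12" = "monthly",
         paste0("blocks", n_blocks))
}
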