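# Independent oracles: deliberately naive re-implementations used only to
# check the package's optimised/structured paths. They share no code with R/.

# Brute-force rise detector: examine literally every ordered pair of observed
# days and keep those within the span whose rise clears delta.
brute_rises <- function(daily, delta, window) {
  obs <- daily[!is.na(daily$chlorophyll), c("date", "chlorophyll")]
  hits <- list()
  for (i in seq_len(nrow(obs))) for (j in seq_len(nrow(obs))) {
    dd <- as.numeric(obs$date[j] - obs$date[i])
    if (dd >= 1 && dd <= window - 1 &&
        obs$chlorophyll[j] - obs$chlorophyll[i] >= delta)
      hits[[length(hits) + 1]] <- c(i, j)
  }
  if (!length(hits))
    return(data.frame(start_date = as.Date(character()),
                      end_date = as.Date(character()), rise = numeric()))
  m <- do.call(rbind, hits)
  out <- data.frame(start_date = obs$date[m[, 1]], end_date = obs$date[m[, 2]],
                    rise = obs$chlorophyll[m[, 2]] - obs$chlorophyll[m[, 1]])
  out[order(out$end_date, out$start_date), ]
}

# Normal-equations OLS: coefficients, rss, per-slope p-values (t), adj r2.
naive_ols <- function(df, response, terms) {
  y <- df[[response]]
  X <- matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  if (length(terms)) X <- cbind(X, as.matrix(df[terms]))
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  rss <- sum(res^2)
  n <- length(y); p <- ncol(X)
  sigma2 <- rss / (n - p)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- b[, 1] / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  adj <- 1 - (rss / (n - p)) / (tss / (n - 1))
  list(coefficients = b[, 1], rss = rss,
       p_values = pval[setdiff(names(pval), "(Intercept)")], adj_r2 = adj)
}

naive_aicc <- function(rss, n, k) {
  n * log(rss / n) + 2 * k + (2 * k^2 + 2 * k) / (n - k - 1)
}

# Enumerate every subset by an explicit loop over binary masks.
naive_enumerate <- function(df, response, candidates) {
  p <- length(candidates)
  out <- NULL
  for (mask in 0:(2^p - 1)) {
    terms <- candidates[as.logical(bitwAnd(mask, 2^(0:(p - 1))))]
    k <- length(terms) + 2
    if (nrow(df) - k - 1 <= 0) next
    fit <- naive_ols(df, response, terms)
    out <- rbind(out, data.frame(
      terms = if (length(terms)) paste(terms, collapse = "+") else "1",
      aicc = naive_aicc(fit$rss, nrow(df), k)))
  }
  out[order(out$aicc), ]
}

naive_backward <- function(df, response, terms, alpha) {
  repeat {
    fit <- naive_ols(df, response, terms)
    if (!length(terms) || all(fit$p_values <= alpha)) return(terms)
    terms <- setdiff(terms, names(which.max(fit$p_values)))
  }
}

# Wrap a plain data frame as an analyzable event frame for direct testing of
# the model-selection operations.
make_frame <- function(df, candidates, response = "chlorophyll") {
  structure(list(data = df, response = response, candidates = candidates,
                 dropped = character(), analyzable = TRUE, n = nrow(df)),
            class = "event_frame")
}

# Random daily chlorophyll fixture with gaps, for detector property tests.
random_daily <- function(n = 60, na_frac = 0.15, start = as.Date("2015-01-01")) {
  chl <- stats::rlnorm(n, log(30), 0.8)
  chl[stats::runif(n) < na_frac] <- NA
  daily_series(start + 0:(n - 1), chlorophyll = chl, site = "fix")
}
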