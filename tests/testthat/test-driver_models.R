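test_that("event frames compute lags, coverage and zero-variance drops", {
  dates <- as.Date("2015-06-01") + 0:9
  daily <- daily_series(dates, temperature = 25 + 0:9 / 10, salinity = 30,
                        chlorophyll = 40 + 0:9)
  met <- met_series(as.Date("2015-05-31") + 0:10,
                    wind_avg = 1:11, wind_max = 2 * (1:11), rain = 0)
  event <- list(window_start = dates[1], window_end = dates[10])
  expect_message(frame <- build_event_frame(event, daily, met), "rain")
  expect_true(frame$analyzable)
  expect_false("rain" %in% frame$candidates)   # zero variance over window
  # lag identity: wind_avg on day d appears as wind_avg_lag1 on day d+1
  expect_equal(frame$data$wind_avg_lag1[-1],
               frame$data$wind_avg[-nrow(frame$data)])
  # incomplete met coverage flags the event not analyzable
  met3 <- met
  met3$wind_avg[5] <- NA
  expect_false(build_event_frame(event, daily, met3)$analyzable)
  met4 <- met[-3, ]   # missing date entirely
  expect_false(build_event_frame(event, daily, met4)$analyzable)
})

test_that("cross-correlation screening keys on the lag-1 coefficient", {
  set.seed(101)
  wind <- stats::rnorm(21)
  # chl(t) = 2 wind(t-1), aligned over 20 days
  scr <- ccf_screen(chl = 2 * wind[1:20], predictor = wind[2:21])
  expect_equal(scr$r_lag1, 1)
  expect_true(scr$include_lag1)
  # contemporaneous dependence with white-noise wind: lag 1 below the bound
  wind <- stats::rnorm(40)
  scr <- ccf_screen(2 * wind, wind)
  expect_equal(scr$r_lag0, 1)
  expect_false(scr$include_lag1)
  expect_warning(scr <- ccf_screen(rep(3, 20), stats::rnorm(20)), "constant")
  expect_false(scr$include_lag1)
  expect_error(ccf_screen(1:4, 1:4), class = "chlorovar_validation_error")
})

test_that("the lag-1 screen holds its nominal level on white noise", {
  set.seed(202)
  hits <- 0L
  for (i in 1:1000) {
    chl <- stats::rnorm(20)
    wind <- stats::rnorm(20)
    if (ccf_screen(chl, wind)$include_lag1) hits <- hits + 1L
  }
  rate <- hits / 1000
  # nominal 5% within 3 binomial SEs
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.01)
})

test_that("AICc arithmetic is exact", {
  # correction term for n = 10, k = 3 adds 2*3*4/6 = 4 to AIC
  rss <- 5
  expect_equal(aicc(rss, 10, 3) - (10 * log(rss / 10) + 2 * 3), 4)
  # halving rss at fixed k lowers AICc by n log 2
  expect_equal(aicc(rss, 20, 3) - aicc(rss / 2, 20, 3), 20 * log(2))
  # the correction vanishes as n grows
  n <- 1e5
  expect_lt(aicc(rss, n, 3) - (n * log(rss / n) + 2 * 3), 1e-3)
  expect_true(is.na(aicc(rss, 5, 4)))
  expect_error(aicc(0, 10, 2), class = "chlorovar_validation_error")
})

test_that("subset enumeration finds exact structure and counts subsets", {
  set.seed(55)
  df <- data.frame(x1 = stats::rnorm(20), x2 = stats::rnorm(20))
  df$chlorophyll <- 3 * df$x1
  frame <- make_frame(df, c("x1", "x2"))
  ranked <- enumerate_models(frame)
  expect_equal(nrow(ranked), 4)            # 2^2 subsets
  expect_equal(ranked$terms[1], "x1")
  fit <- suppressWarnings(backward_eliminate("x1", frame))
  expect_equal(unname(fit$coefficients["x1"]), 3)
  expect_equal(fit$adj_r2, 1)
})

test_that("enumeration, AICc and elimination match naive re-implementations", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(15:30, 1)
    p <- sample(2:4, 1)
    df <- as.data.frame(matrix(stats::rnorm(n * p), n, p))
    names(df) <- paste0("x", seq_len(p))
    df$chlorophyll <- stats::rnorm(n) +
      as.matrix(df[1:p]) %*% stats::runif(p, -2, 2)
    frame <- make_frame(df, names(df)[1:p])
    ranked <- enumerate_models(frame)
    want <- naive_enumerate(df, "chlorophyll", names(df)[1:p])
    expect_equal(ranked$terms, want$terms)
    expect_equal(ranked$aicc, want$aicc, tolerance = 1e-10)
    best <- if (ranked$terms[1] == "1") character() else
      strsplit(ranked$terms[1], "\\+")[[1]]
    fit <- backward_eliminate(best, frame, alpha = 0.05)
    want_terms <- naive_backward(df, "chlorophyll", best, 0.05)
    expect_setequal(fit$terms, want_terms)
    if (length(fit$terms))
      expect_true(all(fit$p_values <= 0.05))
  }
})

test_that("collinearity pruning keeps the response-stronger member", {
  set.seed(88)
  n <- 40
  wind_max <- stats::rnorm(n)
  wind_avg <- wind_max + stats::rnorm(n, 0, 0.2)   # r ~ 0.98
  chl <- 5 * wind_max + stats::rnorm(n, 0, 0.5)     # response tracks wind_max
  df <- data.frame(wind_avg = wind_avg, wind_max = wind_max,
                   temperature = stats::rnorm(n), chlorophyll = chl)
  frame <- make_frame(df, c("wind_avg", "wind_max", "temperature"))
  pruned <- prune_collinear(frame, 0.7)
  expect_true("wind_max" %in% pruned$candidates)
  expect_false("wind_avg" %in% pruned$candidates)
  # oracle: direct correlation comparison says the same
  expect_gt(abs(cor(chl, wind_max)), abs(cor(chl, wind_avg)))
  # orthogonal predictors survive untouched
  df2 <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n),
                    chlorophyll = stats::rnorm(n))
  expect_equal(prune_collinear(make_frame(df2, c("a", "b")), 0.7)$candidates,
               c("a", "b"))
})

test_that("of three mutually collinear predictors exactly one survives", {
  set.seed(99)
  n <- 50
  base <- stats::rnorm(n)
  df <- data.frame(a = base + stats::rnorm(n, 0, 0.1),
                   b = base + stats::rnorm(n, 0, 0.1),
                   c = base + stats::rnorm(n, 0, 0.1))
  df$chlorophyll <- 2 * base + stats::rnorm(n, 0, 0.3)
  pruned <- prune_collinear(make_frame(df, c("a", "b", "c")), 0.7)
  expect_length(pruned$candidates, 1)
  # determinism: same input, same survivor
  again <- prune_collinear(make_frame(df, c("a", "b", "c")), 0.7)
  expect_equal(again$candidates, pruned$candidates)
})

test_that("backward elimination removes null terms and flags pure noise", {
  set.seed(111)
  n <- 30
  df <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  df$chlorophyll <- 4 * df$x1 + stats::rnorm(n, 0, 0.5)  # x2 is null
  frame <- make_frame(df, c("x1", "x2"))
  fit <- backward_eliminate(c("x1", "x2"), frame)
  expect_equal(fit$terms, "x1")
  expect_true(fit$significant)
  # already-significant model is a fixed point
  fit2 <- backward_eliminate("x1", frame)
  expect_equal(fit2$terms, "x1")
  expect_equal(fit2$coefficients, fit$coefficients)
  # pure noise: intercept-only, flagged
  df$chlorophyll <- stats::rnorm(n)
  fit3 <- backward_eliminate(c("x1", "x2"), make_frame(df, c("x1", "x2")))
  if (length(fit3$terms) == 0) expect_false(fit3$significant)
})

test_that("drivers_table mirrors per-event fits", {
  sim <- simulate_bloom_event(seed = 5, lag = 0)
  fit <- fit_event_drivers(sim$event, sim$daily, sim$met)
  tab <- drivers_table(list(`ev-1` = fit))
  expect_true(all(c("event", "term", "coefficient", "p_value", "adj_r2",
                    "model_p", "aicc", "n") %in% names(tab)))
  expect_equal(tab$term[1], "(Intercept)")
  expect_equal(unique(tab$n), fit$n)
})
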