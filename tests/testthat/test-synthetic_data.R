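test_that("wind reduces to its seasonal mean when noise is switched off", {
  truth <- synthetic_truth(wind = list(phi = 0, innovation_sd = 0,
                                       max_noise_sd = 0))
  met <- generate_met(truth, n_days = 365, seed = 1)
  doy <- as.integer(format(met$date, "%j"))
  mu <- 6 + 1.5 * sin(2 * pi * (doy - 100) / 365)
  expect_equal(met$wind_avg, mu)
  expect_equal(met$wind_max, mu * 1.7)
})

test_that("dry configuration produces an identically zero rain record", {
  truth <- synthetic_truth(rain = list(wet_p = 0))
  met <- generate_met(truth, n_days = 200, seed = 2)
  expect_true(all(met$rain == 0))
})

test_that("generated wind has the configured lag-1 autocorrelation", {
  truth <- synthetic_truth()
  met <- generate_met(truth, n_days = 4000, seed = 3)
  # remove the seasonal mean before measuring the AR structure
  doy <- as.integer(format(met$date, "%j"))
  mu <- 6 + 1.5 * sin(2 * pi * (doy - 100) / 365)
  x <- met$wind_avg - mu
  r1 <- stats::cor(x[-1], x[-length(x)])
  se <- sqrt((1 - 0.6^2) / 4000)   # asymptotic SE of an AR(1) lag-1 estimate
  expect_lt(abs(r1 - 0.6), 3 * se + 0.02)  # small flooring bias allowance
})

test_that("met invariants always hold", {
  for (seed in 1:5) {
    met <- generate_met(synthetic_truth(), n_days = 400, seed = seed)
    expect_true(all(met$wind_max >= met$wind_avg))
    expect_true(all(met$wind_avg >= 0))
    expect_true(all(met$rain >= 0))
  }
})

test_that("a noiseless bloom-free record is the deterministic seasonal product", {
  truth <- synthetic_truth(noise_sigma = 0, bloom = list(amplitude = 0))
  met <- generate_met(truth, start = as.Date("2014-01-01"),
                      n_days = 5 * 365, seed = 4)
  daily <- generate_daily_chl(truth, met, seed = 5)
  monthly <- generate_monthly_program(daily, day_of_month = 15)
  fit <- fit_decomposition(build_monthly_matrix(monthly))
  expect_equal(fit$grand_mean, 45, tolerance = 1e-10)
  expect_equal(unname(fit$annual), unname(truth$annual_factors),
               tolerance = 1e-10)
  expect_equal(unname(fit$monthly), unname(truth$monthly_factors),
               tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals - 1)), 0, tolerance = 1e-10)
})

test_that("generators are seed-deterministic and chlorophyll stays positive", {
  truth <- synthetic_truth()
  met <- generate_met(truth, n_days = 365, seed = 6)
  a <- generate_daily_chl(truth, met, seed = 7)
  b <- generate_daily_chl(truth, met, seed = 7)
  expect_identical(a$chlorophyll, b$chlorophyll)
  expect_identical(attr(a, "truth_ledger"), attr(b, "truth_ledger"))
  c <- generate_daily_chl(truth, met, seed = 8)
  expect_false(identical(a$chlorophyll, c$chlorophyll))
  expect_true(all(a$chlorophyll > 0))
})

test_that("default daily chlorophyll is right-skewed", {
  sc <- generate_scenario("default", years = 2, seed = 7)
  expect_gt(mean(sc$daily$chlorophyll), stats::median(sc$daily$chlorophyll))
})

test_that("the ledger matches wind exceedances and lag configuration", {
  truth <- synthetic_truth(noise_sigma = 0, bloom = list(lag = 1))
  met <- generate_met(truth, n_days = 365, seed = 9)
  daily <- generate_daily_chl(truth, met, seed = 10)
  led <- attr(daily, "truth_ledger")
  expect_gt(nrow(led), 0)
  expect_true(all(led$lag == 1))
  expect_true(all(led$driver == "wind"))
  # the trigger day's wind (lagged) exceeds its monthly 90th percentile
  mo <- as.integer(format(met$date, "%m"))
  thr <- stats::ave(met$wind_avg, mo,
                    FUN = function(v) stats::quantile(v, 0.9))
  tidx <- match(led$trigger_date - 1, met$date)
  expect_true(all(met$wind_avg[tidx] > thr[tidx]))
})

test_that("15-minute expansion round-trips and respects planted gaps", {
  dates <- as.Date("2015-03-01") + 0:4
  d <- daily_series(dates, temperature = 20, salinity = 30,
                    chlorophyll = c(10, 20, 30, 25, 15), site = "s")
  # zero diel, zero noise: exact round trip through the QC chain
  s <- generate_15min(d, diel_amplitude = 0, noise_sd = 0)
  expect_equal(nrow(s), 5 * 96)
  back <- daily_average(s, "chlorophyll")
  expect_equal(back$value, d$chlorophyll)
  # the diel factor has zero daily mean, so averages are preserved anyway
  s2 <- generate_15min(d, diel_amplitude = 0.2, noise_sd = 0)
  back2 <- daily_average(s2, "chlorophyll")
  expect_equal(back2$value, d$chlorophyll, tolerance = 1e-10)
  # a 75-min gap knocks its day out; a 60-min gap does not
  s75 <- generate_15min(d, diel_amplitude = 0, gap_spec = list(
    list(start = "2015-03-02 06:00", duration_min = 75)))
  expect_equal(daily_average(s75, "chlorophyll")$provenance[2], "omitted")
  s60 <- generate_15min(d, diel_amplitude = 0, gap_spec = list(
    list(start = "2015-03-02 06:00", duration_min = 60)))
  q <- daily_average(s60, "chlorophyll")
  expect_equal(q$provenance[2], "gap_filled")
  expect_equal(q$value[2], 20, tolerance = 1e-10)
  expect_error(generate_15min(d, gap_spec = list(
    list(start = "2015-03-02 06:00", duration_min = 75),
    list(start = "2015-03-02 06:30", duration_min = 30))),
    class = "chlorovar_validation_error")
})

test_that("monthly programs count samples and honour skip lists", {
  truth <- synthetic_truth()
  met <- generate_met(truth, start = as.Date("2014-01-01"),
                      n_days = 5 * 365, seed = 11)
  daily <- generate_daily_chl(truth, met, seed = 12)
  m <- generate_monthly_program(daily)
  expect_equal(nrow(m), 60)
  m2 <- generate_monthly_program(daily, skip = "2017-01")
  expect_equal(nrow(m2), 59)
  expect_true(is.na(build_monthly_matrix(m2)["2017", 1]))
  r1 <- generate_monthly_program(daily, day_of_month = "random", seed = 3)
  r2 <- generate_monthly_program(daily, day_of_month = "random", seed = 3)
  expect_identical(r1$date, r2$date)
})
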