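mk15 <- function(chl, start = "2015-03-01 00:00") {
  ts <- as.POSIXct(start, tz = "UTC") + 900 * (seq_along(chl) - 1)
  sonde_series(ts, chlorophyll = chl, cadence = "15-min")
}

test_that("linear gap filling matches the explicit two-point line", {
  s <- mk15(c(10, NA, 20))
  expect_equal(fill_gaps_linear(s, "chlorophyll")$chlorophyll, c(10, 15, 20))
  # oracle: evaluate the line between (t0, 10) and (t4, 22) at the grid times
  s <- mk15(c(10, NA, NA, NA, 22))
  line <- 10 + (22 - 10) * (0:4) / 4
  expect_equal(fill_gaps_linear(s, "chlorophyll")$chlorophyll, line)
  # no gaps: identity
  s <- mk15(c(1, 2, 3))
  expect_equal(fill_gaps_linear(s, "chlorophyll")$chlorophyll, c(1, 2, 3))
  # leading/trailing gaps are never extrapolated
  s <- mk15(c(NA, 5, NA, 7, NA))
  expect_equal(fill_gaps_linear(s, "chlorophyll")$chlorophyll,
               c(NA, 5, 6, 7, NA))
  expect_error(fill_gaps_linear(mk15(1:3), "oxygen"),
               class = "chlorovar_validation_error")
})

test_that("gap filling is idempotent", {
  set.seed(42)
  chl <- stats::rlnorm(96 * 3, log(20), 0.3)
  chl[sample(30:200, 40)] <- NA
  once <- fill_gaps_linear(mk15(chl), "chlorophyll")
  twice <- fill_gaps_linear(once, "chlorophyll")
  expect_equal(twice$chlorophyll, once$chlorophyll)
})

test_that("daily averaging applies the more-than-one-hour omission rule", {
  # full constant day
  d <- daily_average(mk15(rep(5, 96)), "chlorophyll")
  expect_equal(d$value, 5)
  expect_equal(d$provenance, "observed_complete")
  # exactly 60 min missing (4 points) is not MORE than one hour: retained
  chl <- rep(5, 96); chl[40:43] <- NA
  d <- daily_average(mk15(chl), "chlorophyll")
  expect_equal(d$provenance, "gap_filled")
  expect_equal(d$value, 5)
  # 75 min missing (5 points): omitted
  chl <- rep(5, 96); chl[40:44] <- NA
  d <- daily_average(mk15(chl), "chlorophyll")
  expect_equal(d$provenance, "omitted")
  expect_true(is.na(d$value))
  # linear ramp: mean of the arithmetic sequence 0..95
  d <- daily_average(mk15(0:95), "chlorophyll")
  expect_equal(d$value, mean(0:95))
  expect_equal(d$value, 47.5)
})

test_that("gaps are assessed on the raw record, per day", {
  # a 2-hour run centred on midnight: 60 min in each day, both retained
  chl <- rep(8, 96 * 2)
  chl[93:100] <- NA
  d <- daily_average(mk15(chl), "chlorophyll")
  expect_equal(d$provenance, c("gap_filled", "gap_filled"))
  # shifted so 75 min fall in day 1: only day 1 omitted
  chl <- rep(8, 96 * 2)
  chl[92:100] <- NA
  d <- daily_average(mk15(chl), "chlorophyll")
  expect_equal(d$provenance, c("omitted", "gap_filled"))
})

test_that("enlarging a missing run never rescues an omitted day", {
  set.seed(7)
  for (rep in 1:20) {
    chl <- stats::rlnorm(96, log(20), 0.4)
    k0 <- sample(4:10, 1)
    at <- sample(1:(96 - 12), 1)
    chl[at:(at + k0 - 1)] <- NA
    before <- daily_average(mk15(chl), "chlorophyll")$provenance
    chl[at:(at + k0)] <- NA       # one point longer
    after <- daily_average(mk15(chl), "chlorophyll")$provenance
    if (before == "omitted") expect_equal(after, "omitted")
  }
})

test_that("gap-free days equal the plain mean of their 96 points", {
  set.seed(11)
  chl <- stats::rlnorm(96 * 4, log(30), 0.5)
  d <- daily_average(mk15(chl), "chlorophyll")
  expect_equal(d$value, colMeans(matrix(chl, nrow = 96)))
  expect_equal(d$provenance, rep("observed_complete", 4))
})

test_that("partial deployment-edge days are omitted", {
  # record starts at 06:00: first day spans only 18 h of grid
  ts <- as.POSIXct("2015-03-01 06:00", tz = "UTC") + 900 * 0:(96 * 2 - 1)
  s <- sonde_series(ts, chlorophyll = 5, cadence = "15-min")
  d <- daily_average(s, "chlorophyll")
  expect_equal(d$provenance[1], "omitted")
  expect_equal(d$provenance[2], "observed_complete")
})

test_that("sonde_to_daily assesses each variable independently", {
  ts <- as.POSIXct("2015-03-01 00:00", tz = "UTC") + 900 * 0:95
  temp <- rep(20, 96)
  chl <- rep(5, 96); chl[10:14] <- NA    # 75 min missing: chl omitted
  s <- sonde_series(ts, temperature = temp, salinity = 30, chlorophyll = chl,
                    cadence = "15-min")
  d <- sonde_to_daily(s)
  expect_true(is.na(d$chlorophyll))
  expect_equal(d$temperature, 20)
  prov <- attr(d, "provenance")
  expect_equal(prov$chlorophyll, "omitted")
  expect_equal(prov$temperature, "observed_complete")
})
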