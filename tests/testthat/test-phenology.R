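const_series <- function(tmean, n, start = "2011-04-01") {
  daily_series(seq(as.Date(start), by = "day", length.out = n),
               rep(tmean, n))
}

test_that("monthly accumulation weights exceedance by days in the month", {
  s <- monthly_series(2011, 6, 20.84)
  expect_equal(monthly_degree_days(s, 10.84), 300)
  cold <- monthly_series(2011, 1:4, c(-2, 1, 5, 9))
  expect_equal(monthly_degree_days(cold, 10.84), 0)
  # leap February carries 29 days
  feb <- monthly_series(2012, 2, 11.84)
  expect_equal(monthly_degree_days(feb, 10.84), 29)
  expect_error(monthly_degree_days(const_series(20, 5), 10.84),
               "resolution mismatch")
})

test_that("daily trajectories accumulate positive exceedance only", {
  flat <- const_series(10.84, 10)
  expect_equal(daily_degree_days(flat, 10.84)$cumulative_dd, rep(0, 10))

  warm <- const_series(20.84, 58)
  traj <- daily_degree_days(warm, 10.84)
  expect_equal(traj$cumulative_dd[58], 580)
  expect_equal(which(traj$cumulative_dd >= 574.08)[1], 58L)

  mixed <- daily_series(as.Date("2011-05-01") + 0:4, c(9, 10, 12, 15, 8))
  expect_equal(sum(daily_degree_days(mixed, 10.84)$daily_dd), 5.32,
               tolerance = 1e-9)
  expect_error(daily_degree_days(monthly_series(2011, 6, 20), 10.84),
               "resolution mismatch")
})

test_that("daily series must be gap-free and ordered", {
  d <- as.Date("2011-05-01") + c(0, 1, 3)
  expect_error(daily_series(d, c(10, 11, 12)), "missing days.*2011-05-02")
  expect_error(daily_series(rev(d), c(10, 11, 12)), "strictly increasing")
})

test_that("voltinism is the annual heat budget over the generation constant", {
  expect_equal(generations_per_year(2183.34, 574.08), 3.80)
  expect_equal(generations_per_year(0, 574.08), 0)
  expect_equal(generations_per_year(1148.16, 574.08), 2.00)
  expect_equal(generations_per_year(3650, 574.08), 6.36)
  expect_equal(generations_per_year(2183.34, 574.08, complete = TRUE), 3)
  expect_error(generations_per_year(1000, 0), "invalid thermal constant")
})

test_that("constant-temperature transitions land on the ceiling day", {
  temps <- athetis_truth()
  s <- const_series(20.84, 80)
  single <- data.frame(stage = c("pupa", "preoviposition", "egg", "larva",
                                 "prepupa"),
                       C = 10.84, K = c(100, 1e6, 1e6, 1e6, 1e6))
  fc <- forecast_emergence(s, single, "2011-04-01", n_generations = 1)
  expect_equal(fc$events$date[1], as.Date("2011-04-11"))  # 10 days after biofix
  expect_false(fc$complete)

  # the full calibrated cycle: successive emergences a whole generation apart
  long <- const_series(20.84, 400)
  fc2 <- forecast_emergence(long, temps, "2011-04-01", n_generations = 3)
  expect_true(fc2$complete)
  em <- fc2$events$date[fc2$events$stage == "pupa"]
  gaps <- as.numeric(diff(em))
  expect_true(all(gaps >= 58 & gaps <= 62))  # ~574.08 DD at 10 DD/day
  # event dates never run backwards
  expect_true(all(diff(fc2$events$date) > 0))
})

test_that("forecast transition days equal chained ceilings on constant series", {
  set.seed(21)
  for (i in 1:100) {
    C <- runif(5, 5, 15)
    K <- runif(5, 20, 400)
    Tt <- max(C) + runif(1, 2, 12)
    const <- data.frame(stage = c("pupa", "preoviposition", "egg", "larva",
                                  "prepupa"), C = C, K = K)
    horizon <- sum(ceiling(K / (Tt - C))) + 5
    s <- const_series(Tt, horizon)
    fc <- forecast_emergence(s, const, "2011-04-01", n_generations = 1)
    expect_true(fc$complete)
    got <- as.numeric(fc$events$date - as.Date("2011-04-01"))
    expect_equal(got, chained_ceiling_days(const, Tt))
  }
})

test_that("no accumulation means no events and an incomplete flag", {
  s <- const_series(10.84, 30)
  const <- data.frame(stage = c("pupa", "preoviposition", "egg", "larva",
                                "prepupa"), C = 10.84, K = 50)
  fc <- forecast_emergence(s, const, "2011-04-01")
  expect_equal(nrow(fc$events), 0L)
  expect_false(fc$complete)
  expect_error(forecast_emergence(s, const, "2010-01-01"), "biofix")
})

test_that("degree-days are additive over splits and monotone in the threshold", {
  set.seed(31)
  n <- 120
  s <- daily_series(as.Date("2011-04-01") + 0:(n - 1),
                    15 + 8 * sin(seq(0, 3, length.out = n)) + rnorm(n, 0, 2))
  thr <- 10.84
  total <- sum(daily_degree_days(s, thr)$daily_dd)
  cut <- 47
  s1 <- daily_series(s$entries$date[1:cut], s$entries$tmean[1:cut])
  s2 <- daily_series(s$entries$date[(cut + 1):n], s$entries$tmean[(cut + 1):n])
  expect_equal(sum(daily_degree_days(s1, thr)$daily_dd) +
                 sum(daily_degree_days(s2, thr)$daily_dd), total,
               tolerance = 1e-12)
  # cumulative trajectory never decreases
  expect_true(all(diff(daily_degree_days(s, thr)$cumulative_dd) >= 0))
  # raising the threshold can only lose heat
  for (d in c(0.5, 1, 3, 7)) {
    expect_lte(sum(daily_degree_days(s, thr + d)$daily_dd), total)
  }
  # matches the explicit day loop
  expect_equal(total, day_loop_dd(s$entries$tmean, thr), tolerance = 1e-12)
})

test_that("monthly and daily accumulation agree when days equal the monthly mean", {
  year <- 2012  # leap year
  months <- 1:12
  tm <- c(-3, 0, 6, 13, 19, 24, 27, 26, 21, 14, 6, -1)
  ms <- monthly_series(year, months, tm)
  dates <- seq(as.Date("2012-01-01"), as.Date("2012-12-31"), by = "day")
  daily <- daily_series(dates, tm[as.integer(format(dates, "%m"))])
  expect_equal(monthly_degree_days(ms, 10.84),
               sum(daily_degree_days(daily, 10.84)$daily_dd),
               tolerance = 1e-9)
})
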