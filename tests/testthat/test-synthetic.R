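test_that("the deterministic limit reproduces the law on the observation grid", {
  truth <- athetis_truth()
  sc <- rearing_scenario(stage_truth = truth, n_per_treatment = 2,
                         duration_noise_cv = 0, observation_interval = 1/3)
  rec <- simulate_rearing(sc, seed = 5)
  done <- rec[rec$outcome == "completed", ]
  for (i in seq_len(nrow(done))) {
    row <- truth[truth$stage == done$stage[i], ]
    exact <- row$K / (done$temperature[i] - row$C)
    expect_equal(done$duration[i], ceiling(exact * 3) / 3, tolerance = 1e-12)
    expect_gte(done$duration[i], exact)  # checks happen after the true moult
  }
})

test_that("simulation is reproducible from its seed and varies across seeds", {
  sc <- athetis_scenario(seed = 42)
  expect_identical(simulate_rearing(sc), simulate_rearing(sc))
  other <- simulate_rearing(sc, seed = 43)
  expect_false(identical(simulate_rearing(sc), other))
})

test_that("arrest frequencies match their configured probabilities", {
  truth <- athetis_truth()[1:5, ]  # chained stages only
  sc <- rearing_scenario(stage_truth = truth, n_per_treatment = 90,
                         duration_noise_cv = 0.05,
                         arrest_probs = c("18" = 0.95, "21" = 0.70))
  rec <- simulate_rearing(sc, seed = 13)
  for (tp in c(18, 21)) {
    p <- c("18" = 0.95, "21" = 0.70)[[as.character(tp)]]
    pre <- rec[rec$temperature == tp & rec$stage == "prepupa", ]
    n <- nrow(pre)  # all 90 survive to the prepupal decision here
    k <- sum(pre$outcome == "arrested")
    bounds <- qbinom(c(0.005, 0.995), n, p)
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
})

test_that("empirical stage survival converges to the configured probability", {
  truth <- data.frame(stage = "egg", C = 11.03, K = 63.51)
  sc <- rearing_scenario(temperatures = 24, n_per_treatment = 4000,
                         stage_truth = truth, duration_noise_cv = 0,
                         survival_probs = data.frame(stage = "egg",
                                                     temperature = 24,
                                                     p = 0.7),
                         observation_interval = 0)
  rec <- simulate_rearing(sc, seed = 17)
  k <- sum(rec$outcome == "completed")
  bounds <- qbinom(c(0.005, 0.995), 4000, 0.7)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("treatments below a stage threshold are skipped with a warning", {
  truth <- data.frame(stage = "prepupa", C = 15.08, K = 30.04)
  sc <- rearing_scenario(temperatures = c(14, 24), stage_truth = truth,
                         n_per_treatment = 5, duration_noise_cv = 0,
                         observation_interval = 0)
  expect_warning(rec <- simulate_rearing(sc, seed = 2),
                 "scenario infeasible")
  expect_equal(unique(rec$temperature), 24)
})

test_that("the calibrated scenario carries the species constants", {
  sc <- athetis_scenario()
  gen <- sc$stage_truth[sc$stage_truth$stage == "generation", ]
  expect_equal(gen$C, 10.84)
  expect_equal(gen$K, 574.08)
  i1 <- sc$survival_probs[sc$survival_probs$stage == "instar1", ]
  expect_gte(i1$p[i1$temperature == 24], 0.95)
  expect_gte(i1$p[i1$temperature == 27], 0.95)
  expect_equal(unname(sc$fecundity_mean[["27"]]), 345.15)
  expect_equal(sc$female_fraction, 0.5)
  expect_equal(unname(sc$arrest_probs[["18"]]), 0.95)
  expect_equal(unname(sc$arrest_probs[["21"]]), 0.70)
})

test_that("scenario validation rejects impossible parameters", {
  truth <- data.frame(stage = "egg", C = 11, K = 60)
  expect_error(rearing_scenario(stage_truth = data.frame(stage = "egg",
                                                         C = 11, K = -5)),
               "positive")
  expect_error(rearing_scenario(temperatures = c(20, 20),
                                stage_truth = truth))
  expect_error(rearing_scenario(stage_truth = truth,
                                arrest_probs = c("18" = 1.2)),
               "probabilities")
})

test_that("synthetic weather follows the seasonal sinusoid", {
  flat <- simulate_weather(2011, mean_annual = 15, amplitude = 0,
                           daily_noise_sd = 0)
  expect_equal(unique(flat$entries$tmean), 15)
  expect_equal(nrow(flat$entries), 365L)
  expect_equal(nrow(simulate_weather(2012, daily_noise_sd = 0)$entries), 366L)

  # noise-free accumulation equals an explicit day loop over the sinusoid
  w <- simulate_weather(2011, daily_noise_sd = 0)
  expect_equal(sum(daily_degree_days(w, 10.84)$daily_dd),
               day_loop_dd(w$entries$tmean, 10.84), tolerance = 1e-9)
  # coldest in January, warmest in July
  mm <- monthly_means(w)
  expect_equal(which.min(mm$entries$tmean), 1L)
  expect_equal(which.max(mm$entries$tmean), 7L)

  expect_identical(simulate_weather(2011, seed = 3)$entries,
                   simulate_weather(2011, seed = 3)$entries)
})

test_that("the default weather regime supports just under four generations", {
  w <- simulate_weather(2011, seed = 8)
  total <- sum(daily_degree_days(w, 10.84)$daily_dd)
  expect_gt(total, 1900)
  expect_lt(total, 2500)
  g <- generations_per_year(total, 574.08)
  expect_gt(g, 3.2)
  expect_lt(g, 4.4)
})
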