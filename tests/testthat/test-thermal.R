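make_records <- function(stage, temps, durations, outcome = "completed") {
  data.frame(individual_id = seq_along(temps), stage = stage,
             temperature = temps, duration = durations, outcome = outcome)
}

test_that("treatment summaries average completed individuals and invert to rates", {
  rec <- make_records("egg", rep(20, 3), rep(10, 3))
  s <- summarize_treatments(rec, "egg")
  expect_equal(s$mean_duration, 10)
  expect_equal(s$rate, 0.1)
  expect_equal(s$n_completed, 3L)

  rec2 <- make_records("egg", c(24, 24), c(3, 5))
  s2 <- summarize_treatments(rec2, "egg")
  expect_equal(s2$mean_duration, 4)
  expect_equal(s2$rate, 0.25)
})

test_that("arrested and dead individuals are excluded from duration means", {
  rec <- rbind(make_records("prepupa", c(18, 18), c(5, 7)),
               make_records("prepupa", 18, 40, outcome = "arrested"),
               make_records("prepupa", 18, NA, outcome = "died"))
  s <- summarize_treatments(rec, "prepupa")
  expect_equal(s$mean_duration, 6)
  expect_equal(s$n_completed, 2L)
})

test_that("summaries fail informatively on empty or malformed input", {
  rec <- make_records("egg", 20, 4, outcome = "died")
  expect_error(summarize_treatments(rec, "egg"), "no completed records.*egg")
  expect_error(summarize_treatments(rec, "not_a_stage"), "unknown stage")
  expect_error(summarize_treatments(rec[, -4], "egg"), "lack column")
})

test_that("two exact points determine threshold and thermal constant", {
  s <- data.frame(temperature = c(20, 30), rate = c(0.1, 0.2))
  fit <- fit_thermal_constants(s)
  expect_equal(fit$C, 10, tolerance = 1e-12)
  expect_equal(fit$K, 100, tolerance = 1e-12)
  expect_equal(fit$r, 1)
  expect_true(is.na(fit$Sc) && is.na(fit$Sk))
  expect_equal(fit$n, 2L)
})

test_that("collinear rate data are recovered exactly with r = 1", {
  C <- 10.84; K <- 574.08
  temps <- c(18, 21, 24, 27, 30)
  s <- data.frame(temperature = temps, rate = (temps - C) / K)
  fit <- fit_thermal_constants(s)
  expect_equal(fit$C, C, tolerance = 1e-6)
  expect_equal(fit$K, K, tolerance = 1e-6)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_lt(sum(stats::residuals(fit$fit)^2), 1e-12)
  expect_equal(fit$Sc, 0, tolerance = 1e-6)

  # the fit must not depend on row order
  shuffled <- s[c(3, 1, 5, 2, 4), ]
  fit2 <- fit_thermal_constants(shuffled)
  expect_equal(fit2$C, fit$C)
  expect_equal(fit2$K, fit$K)
})

test_that("degenerate or non-physical designs are rejected", {
  one_t <- data.frame(temperature = c(20, 20), rate = c(0.1, 0.11))
  expect_error(fit_thermal_constants(one_t), "degenerate")
  cooling <- data.frame(temperature = c(20, 30), rate = c(0.2, 0.1))
  expect_error(fit_thermal_constants(cooling), "non-physical")
  bad_rate <- data.frame(temperature = c(20, 30), rate = c(-0.1, 0.2))
  expect_error(fit_thermal_constants(bad_rate), "positive")
})

test_that("predicted durations follow K / (T - C) and refuse sub-threshold input", {
  expect_equal(predict_duration(list(C = 10, K = 100), 110), 1)
  expect_equal(predict_duration(list(C = 10.84, K = 574.08), 26.84),
               35.88, tolerance = 1e-10)
  expect_equal(predict_duration(list(C = 11.03, K = 63.51), 27),
               3.98, tolerance = 1e-2)
  expect_error(predict_duration(list(C = 10, K = 100), 10), "threshold")
  expect_error(predict_duration(list(C = 10, K = 100), 9), "threshold")

  # strictly decreasing in temperature above the threshold
  d <- predict_duration(list(C = 11.6, K = 35), seq(12, 35, by = 0.5))
  expect_true(all(diff(d) < 0))
})

test_that("a noise-free rearing experiment round-trips through the model", {
  rec <- simulate_rearing(noise_free_scenario(), seed = 1)
  tm <- thermal_model(rec)
  truth <- athetis_truth()
  est <- coef(tm)
  expect_setequal(rownames(est), truth$stage)
  expect_equal(est[truth$stage, "C"], setNames(truth$C, truth$stage),
               tolerance = 1e-8)
  expect_equal(est[truth$stage, "K"], setNames(truth$K, truth$stage),
               tolerance = 1e-8)
  expect_true(all(abs(tm$constants$r - 1) < 1e-9))
  expect_true(all(abs(unlist(residuals(tm))) < 1e-9))

  # methods run
  expect_output(print(tm), "thermal constants|law of effective",
                ignore.case = TRUE)
  p <- predict(tm, c(24, 27))
  expect_equal(unname(p["24", "generation"]), 574.08 / (24 - 10.84),
               tolerance = 1e-8)
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  expect_invisible(plot(tm))
})

test_that("estimates from noisy cohorts concentrate near the truth", {
  set.seed(101)
  sc <- rearing_scenario(stage_truth = athetis_truth()[6, ],
                         duration_noise_cv = 0.05,
                         observation_interval = 0)
  errC <- replicate(20, {
    tm <- thermal_model(simulate_rearing(sc), stages = "generation")
    tm$constants$C - 10.84
  })
  expect_lt(median(abs(errC)), 1)
  expect_lt(abs(mean(errC)), 1)
})

test_that("simulate() on a fitted model regenerates analysable data", {
  rec <- simulate_rearing(noise_free_scenario(), seed = 3)
  tm <- thermal_model(rec, stages = c("egg", "generation"))
  sims <- simulate(tm, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  refit <- thermal_model(sims[[1]])
  expect_equal(sort(refit$constants$stage), c("egg", "generation"))
  expect_lt(abs(refit$constants$C[refit$constants$stage == "generation"] -
                  tm$constants$C[tm$constants$stage == "generation"]), 2)
})
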