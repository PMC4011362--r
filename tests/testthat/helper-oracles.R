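# Independent oracles used across the suite. These deliberately avoid the
# package's own closed-form code paths: grids, day loops and explicit
# cohort walks.

# true stage constants for the calibrated A. lepigone scenario
athetis_truth <- function() {
  data.frame(
    stage = c("egg", "larva", "prepupa", "pupa", "preoviposition",
              "generation"),
    C = c(11.03, 9.04, 15.08, 11.79, 11.63, 10.84),
    K = c(63.51, 339.42, 30.04, 118.41, 35.06, 574.08)
  )
}

# deterministic rearing scenario: no noise, no mortality, no arrest,
# continuous observation
noise_free_scenario <- function(truth = athetis_truth(),
                                temperatures = c(18, 21, 24, 27, 30),
                                n = 3) {
  rearing_scenario(temperatures = temperatures, n_per_treatment = n,
                   stage_truth = truth, duration_noise_cv = 0,
                   observation_interval = 0)
}

# dense grid argmax of a cubic on [lo, hi]
grid_optimum <- function(coefs, lo, hi, step = 1e-4) {
  tt <- seq(lo, hi, by = step)
  y <- coefs[1] * tt^3 + coefs[2] * tt^2 + coefs[3] * tt + coefs[4]
  tt[which.max(y)]
}

# brute-force cohort walk: start eggs, multiply through, return
# next-generation eggs per initial egg
cohort_walk_index <- function(survivals, female_fraction, eggs_per_female,
                              initial_eggs = 100) {
  n <- initial_eggs
  for (s in survivals) n <- n * s
  females <- n * female_fraction
  (females * eggs_per_female) / initial_eggs
}

# explicit day loop degree-day accumulation
day_loop_dd <- function(tmean, threshold) {
  total <- 0
  for (t in tmean) if (t > threshold) total <- total + (t - threshold)
  total
}

# chained stage-transition days on a constant-temperature series:
# each stage crosses ceiling(K / (T - C)) days after the previous one
chained_ceiling_days <- function(constants, temperature) {
  cyc <- c("pupa", "preoviposition", "egg", "larva", "prepupa")
  rows <- constants[match(cyc, constants$stage), ]
  cumsum(ceiling(rows$K / (temperature - rows$C)))
}
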