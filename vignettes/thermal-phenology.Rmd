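---
title: "Thermal development models, life tables and degree-day phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal development models, life tables and degree-day phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermaldev)
```

## The model

Insect development under moderate temperatures is well described by the
law of effective temperature: a stage needs a fixed heat sum of
`K` degree-days above its developmental threshold `C`, so its duration at
a constant temperature `T > C` is `D = K / (T - C)`. Writing the
developmental rate `V = 1/D`, the law is linear in the rate,

```
T = C + K * V,
```

and `thermal_model()` estimates `C` (intercept) and `K` (slope) by
ordinary least squares of `T` on `V`. Three choices deserve comment:

* **Regression orientation.** We regress temperature on rate, the
  classical formulation, so the intercept and slope *are* `C` and `K`.
  Regressing rate on temperature and back-transforming would bias the
  threshold whenever rates are noisy, because the error then sits in the
  response of a reciprocal transform.
* **Treatment-level fitting.** The regression runs on per-treatment
  *mean* rates (arithmetic mean of durations, then the reciprocal), so
  `n` is the number of temperature treatments. This matches how such
  experiments are designed and reported: replication lives inside a
  treatment, and the linear law is a statement about treatment means. The
  reciprocal-of-mean convention (rather than mean of reciprocals) keeps
  the reported mean durations and the fitted rates consistent.
* **Standard errors.** `Sc` and `Sk` are the standard OLS intercept and
  slope errors from that treatment-level fit, undefined for two
  treatments (zero residual degrees of freedom). With five treatments
  they carry only three residual degrees of freedom — intervals built
  from them are honest but heavy-tailed, which matters when interpreting
  coverage (below).

Stages that cannot complete at a treatment — developmental arrest of
mature larvae at 18 °C, pupal failure there — simply drop that
temperature from their fit; records with outcome `died` or `arrested`
never enter duration means.

`predict_duration()` inverts the fitted law and refuses temperatures at
or below the threshold.

## Survival and the optimum temperature

Across the rearing range, generation survival against temperature is
concave with a single interior peak, and is modelled as a cubic
`Y = aT^3 + bT^2 + cT + d` fitted by least squares within a stated range
(default 21–30 °C; four in-range temperatures exactly interpolate).
`optimal_temperature()` solves the derivative quadratic in closed form
and keeps the root with negative second derivative inside the range.
Curves used for optimum-finding must have an interior maximum: the
leading coefficient must be negative for a cubic of this shape, and a
curve rising monotonically through the whole range yields `NA` with a
warning rather than a boundary extrapolation. For the calibrated
*A. lepigone* curve (coefficients −0.0914, 2.57, 56.076, −1450.7) the
optimum is 26.47 °C.

## Life tables and the index of population trend

`build_life_table()` propagates a cohort (conventionally 100 eggs)
multiplicatively through egg → larva → prepupa → pupa → adult. The index
of population trend is

```
I = (prod of stage survival fractions) * female_fraction * eggs_per_female,
```

the expected next-generation eggs per current-generation egg; with the
100-egg start it is the per-egg replacement rate. Construction choices:

* "adult" survival means emergence-to-oviposition success; adult
  longevity does not enter `I`;
* mature larvae that arrest instead of pupating are mortality at the
  pre-pupal transition, with the arrested fraction carried as a separate
  reported column;
* the default sex ratio is 0.5 (no consistent departure is seen across
  rearing temperatures in this system).

`I` is exactly linear in fecundity and in each survival fraction, and the
closed-form product equals a brute-force cohort walk to floating-point
accuracy — both are enforced in the test suite.

## Degree-day accumulation and forecasting

Monthly series accumulate
`max(0, monthly mean − threshold) × days in month`; plain sums of monthly
means could not reach annual totals of the observed ≈2180 DD magnitude,
so the days-in-month weighting is structural, with Gregorian month
lengths and leap years respected. Daily series accumulate
`max(0, daily mean − threshold)` — negative days contribute zero heat
rather than a degree-day debt.

`generations_per_year()` is the annual total over the generation constant
(e.g. 2183.34/574.08 = 3.80), reported to two decimals with the fraction
retained; an integer "complete generations" floor is available via
`complete = TRUE`.

`forecast_emergence()` chains stages over a daily series. The cycle
starts at the **pupal** stage: spring adults emerge from overwintered
pupae, whose threshold is lower than the prepupal one, so a pupal biofix
reproduces early-season emergence that a prepupal start would miss. Each
generation then runs pupa → preoviposition → egg → larva → prepupa. A
stage's heat is accumulated from the day after the previous transition;
the first day whose running total reaches `K` is the transition date (no
within-day interpolation — daily means are the finest input used, so on a
constant series the transition day is exactly `ceiling(K / (T − C))`).
Completion of a pupal stage is that generation's adult emergence peak. A
series that ends mid-stage flags the forecast incomplete instead of
erroring.

## What the synthetic data emulate

`rearing_scenario()` / `simulate_rearing()` generate the canonical
constant-temperature rearing design: five chambers (18, 21, 24, 27,
30 °C), 90 individuals per treatment, stages checked three times a day.

* **Durations** are `K/(T − C)` times unit-mean multiplicative lognormal
  noise (durations are positive and right-skewed), default CV 5%, then
  rounded **up** to the 1/3-day observation grid: an insect found moulted
  at a check completed the stage at some earlier unobserved instant.
  `observation_interval = 0` disables the grid for calibration work —
  the ceiling adds ≈ +1/6 day on average per stage, a real bias of
  discrete checking that exact-recovery checks must switch off.
* **Mortality** is Bernoulli per stage with configurable probabilities;
  the chained stages share one cohort, so a death leaves no later-stage
  records. At 18 and 21 °C surviving mature larvae arrest in their
  cocoons with probabilities 0.95 and 0.70.
* **The whole generation** is simulated from its own `(C, K)` rather
  than as the sum of stage durations. The published per-stage and
  whole-generation constants for this species are independently
  estimated and internally inconsistent at the fraction-of-a-day level
  (summed stage durations at 24 °C give ≈43.49 d against 43.62 d from
  the generation law), and the generator mirrors that practice: each
  constant is its own linear law.
* **Instar number** (five or six stadia, temperature-dependent mix) is
  generated only as a label on larval records; it does not alter total
  larval duration.

`athetis_scenario()` fixes the truth to the *A. lepigone* constants
(thresholds 11.03/9.04/15.08/11.79/11.63/10.84 °C; thermal constants
63.51/339.42/30.04/118.41/35.06/574.08 DD) and the quoted survival,
arrest and fecundity figures (first-instar survival 20.56/50.48/62.49% at
18/21/30 °C and >95% at 24–27; fecundity 345.15 eggs per female at 27 °C,
×0.83 at 21–24, ×0.875 at 30, none at 18 where pupae and adults fail).
Survival entries no report pins down — egg hatch, whole-larval survival
at the optimum, prepupal, pupal and adult rows — were set once to values
typical of noctuid rearing, high near 24–27 °C and depressed at the
extremes; they were not revisited. Under these inputs the 27 °C life
table ranks first by trend index.

`simulate_weather()` draws a sinusoidal year (minimum mid-January,
maximum mid-July) plus Gaussian daily noise. The defaults — annual mean
13.15 °C, amplitude 15 °C — were solved once from the noise-free sinusoid
to hold ≈2183 DD above a 10.84 °C threshold, the regime in which this
species completes just under four generations.

**What the generator does not emulate:** within-day temperature cycles
(and the resulting rate averaging over a nonlinear response),
photoperiod-driven diapause induction, between-individual correlation of
stage durations, overdispersed mortality, or real station weather with
fronts and autocorrelation. Passing tests therefore certify the
estimators and the degree-day arithmetic under the stated generative
model, not forecast accuracy against field records.

## Numerical choices and calibration checks

* Internal computation is at full precision; reporting rounds half-up
  (survival percentages, trend indices, generation counts to two
  decimals) only at the presentation layer, because R's default
  round-half-even disagrees with the field's reporting convention.
* Collinear (noise-free) input recovers `(C, K)` to 1e−6 with `|r| = 1`
  and residual sums of squares below 1e−12.
* Estimator calibration: over 200 seeded replicates of the full design
  (5 temperatures × 90 individuals, CV 5%, continuous observation), the
  true `C` and `K` each fall inside ±3 standard errors in ≥95% of
  replicates. Note the theoretical two-sided ±3·SE coverage under a
  t-distribution with 3 degrees of freedom is ≈94.2%; the check sits
  near that boundary and is sensitive to the replicate seed, which is
  fixed in the suite.
* Problem sizes throughout the suite (200 fit replicates, 100-draw
  property loops, 400-day forecast horizons) keep the whole run around
  ten seconds while still exercising every invariant at meaningful
  resolution.

## Limitations

The linear law is used inside the tested 18–30 °C range only; no
high-temperature inhibition (Brière/Lactin-type curvature) is modelled,
and extrapolating thresholds far below the coldest treatment inherits the
usual x-intercept uncertainty. The cubic survival curve is descriptive,
valid only on its fit range. Forecasts treat air temperature as the
insect's environment, ignoring microhabitat buffering (residue-covered
soil runs warmer in spring), food quality, and generation overlap — peak
dates should be read as degree-day expectations, not census predictions.
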