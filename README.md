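# thermaldev

Degree-day models, experimental life tables and phenology forecasting for
insect development, built around the **law of effective temperature**.

For an ectotherm, the duration *D* (days) of a life stage at a constant
temperature *T* follows

> D · (T − C) = K    equivalently    T = C + K · V,  V = 1/D

where *C* is the **developmental threshold temperature** (°C, below which
the stage does not develop) and *K* the **effective accumulative
temperature** or thermal constant (degree-days the stage requires). With
rearing data at several constant temperatures, regressing *T* on the mean
developmental rate *V* gives *C* as the intercept and *K* as the slope,
with ordinary least-squares standard errors *Sc* and *Sk*.

From those constants the package supports the full applied-entomology
workflow used to forecast pest outbreaks:

- **`thermal_model()`** — per-stage estimation of (C, Sc, K, Sk, r, n)
  from individual rearing records, with `print`, `summary`, `coef`,
  `predict`, `plot`, `residuals` and `simulate` methods;
- **`fit_survival_cubic()` / `optimal_temperature()`** — cubic model of
  generation survival against temperature, with the optimum temperature
  found from the closed-form derivative root;
- **`build_life_table()` / `compare_trend_indices()`** — experimental
  population life tables and the index of population trend
  *I* = (Π stage survivals) × female fraction × eggs per female;
- **`monthly_degree_days()`, `daily_degree_days()`,
  `generations_per_year()`, `forecast_emergence()`** — degree-day
  accumulation over weather series, voltinism estimates and per-generation
  adult emergence-peak dates;
- **`simulate_rearing()` / `simulate_weather()`** — seeded synthetic
  rearing experiments and annual weather series; `athetis_scenario()` is
  a calibrated default emulating a five-temperature (18–30 °C) rearing
  study of the maize pest moth *Athetis lepigone*.

A command-line interface with `simulate`, `fit-thermal`, `fit-survival`,
`life-table` and `forecast` subcommands is installed at
`system.file("exec", "thermaldev.R", package = "thermaldev")`.

## Worked example

Simulate the calibrated rearing study, fit the thermal constants, and
forecast a season:

```r
library(thermaldev)

sc  <- athetis_scenario(seed = 101)
rec <- simulate_rearing(sc)
tm  <- thermal_model(rec)
tm
#>           stage     C   Sc      K   Sk      r n
#>             egg 10.62 0.11  68.19 0.54 0.9999 5
#>           larva  8.51 0.15 353.66 3.30 0.9999 5
#>         prepupa 14.71 0.38  33.54 1.14 0.9989 4
#>            pupa 11.60 0.22 122.84 1.90 0.9998 4
#>  preoviposition 10.73 0.16  39.57 0.42 0.9999 4
#>      generation 10.63 0.12 584.76 4.50 0.9999 4
```

Each row is one life stage: the estimated threshold `C` (°C), thermal
constant `K` (degree-days), their standard errors, the rate–temperature
correlation `r`, and the number of usable temperature treatments `n`
(pre-pupae and later stages lose the 18 °C treatment to developmental
arrest and pupal failure, so `n = 4` there). The small systematic offset
from the generating values (e.g. threshold 10.63 vs 10.84 for the whole
generation) is the thrice-daily observation grid at work: recorded
durations are rounded up to the next check.

```r
w  <- simulate_weather(2011, seed = 102)      # a North China Plain-like year
dd <- sum(daily_degree_days(w, coef(tm)["generation", "C"])$daily_dd)
generations_per_year(dd, coef(tm)["generation", "K"])
#> [1] 3.79

forecast_emergence(w, tm$constants, "2011-04-01", n_generations = 4)
#>  generation  stage       date  cumulative_dd  event
#>           1  pupa   2011-05-11        123.39  adult emergence peak
#>           2  pupa   2011-06-26        125.71  adult emergence peak
#>           3  pupa   2011-08-02        130.30  adult emergence peak
#>           4  pupa   2011-09-19        127.62  adult emergence peak
#>  ... (intermediate stage transitions omitted here)
```

The year holds ≈2216 degree-days above the generation threshold — just
under four generations — and the chained stage-by-stage accumulation
(starting from overwintered pupae at the April biofix) places adult
emergence peaks in mid-May, late June, early August and mid-September,
the multivoltine pattern typical of this pest on the North China Plain.

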