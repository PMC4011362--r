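#' Read and write rearing-record CSV files
#'
#' The rearing CSV dialect is UTF-8 with a header row and columns
#' `individual_id`, `stage`, `temperature_c`, `duration_days`, `outcome`.
#' Stage labels must come from [life_stages()] and outcomes from
#' `completed`/`died`/`arrested`; violations are reported with the
#' offending CSV line number (header = line 1).
#'
#' @param path File path.
#' @return `read_rearing_csv()`: a records data frame with columns
#'   `individual_id`, `stage`, `temperature`, `duration`, `outcome`.
#' @export
read_rearing_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("individual_id", "stage", "temperature_c", "duration_days",
              "outcome")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("rearing CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("empty input: rearing CSV '", path, "' has no data rows",
         call. = FALSE)
  }
  check_levels <- function(values, allowed, field) {
    bad <- which(!(values %in% allowed))
    if (length(bad) > 0L) {
      stop(sprintf("rearing CSV '%s' line %d: invalid %s '%s'",
                   path, bad[1L] + 1L, field, values[bad[1L]]),
           call. = FALSE)
    }
  }
  check_levels(df$stage, life_stages(), "stage")
  check_levels(df$outcome, rearing_outcomes(), "outcome")
  bad_t <- which(!is.finite(df$temperature_c))
  if (length(bad_t) > 0L) {
    stop(sprintf("rearing CSV '%s' line %d: non-numeric temperature_c",
                 path, bad_t[1L] + 1L), call. = FALSE)
  }
  bad_d <- which(df$outcome == "completed" &
                   (!is.finite(df$duration_days) | df$duration_days <= 0))
  if (length(bad_d) > 0L) {
    stop(sprintf(paste0("rearing CSV '%s' line %d: completed record needs ",
                        "a positive duration_days"),
                 path, bad_d[1L] + 1L), call. = FALSE)
  }
  data.frame(individual_id = as.character(df$individual_id),
             stage = df$stage,
             temperature = df$temperature_c,
             duration = df$duration_days,
             outcome = df$outcome)
}

#' @rdname read_rearing_csv
#' @param records Records data frame (see [simulate_rearing()]).
#' @export
write_rearing_csv <- function(records, path) {
  out <- data.frame(individual_id = records$individual_id,
                    stage = records$stage,
                    temperature_c = records$temperature,
                    duration_days = records$duration,
                    outcome = records$outcome)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write survival-count CSV files
#'
#' Columns: `temperature_c`, `stage`, `n_entering`, `n_advancing`,
#' optionally `n_arrested`.
#'
#' @param path File path.
#' @return A counts data frame usable by [life_tables_from_counts()].
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("temperature_c", "stage", "n_entering", "n_advancing")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("survival CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$n_advancing > df$n_entering | df$n_advancing < 0)
  if (length(bad) > 0L) {
    stop(sprintf(paste0("survival CSV '%s' line %d: n_advancing must lie ",
                        "in [0, n_entering]"), path, bad[1L] + 1L),
         call. = FALSE)
  }
  out <- data.frame(temperature = df$temperature_c, stage = df$stage,
                    n_entering = df$n_entering,
                    n_advancing = df$n_advancing)
  out$n_arrested <- if ("n_arrested" %in% names(df)) df$n_arrested else 0L
  out
}

#' @rdname read_survival_csv
#' @param counts Counts data frame (see [tabulate_survival()]).
#' @export
write_survival_csv <- function(counts, path) {
  out <- data.frame(temperature_c = counts$temperature,
                    stage = counts$stage,
                    n_entering = counts$n_entering,
                    n_advancing = counts$n_advancing,
                    n_arrested = if ("n_arrested" %in% names(counts)) {
                      counts$n_arrested
                    } else 0L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a weather CSV at daily or monthly resolution
#'
#' Daily files have columns `date` (YYYY-MM-DD) and `tmean_c`; monthly
#' files have `year`, `month`, `tmean_c`. The resolution is detected from
#' the header.
#'
#' @param path File path.
#' @return A [daily_series()] or [monthly_series()].
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("date", "tmean_c") %in% names(df))) {
    daily_series(df$date, df$tmean_c)
  } else if (all(c("year", "month", "tmean_c") %in% names(df))) {
    monthly_series(df$year, df$month, df$tmean_c)
  } else {
    stop("weather CSV '", path, "' must have columns date,tmean_c (daily) ",
         "or year,month,tmean_c (monthly)", call. = FALSE)
  }
}

#' @rdname read_weather_csv
#' @param series A `temperature_series`.
#' @export
write_weather_csv <- function(series, path) {
  e <- series$entries
  out <- if (series$resolution == "daily") {
    data.frame(date = format(e$date), tmean_c = e$tmean)
  } else {
    data.frame(year = e$year, month = e$month, tmean_c = e$tmean)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write fitted thermal constants
#'
#' The constants table has columns `stage`, `C`, `Sc`, `K`, `Sk`, `r`,
#' `n` (CSV) and is also writable as JSON. `write_constants()` accepts a
#' [thermal_model()] or its `constants` data frame and picks the format
#' from the file extension (`.json` for JSON, anything else CSV).
#'
#' @param path File path.
#' @return `read_constants_csv()`: the constants data frame.
#' @export
read_constants_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("stage", "C", "K"), names(df))
  if (length(miss) > 0L) {
    stop("constants file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stopifnot_stage(df$stage)
  df
}

#' @rdname read_constants_csv
#' @param x A `thermal_model` or constants data frame.
#' @export
write_constants <- function(x, path) {
  tab <- if (inherits(x, "thermal_model")) x$constants else x
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write fecundity CSV files
#'
#' Columns: `temperature_c`, `eggs_per_female`, optionally
#' `female_fraction` (default 0.5).
#'
#' @param path File path.
#' @export
read_fecundity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("temperature_c", "eggs_per_female"), names(df))
  if (length(miss) > 0L) {
    stop("fecundity CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(temperature = df$temperature_c,
                    eggs_per_female = df$eggs_per_female)
  out$female_fraction <- if ("female_fraction" %in% names(df)) {
    df$female_fraction
  } else 0.5
  out
}

#' Write a life table as CSV (stage rows plus a footer block) or JSON
#'
#' @param lt A [build_life_table()] object.
#' @param path Output path; `.json` selects the JSON mirror.
#' @export
write_life_table <- function(lt, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(temperature = lt$temperature, initial_eggs = lt$initial_eggs,
           rows = lt$rows, female_fraction = lt$female_fraction,
           eggs_per_female = lt$eggs_per_female,
           arrested_fraction = lt$arrested_fraction,
           trend_index = lt$trend_index),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      na = "null", pretty = TRUE)
  } else {
    rows <- lt$rows
    rows$n_entering <- round_half_up(rows$n_entering, 2)
    rows$survival_pct <- round_half_up(100 * rows$survival_fraction, 2)
    rows$survival_fraction <- NULL
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
    cat(sprintf("# female_fraction,%.4f\n", lt$female_fraction), file = con)
    cat(sprintf("# eggs_per_female,%.4f\n", lt$eggs_per_female), file = con)
    cat(sprintf("# trend_index,%.2f\n", round_half_up(lt$trend_index, 2)),
        file = con)
  }
  invisible(path)
}

#' Write a phenology forecast as JSON or a CSV event calendar
#'
#' JSON keeps full precision (`annual_degree_days`, `generations`, the
#' event list and completeness flag); the CSV calendar rounds degree-day
#' totals to two decimals.
#'
#' @param forecast A [forecast_emergence()] object.
#' @param path Output path; `.json` selects JSON.
#' @export
write_forecast <- function(forecast, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    ev <- forecast$events
    ev$date <- format(ev$date)
    jsonlite::write_json(
      list(biofix = format(forecast$biofix),
           annual_degree_days = forecast$annual_degree_days,
           generations = forecast$generations,
           complete = forecast$complete, events = ev),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      na = "null", pretty = TRUE)
  } else {
    ev <- forecast$events
    ev$cumulative_dd <- round_half_up(ev$cumulative_dd, 2)
    ev$date <- format(ev$date)
    utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
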