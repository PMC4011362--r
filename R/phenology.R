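#' Temperature series
#'
#' Containers for dated mean temperatures at daily or monthly resolution.
#' `daily_series()` requires a gap-free, strictly increasing run of dates;
#' `monthly_series()` stores year/month pairs and derives the number of
#' days in each month (Gregorian calendar, leap years respected).
#'
#' @param date `Date` vector (or strings coercible via [as.Date()]).
#' @param tmean Mean temperature per entry, degrees C.
#' @param year,month Integer vectors identifying each month.
#' @return An object of class `temperature_series` with fields
#'   `resolution` (`"daily"` or `"monthly"`) and `entries` (a data frame).
#' @export
#' @examples
#' daily_series(as.Date("2011-07-01") + 0:9, rep(25, 10))
daily_series <- function(date, tmean) {
  date <- as.Date(date)
  stopifnot(length(date) == length(tmean), length(date) > 0L,
            all(is.finite(tmean)))
  if (anyNA(date)) stop("unparseable dates in daily series", call. = FALSE)
  d <- diff(as.integer(date))
  if (any(d <= 0)) {
    stop("daily series must be strictly increasing with no duplicates",
         call. = FALSE)
  }
  if (any(d > 1)) {
    gaps <- date[which(d > 1)]
    stop("missing days in daily series after: ",
         paste(format(gaps), collapse = ", "), call. = FALSE)
  }
  structure(list(resolution = "daily",
                 entries = data.frame(date = date, tmean = as.numeric(tmean))),
            class = "temperature_series")
}

#' @rdname daily_series
#' @export
monthly_series <- function(year, month, tmean) {
  if (length(year) == 1L) year <- rep(year, length(month))
  stopifnot(length(year) == length(month), length(month) == length(tmean),
            length(year) > 0L, all(is.finite(tmean)),
            all(month %in% 1:12))
  idx <- year * 12 + month
  if (any(diff(idx) <= 0)) {
    stop("monthly series must be strictly increasing with no duplicates",
         call. = FALSE)
  }
  structure(list(resolution = "monthly",
                 entries = data.frame(year = as.integer(year),
                                      month = as.integer(month),
                                      tmean = as.numeric(tmean),
                                      days_in_month = days_in_month(year, month))),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("%s temperature series, %d entries\n",
              x$resolution, nrow(x$entries)))
  if (x$resolution == "daily") {
    cat(sprintf("  %s .. %s, mean %.2f degrees C\n",
                format(min(x$entries$date)), format(max(x$entries$date)),
                mean(x$entries$tmean)))
  } else {
    cat(sprintf("  %d-%02d .. %d-%02d, mean %.2f degrees C\n",
                x$entries$year[1L], x$entries$month[1L],
                x$entries$year[nrow(x$entries)],
                x$entries$month[nrow(x$entries)], mean(x$entries$tmean)))
  }
  invisible(x)
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  out[month == 2L & leap] <- 29L
  out
}

#' Degree-days from a monthly temperature series
#'
#' Monthly effective-temperature accumulation: each month contributes
#' `max(0, mean temperature - threshold) * days in month` degree-days.
#' Months at or below the threshold contribute nothing (no degree-day
#' "debt").
#'
#' @param series A monthly [monthly_series()].
#' @param threshold Developmental threshold temperature, degrees C.
#' @return Total degree-days over the series.
#' @export
#' @examples
#' s <- monthly_series(2011, 6, 20.84)
#' monthly_degree_days(s, 10.84)  # 10 deg x 30 d = 300 DD
monthly_degree_days <- function(series, threshold) {
  stopifnot(inherits(series, "temperature_series"))
  if (series$resolution != "monthly") {
    stop("resolution mismatch: monthly_degree_days() needs a monthly ",
         "series; see daily_degree_days()", call. = FALSE)
  }
  e <- series$entries
  sum(pmax(0, e$tmean - threshold) * e$days_in_month)
}

#' Degree-day trajectory from a daily temperature series
#'
#' Running accumulation of daily effective temperature
#' `max(0, mean temperature - threshold)`. The final cumulative value is
#' the series total.
#'
#' @param series A daily [daily_series()].
#' @param threshold Developmental threshold temperature, degrees C.
#' @return Data frame with columns `date`, `daily_dd` and `cumulative_dd`;
#'   the total is `cumulative_dd[nrow]`.
#' @export
daily_degree_days <- function(series, threshold) {
  stopifnot(inherits(series, "temperature_series"))
  if (series$resolution != "daily") {
    stop("resolution mismatch: daily_degree_days() needs a daily series; ",
         "see monthly_degree_days()", call. = FALSE)
  }
  e <- series$entries
  dd <- pmax(0, e$tmean - threshold)
  data.frame(date = e$date, daily_dd = dd, cumulative_dd = cumsum(dd))
}

#' Generations per year from annual heat accumulation
#'
#' Voltinism estimate: the annual effective accumulated temperature
#' divided by the degree-days one full generation requires, reported to
#' two decimals with the fractional part retained.
#'
#' @param annual_degree_days Annual degree-day total above the generation
#'   threshold.
#' @param K_generation Degree-days to complete one generation.
#' @param complete If `TRUE`, return the integer number of completed
#'   generations (floor of the quotient) instead.
#' @return Generations per year (two decimals), or an integer count when
#'   `complete = TRUE`.
#' @export
#' @examples
#' generations_per_year(2183.34, 574.08)  # 3.80
generations_per_year <- function(annual_degree_days, K_generation,
                                 complete = FALSE) {
  if (!is.finite(K_generation) || K_generation <= 0) {
    stop("invalid thermal constant: K_generation must be positive",
         call. = FALSE)
  }
  stopifnot(is.finite(annual_degree_days), annual_degree_days >= 0)
  q <- annual_degree_days / K_generation
  if (complete) floor(q) else round_half_up(q, 2)
}

#' Forecast stage transitions and adult emergence peaks
#'
#' Chains degree-day accumulation through the generation cycle over a
#' daily temperature series. The cycle starts at the pupal stage (the
#' overwintered generation emerges from overwintered pupae) and then runs
#' pupa -> preoviposition -> egg -> larva -> prepupa within each
#' generation. For each stage, daily effective temperature above that
#' stage's threshold `C` is accumulated, starting the day after the
#' previous transition (or the day after `biofix` for the first stage);
#' the first day on which the running total reaches the stage's thermal
#' constant `K` is the transition date. Completion of a pupal stage is
#' that generation's adult emergence peak.
#'
#' No within-day interpolation is applied: daily means are the finest
#' resolution used, so a transition lands on the first whole day whose
#' cumulative total reaches `K`.
#'
#' @param series A daily [daily_series()] spanning the forecast horizon.
#' @param stage_constants Data frame with columns `stage`, `C` and `K`
#'   containing at least the stages `pupa`, `preoviposition`, `egg`,
#'   `larva`, `prepupa` (e.g. `as.data.frame`-style from
#'   [thermal_model()] constants or [read_constants_csv()]).
#' @param biofix Date at which accumulation starts (first heat counted on
#'   the following day). Must lie inside the series span.
#' @param n_generations Maximum number of full generation cycles to
#'   forecast; default 4.
#' @param generation_constants Optional list/row with `C` and `K` for the
#'   whole generation; when supplied, the forecast also reports the
#'   series' total degree-days above that threshold and the implied
#'   generations per year.
#' @return Object of class `phenology_forecast`: list with `events`
#'   (generation, stage, date, cumulative_dd at crossing), `complete`
#'   (`FALSE` when the series ended before the requested generations
#'   finished), `biofix`, and optionally `annual_degree_days` and
#'   `generations`.
#' @export
forecast_emergence <- function(series, stage_constants, biofix,
                               n_generations = 4,
                               generation_constants = NULL) {
  stopifnot(inherits(series, "temperature_series"))
  if (series$resolution != "daily") {
    stop("resolution mismatch: forecasting needs a daily series",
         call. = FALSE)
  }
  biofix <- as.Date(biofix)
  e <- series$entries
  if (biofix < min(e$date) || biofix > max(e$date)) {
    stop("biofix must lie inside the series span", call. = FALSE)
  }
  cyc <- c("pupa", "preoviposition", "egg", "larva", "prepupa")
  stopifnot(is.data.frame(stage_constants),
            all(c("stage", "C", "K") %in% names(stage_constants)))
  missing_st <- setdiff(cyc, stage_constants$stage)
  if (length(missing_st) > 0L) {
    stop("stage constants missing for: ",
         paste(missing_st, collapse = ", "), call. = FALSE)
  }
  const <- stage_constants[match(cyc, stage_constants$stage), ]

  events <- data.frame(generation = integer(0), stage = character(0),
                       date = as.Date(character(0)),
                       cumulative_dd = numeric(0))
  complete <- TRUE
  # index of the first day whose heat counts toward the current stage
  i <- match(biofix, e$date) + 1L
  nd <- nrow(e)
  for (gen in seq_len(n_generations)) {
    for (k in seq_along(cyc)) {
      C <- const$C[k]; K <- const$K[k]
      acc <- 0
      crossed <- FALSE
      while (i <= nd) {
        acc <- acc + max(0, e$tmean[i] - C)
        if (acc >= K) { crossed <- TRUE; break }
        i <- i + 1L
      }
      if (!crossed) { complete <- FALSE; break }
      events <- rbind(events, data.frame(
        generation = gen, stage = cyc[k], date = e$date[i],
        cumulative_dd = acc))
      i <- i + 1L  # the next stage starts accumulating the following day
    }
    if (!complete) break
  }

  out <- list(events = events, complete = complete, biofix = biofix,
              n_generations = n_generations)
  if (!is.null(generation_constants)) {
    gC <- generation_constants[["C"]]; gK <- generation_constants[["K"]]
    traj <- daily_degree_days(series, gC)
    out$annual_degree_days <- traj$cumulative_dd[nrow(traj)]
    out$generations <- generations_per_year(out$annual_degree_days, gK)
  }
  structure(out, class = "phenology_forecast")
}

#' @export
print.phenology_forecast <- function(x, ...) {
  cat("Degree-day phenology forecast (biofix ", format(x$biofix), ")\n",
      sep = "")
  if (!is.null(x$annual_degree_days)) {
    cat(sprintf("  series total: %.2f DD above the generation threshold -> %.2f generations\n",
                x$annual_degree_days, x$generations))
  }
  if (nrow(x$events) == 0L) {
    cat("  no stage transitions reached")
  } else {
    ev <- x$events
    ev$cumulative_dd <- round_half_up(ev$cumulative_dd, 2)
    ev$event <- ifelse(ev$stage == "pupa", "adult emergence peak", "")
    print(ev, row.names = FALSE)
  }
  if (!x$complete) {
    cat("  [incomplete: series ended before the requested generations finished]\n")
  }
  invisible(x)
}

#' @export
#' @rdname forecast_emergence
#' @param x A `phenology_forecast`.
#' @param series_plot Daily series to draw the cumulative trajectory from.
#' @param threshold Threshold for the plotted trajectory.
#' @param ... Passed to [graphics::plot()].
plot.phenology_forecast <- function(x, series_plot, threshold = 10.84, ...) {
  traj <- daily_degree_days(series_plot, threshold)
  graphics::plot(traj$date, traj$cumulative_dd, type = "l",
                 xlab = "date", ylab = "cumulative degree-days", ...)
  em <- x$events[x$events$stage == "pupa", ]
  if (nrow(em) > 0L) {
    graphics::abline(v = em$date, lty = 2, col = "firebrick")
  }
  invisible(x)
}
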