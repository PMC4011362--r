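#' Summarise rearing records into per-treatment developmental rates
#'
#' Collapses individual stage-duration records to one row per constant
#' rearing temperature: the arithmetic mean duration over individuals that
#' completed the stage, the number completing, and the developmental rate
#' `V = 1 / mean duration` (per day). Individuals that died or entered
#' developmental arrest are excluded from the mean.
#'
#' @param records Data frame of rearing records with columns
#'   `individual_id`, `stage`, `temperature` (degrees C), `duration` (days)
#'   and `outcome` (`"completed"`, `"died"` or `"arrested"`). See
#'   [read_rearing_csv()] and [simulate_rearing()].
#' @param stage Single stage label (see [life_stages()]) to summarise.
#' @return Data frame with columns `stage`, `temperature`, `n_completed`,
#'   `mean_duration` and `rate`, one row per distinct temperature, sorted
#'   by temperature.
#' @seealso [fit_thermal_constants()], [thermal_model()]
#' @export
#' @examples
#' rec <- data.frame(individual_id = 1:4, stage = "egg",
#'                   temperature = c(24, 24, 27, 27),
#'                   duration = c(3, 5, 2.5, 3.5), outcome = "completed")
#' summarize_treatments(rec, "egg")
summarize_treatments <- function(records, stage) {
  stopifnot(is.data.frame(records))
  needed <- c("individual_id", "stage", "temperature", "duration", "outcome")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("rearing records lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(stage) != 1L) stop("'stage' must be a single label", call. = FALSE)
  stopifnot_stage(stage)

  sub <- records[records$stage == stage & records$outcome == "completed", ]
  if (nrow(sub) == 0L) {
    stop("no completed records for stage '", stage,
         "' at any temperature", call. = FALSE)
  }
  if (any(!is.finite(sub$temperature))) {
    stop("non-finite temperature in rearing records", call. = FALSE)
  }
  if (any(!is.finite(sub$duration) | sub$duration <= 0)) {
    stop("completed records must have positive finite durations", call. = FALSE)
  }

  mean_d <- tapply(sub$duration, sub$temperature, mean)
  n <- tapply(sub$duration, sub$temperature, length)
  temps <- as.numeric(names(mean_d))
  ord <- order(temps)
  out <- data.frame(
    stage = stage,
    temperature = temps[ord],
    n_completed = as.integer(n[ord]),
    mean_duration = as.numeric(mean_d[ord]),
    row.names = NULL
  )
  out$rate <- 1 / out$mean_duration
  out
}

#' Fit the law of effective temperature for one life stage
#'
#' Estimates the developmental threshold temperature `C` (degrees C) and
#' the effective accumulative temperature (thermal constant) `K`
#' (degree-days) by ordinary least squares on the linear law
#' `T = C + K * V`, where `T` is the rearing temperature and `V` the
#' per-treatment mean developmental rate. The intercept is `C` and the
#' slope is `K`; `Sc` and `Sk` are the standard OLS intercept and slope
#' standard errors (undefined, returned as `NA`, with only two
#' treatments), and `r` is the Pearson correlation between rate and
#' temperature.
#'
#' The regression is run on treatment-level mean rates, so `n` is the
#' number of temperature treatments, not the number of insects.
#'
#' @param summaries Per-treatment summaries as returned by
#'   [summarize_treatments()]: a data frame with columns `temperature` and
#'   `rate` (and optionally `stage`).
#' @return An object of class `thermal_constants`: a list with elements
#'   `stage`, `C`, `Sc`, `K`, `Sk`, `r`, `n`, the underlying `lm` fit
#'   (`fit`) and the input `summaries`.
#' @seealso [thermal_model()] to fit all stages of a rearing data set at
#'   once; [predict_duration()] for the inverse prediction.
#' @export
#' @examples
#' s <- data.frame(temperature = c(20, 30), rate = c(0.1, 0.2))
#' fit_thermal_constants(s)  # C = 10, K = 100
fit_thermal_constants <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  if (!all(c("temperature", "rate") %in% names(summaries))) {
    stop("summaries need 'temperature' and 'rate' columns", call. = FALSE)
  }
  temps <- summaries$temperature
  rate <- summaries$rate
  if (length(unique(temps)) < 2L) {
    stop("degenerate design: need at least 2 distinct temperatures",
         call. = FALSE)
  }
  if (any(!is.finite(rate) | rate <= 0)) {
    stop("all developmental rates must be positive and finite",
         call. = FALSE)
  }

  fit <- stats::lm(temps ~ rate)
  co <- stats::coef(fit)
  C <- unname(co[1L])
  K <- unname(co[2L])
  if (!is.finite(K) || K <= 0) {
    stop("non-physical fit: estimated thermal constant K <= 0 ",
         "(development must accelerate with temperature)", call. = FALSE)
  }
  n <- length(temps)
  if (n > 2L) {
    # collinear (noise-free) input triggers lm's "essentially perfect
    # fit" warning; the zero standard errors are exactly what we want
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    Sc <- unname(se[1L])
    Sk <- unname(se[2L])
  } else {
    Sc <- NA_real_
    Sk <- NA_real_
  }
  stage <- if ("stage" %in% names(summaries)) summaries$stage[1L] else NA_character_

  structure(
    list(stage = stage, C = C, Sc = Sc, K = K, Sk = Sk,
         r = stats::cor(rate, temps), n = n,
         fit = fit, summaries = summaries),
    class = "thermal_constants"
  )
}

#' @export
print.thermal_constants <- function(x, digits = 2, ...) {
  cat("Law of effective temperature: T = C + K * V\n")
  if (!is.na(x$stage)) cat("Stage:", x$stage, "\n")
  cat(sprintf("  C  = %.*f degrees C (threshold), Sc = %s\n", digits, x$C,
              if (is.na(x$Sc)) "NA" else sprintf("%.*f", digits, x$Sc)))
  cat(sprintf("  K  = %.*f degree-days (thermal constant), Sk = %s\n",
              digits, x$K,
              if (is.na(x$Sk)) "NA" else sprintf("%.*f", digits, x$Sk)))
  cat(sprintf("  r  = %.4f over n = %d temperature treatments\n", x$r, x$n))
  invisible(x)
}

#' @export
coef.thermal_constants <- function(object, ...) {
  c(C = object$C, K = object$K)
}

#' @export
predict.thermal_constants <- function(object, temperature, ...) {
  predict_duration(object, temperature)
}

#' Predict stage duration at a temperature
#'
#' Inverts the law of effective temperature: at temperature `T` above the
#' threshold `C`, development takes `K / (T - C)` days.
#'
#' @param constants A `thermal_constants` fit, or any list/vector with
#'   elements `C` and `K`.
#' @param temperature Temperatures (degrees C), all strictly above `C`.
#' @return Predicted durations in days, one per temperature.
#' @export
#' @examples
#' predict_duration(list(C = 10.84, K = 574.08), 26.84)  # 35.88 days
predict_duration <- function(constants, temperature) {
  C <- constants[["C"]]
  K <- constants[["K"]]
  stopifnot(is.finite(C), is.finite(K), K > 0)
  if (any(!is.finite(temperature))) {
    stop("temperatures must be finite", call. = FALSE)
  }
  if (any(temperature <= C)) {
    stop(sprintf(paste0("temperature at or below the developmental ",
                        "threshold (%.2f degrees C): development does not ",
                        "proceed"), C), call. = FALSE)
  }
  K / (temperature - C)
}

#' Fit thermal constants for every stage of a rearing data set
#'
#' The package's central model fit. For each requested life stage it
#' summarises the rearing records to per-treatment mean rates
#' ([summarize_treatments()]) and fits the law of effective temperature
#' `T = C + K * V` ([fit_thermal_constants()]). Stages with fewer than two
#' temperatures at which any individual completed (e.g. because of
#' low-temperature developmental arrest) are dropped with a warning.
#'
#' @param records Rearing records; see [summarize_treatments()].
#' @param stages Stage labels to fit. Defaults to every stage present in
#'   `records`, in [life_stages()] order.
#' @return Object of class `thermal_model`: list with `constants` (data
#'   frame of stage, C, Sc, K, Sk, r, n), `fits` (named list of
#'   `thermal_constants`), and the matched call.
#' @export
#' @examples
#' sc <- athetis_scenario(duration_noise_cv = 0, observation_interval = 0)
#' tm <- thermal_model(simulate_rearing(sc))
#' coef(tm)
thermal_model <- function(records, stages = NULL) {
  if (is.null(stages)) {
    stages <- intersect(life_stages(), unique(records$stage))
  }
  stopifnot_stage(stages)
  fits <- list()
  for (st in stages) {
    fit <- tryCatch({
      s <- summarize_treatments(records, st)
      if (length(unique(s$temperature)) < 2L) {
        warning("stage '", st, "' completed at fewer than 2 temperatures; ",
                "dropped from the model", call. = FALSE)
        NULL
      } else {
        fit_thermal_constants(s)
      }
    }, error = function(e) {
      warning("stage '", st, "' could not be fitted: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(fit)) fits[[st]] <- fit
  }
  if (length(fits) == 0L) {
    stop("no stage could be fitted from these records", call. = FALSE)
  }
  constants <- do.call(rbind, lapply(names(fits), function(st) {
    f <- fits[[st]]
    data.frame(stage = st, C = f$C, Sc = f$Sc, K = f$K, Sk = f$Sk,
               r = f$r, n = f$n, row.names = NULL)
  }))
  structure(list(constants = constants, fits = fits,
                 call = match.call()),
            class = "thermal_model")
}

#' @export
print.thermal_model <- function(x, digits = 2, ...) {
  cat("Thermal development model (law of effective temperature)\n")
  cat("  per-stage fits of T = C + K * V on treatment mean rates\n\n")
  tab <- x$constants
  tab$C <- round(tab$C, digits); tab$Sc <- round(tab$Sc, digits)
  tab$K <- round(tab$K, digits); tab$Sk <- round(tab$Sk, digits)
  tab$r <- round(tab$r, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.thermal_model <- function(object, ...) {
  m <- as.matrix(object$constants[, c("C", "K")])
  rownames(m) <- object$constants$stage
  m
}

#' @export
summary.thermal_model <- function(object, ...) {
  structure(list(constants = object$constants,
                 lm_summaries = lapply(object$fits,
                                       function(f) summary(f$fit))),
            class = "summary.thermal_model")
}

#' @export
print.summary.thermal_model <- function(x, ...) {
  cat("Per-stage thermal constants (treatment-level OLS):\n")
  print(x$constants, row.names = FALSE)
  cat("\nResidual standard errors (degrees C) by stage:\n")
  for (st in names(x$lm_summaries)) {
    cat(sprintf("  %-15s %.4g on %d df\n", st, x$lm_summaries[[st]]$sigma,
                x$lm_summaries[[st]]$df[2L]))
  }
  invisible(x)
}

#' @export
#' @rdname thermal_model
#' @param object,x A `thermal_model`.
#' @param temperature Temperatures at which to predict stage durations.
#' @param ... Unused.
predict.thermal_model <- function(object, temperature, ...) {
  out <- sapply(object$fits, function(f) {
    ifelse(temperature > f$C, f$K / (temperature - f$C), NA_real_)
  })
  if (length(temperature) == 1L) out <- t(as.matrix(out))
  rownames(out) <- as.character(temperature)
  out
}

#' @export
residuals.thermal_model <- function(object, ...) {
  lapply(object$fits, function(f) stats::residuals(f$fit))
}

#' @export
#' @rdname thermal_model
plot.thermal_model <- function(x, ...) {
  fits <- x$fits
  temps <- unlist(lapply(fits, function(f) f$summaries$temperature))
  rates <- unlist(lapply(fits, function(f) f$summaries$rate))
  graphics::plot(NA, xlim = range(rates), ylim = range(temps),
                 xlab = "developmental rate V (1/day)",
                 ylab = "temperature (degrees C)", ...)
  cols <- seq_along(fits)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    graphics::points(f$summaries$rate, f$summaries$temperature,
                     col = cols[i], pch = 16)
    graphics::abline(f$C, f$K, col = cols[i])
  }
  graphics::legend("topleft", legend = names(fits), col = cols,
                   lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate new rearing records from a fitted thermal model
#'
#' Draws synthetic rearing data sets whose true thresholds and thermal
#' constants are the fitted ones, using [simulate_rearing()]. Useful for
#' parametric-bootstrap style checks of estimator behaviour.
#'
#' @param object A `thermal_model`.
#' @param nsim Number of data sets.
#' @param seed Integer seed.
#' @param temperatures,n_per_treatment,duration_noise_cv Passed to
#'   [rearing_scenario()].
#' @param ... Unused.
#' @return A list of `nsim` rearing-record data frames.
#' @export
simulate.thermal_model <- function(object, nsim = 1, seed = NULL,
                                   temperatures = c(18, 21, 24, 27, 30),
                                   n_per_treatment = 90,
                                   duration_noise_cv = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  truth <- data.frame(stage = object$constants$stage,
                      C = object$constants$C, K = object$constants$K)
  lapply(seq_len(nsim), function(i) {
    sc <- rearing_scenario(
      temperatures = temperatures, n_per_treatment = n_per_treatment,
      stage_truth = truth, duration_noise_cv = duration_noise_cv,
      observation_interval = 0, seed = NULL
    )
    simulate_rearing(sc)
  })
}
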