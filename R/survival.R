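#' Stage survival rate
#'
#' Percentage of insects that progressed into the next developmental
#' stage: `100 * n_advancing / n_entering`, reported to two decimals
#' (half-up, matching the usual reporting convention).
#'
#' @param n_advancing Count of insects reaching the next stage.
#' @param n_entering Count of insects that entered the stage.
#' @return Survival in percent, rounded half-up to two decimals.
#'   Vectorised over both arguments.
#' @export
#' @examples
#' survival_rate(37, 180)  # 20.56
survival_rate <- function(n_advancing, n_entering) {
  if (any(n_entering <= 0)) {
    stop("undefined rate: n_entering must be positive", call. = FALSE)
  }
  if (any(n_advancing < 0) || any(n_advancing > n_entering)) {
    stop("inconsistent counts: need 0 <= n_advancing <= n_entering",
         call. = FALSE)
  }
  round_half_up(100 * n_advancing / n_entering, 2)
}

#' Cubic survival-versus-temperature curve
#'
#' Constructs a `survival_cubic` object directly from known coefficients,
#' in descending degree order: `Y = a*T^3 + b*T^2 + c*T + d` with `Y` the
#' generation survival (percent) and `T` the temperature (degrees C).
#' Use [fit_survival_cubic()] to estimate the coefficients from data.
#'
#' @param coefficients Numeric length-4 vector `c(a, b, c, d)`.
#' @param fit_range Length-2 numeric: the temperature interval (degrees C)
#'   on which the curve is considered valid. Default `c(21, 30)`.
#' @return An object of class `survival_cubic`.
#' @export
#' @examples
#' survival_cubic(c(-0.0914, 2.57, 56.076, -1450.7))
survival_cubic <- function(coefficients, fit_range = c(21, 30)) {
  stopifnot(length(coefficients) == 4L, all(is.finite(coefficients)),
            length(fit_range) == 2L, fit_range[1L] < fit_range[2L])
  coefficients <- as.numeric(coefficients)
  names(coefficients) <- c("a", "b", "c", "d")
  structure(list(coefficients = coefficients,
                 fit_range = as.numeric(fit_range),
                 model = NULL),
            class = "survival_cubic")
}

#' Fit the cubic generation-survival model
#'
#' Least-squares fit of `Y = a*T^3 + b*T^2 + c*T + d` to survival
#' percentages observed at constant temperatures. Observations outside
#' `fit_range` are excluded. With exactly four points the fit is the
#' unique interpolating cubic.
#'
#' @param temperature Temperatures (degrees C).
#' @param survival_pct Survival at each temperature, percent.
#' @param fit_range Temperature interval used for fitting and later
#'   optimum-finding; default `c(21, 30)` degrees C.
#' @return A `survival_cubic` object; `coefficients` are in descending
#'   degree order `(a, b, c, d)`.
#' @seealso [optimal_temperature()]
#' @export
fit_survival_cubic <- function(temperature, survival_pct,
                               fit_range = c(21, 30)) {
  stopifnot(length(temperature) == length(survival_pct))
  keep <- temperature >= fit_range[1L] & temperature <= fit_range[2L]
  temperature <- temperature[keep]
  survival_pct <- survival_pct[keep]
  if (length(unique(temperature)) < 4L) {
    stop("underdetermined fit: need >= 4 distinct temperatures within ",
         "the fit range to identify a cubic", call. = FALSE)
  }
  fit <- stats::lm(survival_pct ~ temperature + I(temperature^2) +
                     I(temperature^3))
  co <- rev(unname(stats::coef(fit)))  # descending degree
  obj <- survival_cubic(co, fit_range)
  obj$model <- fit
  obj
}

#' @export
predict.survival_cubic <- function(object, temperature, ...) {
  co <- object$coefficients
  co[1L] * temperature^3 + co[2L] * temperature^2 +
    co[3L] * temperature + co[4L]
}

#' @export
print.survival_cubic <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Generation survival curve: Y = %.4g*T^3 + %.4g*T^2 + %.4g*T + %.4g\n",
              co[1L], co[2L], co[3L], co[4L]))
  cat(sprintf("  valid on [%.1f, %.1f] degrees C\n",
              x$fit_range[1L], x$fit_range[2L]))
  opt <- tryCatch(suppressWarnings(optimal_temperature(x)),
                  error = function(e) NA_real_)
  if (is.finite(opt)) {
    cat(sprintf("  interior optimum at %.2f degrees C\n", opt))
  } else {
    cat("  no interior optimum in the fit range\n")
  }
  invisible(x)
}

#' @export
#' @rdname survival_cubic
#' @param x A `survival_cubic`.
#' @param ... Passed to [graphics::plot()].
plot.survival_cubic <- function(x, ...) {
  tt <- seq(x$fit_range[1L], x$fit_range[2L], length.out = 200L)
  graphics::plot(tt, predict(x, tt), type = "l",
                 xlab = "temperature (degrees C)",
                 ylab = "generation survival (%)", ...)
  opt <- tryCatch(suppressWarnings(optimal_temperature(x)),
                  error = function(e) NA_real_)
  if (is.finite(opt)) graphics::abline(v = opt, lty = 2)
  invisible(x)
}

#' Optimum temperature of a survival curve
#'
#' Locates the interior maximum of the cubic survival curve on its fit
#' range by solving the derivative quadratic `3a*T^2 + 2b*T + c = 0` in
#' closed form and keeping the root with negative second derivative that
#' lies inside the range. Degenerate cases (`a = 0`) reduce to the
#' parabola vertex.
#'
#' @param curve A `survival_cubic`.
#' @return The optimum temperature in degrees C (full precision; round to
#'   two decimals for reporting), or `NA` with a warning when the curve
#'   has no interior maximum on its fit range.
#' @export
#' @examples
#' optimal_temperature(survival_cubic(c(-0.0914, 2.57, 56.076, -1450.7)))
optimal_temperature <- function(curve) {
  stopifnot(inherits(curve, "survival_cubic"))
  co <- curve$coefficients
  a <- co[1L]; b <- co[2L]; cc <- co[3L]
  lo <- curve$fit_range[1L]; hi <- curve$fit_range[2L]

  cands <- numeric(0)
  if (abs(a) < .Machine$double.eps) {
    if (b < 0) cands <- -cc / (2 * b)        # parabola vertex (maximum)
  } else {
    disc <- (2 * b)^2 - 4 * (3 * a) * cc
    if (disc >= 0) {
      roots <- (-2 * b + c(-1, 1) * sqrt(disc)) / (2 * 3 * a)
      # maximum where the second derivative 6a*T + 2b is negative
      cands <- roots[6 * a * roots + 2 * b < 0]
    }
  }
  cands <- cands[is.finite(cands) & cands >= lo & cands <= hi]
  if (length(cands) == 0L) {
    warning("no interior maximum of the survival curve on [",
            lo, ", ", hi, "] degrees C", call. = FALSE)
    return(NA_real_)
  }
  unname(cands[1L])
}
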