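#' Recognised life stages
#'
#' The stage vocabulary used throughout the package. `larva` denotes the
#' whole larval period (hatch to cocoon completion); `instar1`..`instar6`
#' are the individual larval stadia; `generation` is the full egg-to-first-
#' oviposition cycle; `preoviposition` is the interval between female
#' emergence and first egg laying.
#'
#' @return Character vector of valid stage labels.
#' @export
#' @examples
#' life_stages()
life_stages <- function() {
  c("egg", paste0("instar", 1:6), "larva", "prepupa", "pupa",
    "preoviposition", "adult_female", "adult_male", "generation")
}

# outcome vocabulary for rearing records
rearing_outcomes <- function() c("completed", "died", "arrested")

# stages propagated by the life table, in cohort order
life_table_stages <- function() c("egg", "larva", "prepupa", "pupa", "adult")

# half-up rounding to `digits` decimals; R's round() is round-half-even,
# which disagrees with the reporting convention used for survival
# percentages and generation counts
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopifnot_stage <- function(stage) {
  bad <- setdiff(stage, life_stages())
  if (length(bad) > 0L) {
    stop("unknown stage label(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  invisible(stage)
}
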