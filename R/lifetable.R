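#' Build an experimental population life table
#'
#' Propagates a cohort of eggs multiplicatively through the fixed stage
#' chain egg -> larva -> prepupa -> pupa -> adult and computes the index
#' of population trend
#' `I = (product of stage survival fractions) * female_fraction *
#' eggs_per_female`, i.e. the expected next-generation egg count per
#' current-generation egg. With the conventional 100-egg start, `I` is
#' the per-egg replacement rate of the population.
#'
#' "Adult" survival is emergence-to-oviposition success; adult longevity
#' does not enter `I`. Larvae that arrest instead of pupating should be
#' charged as mortality at the pre-pupal transition (see
#' `arrested_fraction`).
#'
#' @param stage_survivals Named numeric vector of survival fractions in
#'   `[0, 1]`, with names `egg`, `larva`, `prepupa`, `pupa`, `adult` (in
#'   that order). A missing stage is an error.
#' @param female_fraction Proportion of adults that are female, in
#'   `[0, 1]`. Default 0.5.
#' @param eggs_per_female Mean fecundity (eggs laid per female).
#' @param initial_eggs Cohort size the table starts from; default 100.
#' @param temperature Optional rearing temperature (degrees C) the table
#'   describes; used for labelling and tie-breaking in rankings.
#' @param arrested_fraction Optional fraction of mature larvae that
#'   entered developmental arrest instead of pupating. Reported alongside
#'   the table; callers who include arrest should already have folded it
#'   into the `prepupa` survival fraction.
#' @return Object of class `life_table`: list with `rows` (stage,
#'   n_entering, survival_fraction), `trend_index`, and the inputs.
#' @export
#' @examples
#' lt <- build_life_table(
#'   c(egg = 0.9, larva = 0.8, prepupa = 0.95, pupa = 0.9, adult = 1.0),
#'   female_fraction = 0.5, eggs_per_female = 345.15)
#' lt$trend_index  # 106.24 next-generation eggs per current egg
build_life_table <- function(stage_survivals, female_fraction = 0.5,
                             eggs_per_female, initial_eggs = 100,
                             temperature = NA_real_,
                             arrested_fraction = NA_real_) {
  req <- life_table_stages()
  missing_st <- setdiff(req, names(stage_survivals))
  if (length(missing_st) > 0L) {
    stop("incomplete life table: missing stage(s) ",
         paste(missing_st, collapse = ", "), call. = FALSE)
  }
  s <- as.numeric(stage_survivals[req])
  if (any(!is.finite(s) | s < 0 | s > 1)) {
    stop("survival fractions must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(is.finite(female_fraction), female_fraction >= 0,
            female_fraction <= 1,
            is.finite(eggs_per_female), eggs_per_female >= 0,
            is.finite(initial_eggs), initial_eggs > 0)

  n <- initial_eggs * cumprod(c(1, s))[seq_along(req)]
  rows <- data.frame(stage = req, n_entering = n, survival_fraction = s,
                     row.names = NULL)
  trend_index <- prod(s) * female_fraction * eggs_per_female

  structure(list(rows = rows, trend_index = trend_index,
                 female_fraction = female_fraction,
                 eggs_per_female = eggs_per_female,
                 initial_eggs = initial_eggs,
                 temperature = temperature,
                 arrested_fraction = arrested_fraction),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  hdr <- "Experimental population life table"
  if (is.finite(x$temperature)) {
    hdr <- sprintf("%s at %g degrees C", hdr, x$temperature)
  }
  cat(hdr, "\n", sep = "")
  rows <- x$rows
  rows$n_entering <- round_half_up(rows$n_entering, 2)
  rows$survival_pct <- round_half_up(100 * rows$survival_fraction, 2)
  rows$survival_fraction <- NULL
  print(rows, row.names = FALSE)
  if (is.finite(x$arrested_fraction)) {
    cat(sprintf("  arrested at pre-pupal transition: %.2f%%\n",
                100 * x$arrested_fraction))
  }
  cat(sprintf("  female fraction: %.2f, eggs per female: %.2f\n",
              x$female_fraction, x$eggs_per_female))
  cat(sprintf("  index of population trend I = %.2f\n",
              round_half_up(x$trend_index, 2)))
  invisible(x)
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  x$rows
}

#' Rank life tables by index of population trend
#'
#' @param tables A list of [build_life_table()] objects.
#' @return Data frame with `temperature`, `trend_index` and `rank`,
#'   sorted by descending trend index; ties are broken by ascending
#'   temperature.
#' @export
compare_trend_indices <- function(tables) {
  if (length(tables) < 2L) {
    stop("need at least two life tables to rank", call. = FALSE)
  }
  stopifnot(all(vapply(tables, inherits, logical(1), "life_table")))
  df <- data.frame(
    temperature = vapply(tables, function(t) t$temperature, numeric(1)),
    trend_index = vapply(tables, function(t) t$trend_index, numeric(1))
  )
  ord <- order(-df$trend_index, df$temperature)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Tabulate stage survival counts from rearing records
#'
#' Counts, per treatment temperature and life-table stage, how many
#' individuals entered the stage and how many advanced to the next one.
#' Deaths and developmental arrest both count as failures to advance;
#' arrested individuals are additionally reported in `n_arrested`.
#' The `adult` row maps the preoviposition stage: entering it means
#' having emerged from the pupa, advancing means surviving to oviposit.
#'
#' @param records Rearing records (see [simulate_rearing()] or
#'   [read_rearing_csv()]).
#' @return Data frame with `temperature`, `stage` (life-table labels),
#'   `n_entering`, `n_advancing`, `n_arrested` and `survival_pct`.
#' @export
tabulate_survival <- function(records) {
  map <- c(egg = "egg", larva = "larva", prepupa = "prepupa",
           pupa = "pupa", preoviposition = "adult")
  sub <- records[records$stage %in% names(map), ]
  if (nrow(sub) == 0L) {
    stop("no chained-stage records to tabulate", call. = FALSE)
  }
  out <- list()
  for (T in sort(unique(sub$temperature))) {
    for (st in names(map)) {
      rows <- sub[sub$temperature == T & sub$stage == st, ]
      if (nrow(rows) == 0L) next
      n_in <- nrow(rows)
      n_adv <- sum(rows$outcome == "completed")
      out[[length(out) + 1L]] <- data.frame(
        temperature = T, stage = unname(map[st]),
        n_entering = n_in, n_advancing = n_adv,
        n_arrested = sum(rows$outcome == "arrested"),
        survival_pct = survival_rate(n_adv, n_in))
    }
  }
  do.call(rbind, out)
}

#' Build life tables for every temperature of a survival-count table
#'
#' For each temperature, converts the observed stage counts into survival
#' fractions (a stage no individual entered gets survival 0: the cohort
#' had already collapsed), attaches fecundity and the female fraction,
#' and builds the [build_life_table()]; tables are then ranked by trend
#' index.
#'
#' @param counts Survival counts as from [tabulate_survival()] or
#'   [read_survival_csv()].
#' @param fecundity Data frame `temperature`, `eggs_per_female` and
#'   optionally `female_fraction` (default 0.5).
#' @param initial_eggs Cohort size each table starts from; default 100.
#' @return List with `tables` (one `life_table` per temperature) and
#'   `ranking` (from [compare_trend_indices()], `NULL` when only one
#'   temperature is present).
#' @export
life_tables_from_counts <- function(counts, fecundity, initial_eggs = 100) {
  stopifnot(is.data.frame(counts),
            all(c("temperature", "stage", "n_entering", "n_advancing") %in%
                  names(counts)),
            is.data.frame(fecundity),
            all(c("temperature", "eggs_per_female") %in% names(fecundity)))
  if (any(counts$n_advancing > counts$n_entering)) {
    stop("validation error: n_advancing exceeds n_entering", call. = FALSE)
  }
  tables <- list()
  for (T in sort(unique(counts$temperature))) {
    sub <- counts[counts$temperature == T, ]
    s <- vapply(life_table_stages(), function(st) {
      row <- sub[sub$stage == st, ]
      if (nrow(row) == 0L || row$n_entering[1L] == 0L) 0
      else row$n_advancing[1L] / row$n_entering[1L]
    }, numeric(1))
    frow <- fecundity[fecundity$temperature == T, ]
    epf <- if (nrow(frow) > 0L) frow$eggs_per_female[1L] else 0
    ff <- if (nrow(frow) > 0L && "female_fraction" %in% names(frow)) {
      frow$female_fraction[1L]
    } else 0.5
    arr <- NA_real_
    prow <- sub[sub$stage == "prepupa", ]
    if (nrow(prow) > 0L && "n_arrested" %in% names(prow) &&
        prow$n_entering[1L] > 0L) {
      arr <- prow$n_arrested[1L] / prow$n_entering[1L]
    }
    tables[[as.character(T)]] <- build_life_table(
      s, female_fraction = ff, eggs_per_female = epf,
      initial_eggs = initial_eggs, temperature = T,
      arrested_fraction = arr)
  }
  ranking <- if (length(tables) >= 2L) compare_trend_indices(tables) else NULL
  list(tables = tables, ranking = ranking)
}
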