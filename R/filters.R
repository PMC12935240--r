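#' Dataset inclusion criteria
#'
#' The four rules used to build comparable phenology datasets: a cap on how
#' many calendar months a species flowers, a minimum specimen count, either
#' a minimum span of collection years or a calendar-year window, and an
#' optional cap on specimens per day.
#'
#' @param max_months_flowering maximum number of distinct flowering months.
#' @param min_specimens minimum number of specimens per species (counted
#'   after any window filter and per-day dedup).
#' @param min_year_span minimum `max(year) - min(year)` per species, or
#'   `NULL` when a `year_window` is used instead.
#' @param year_window optional `c(earliest, latest)` inclusive year bounds
#'   (use `-Inf`/`Inf` for one-sided windows); records outside are removed
#'   before anything is counted.
#' @param max_per_day optional cap on specimens per species per calendar day.
#' @param require_consecutive_months if `TRUE`, the flowering months must
#'   form one contiguous circular block (December and January are adjacent).
#' @return object of class `dataset_criteria`.
#' @export
dataset_criteria <- function(max_months_flowering = 4L,
                             min_specimens = 20L,
                             min_year_span = 29L,
                             year_window = NULL,
                             max_per_day = NULL,
                             require_consecutive_months = TRUE) {
  stopifnot(max_months_flowering >= 1, min_specimens >= 1)
  if (!is.null(min_year_span)) stopifnot(min_year_span >= 1)
  if (!is.null(year_window)) stopifnot(length(year_window) == 2,
                                       year_window[1] <= year_window[2])
  if (!is.null(max_per_day)) stopifnot(max_per_day >= 1)
  structure(list(max_months_flowering = max_months_flowering,
                 min_specimens = min_specimens,
                 min_year_span = min_year_span,
                 year_window = year_window,
                 max_per_day = max_per_day,
                 require_consecutive_months = require_consecutive_months),
            class = "dataset_criteria")
}

#' The six standard criteria sets
#'
#' Presets for the six datasets: (1) <=4 months, >=20 specimens, >=29-year
#' span; (2) as 1 but <=3 months; (3) as 1 but >50 specimens; (4) as 1 but
#' collections from 1960 on, no span rule; (5) as 4 but before 1960;
#' (6) as 1 plus at most one specimen per day.
#'
#' @param id dataset number 1-6.
#' @return a [dataset_criteria()] object.
#' @export
table_criteria <- function(id) {
  switch(as.character(id),
    "1" = dataset_criteria(),
    "2" = dataset_criteria(max_months_flowering = 3L),
    "3" = dataset_criteria(min_specimens = 51L),
    "4" = dataset_criteria(min_year_span = NULL, year_window = c(1960, Inf)),
    "5" = dataset_criteria(min_year_span = NULL, year_window = c(-Inf, 1959)),
    "6" = dataset_criteria(max_per_day = 1L),
    stop("dataset id must be 1-6, got ", id)
  )
}

#' Count flowering months and their circular contiguity
#'
#' Months are pooled over all years: the count is the number of distinct
#' calendar months with at least one flowering record, and the months are
#' contiguous when they form a single block on the 12-month circle
#' (December-January counts as adjacent).
#'
#' @param records specimen records of one species (needs `event_month`).
#' @return list with `count` and `consecutive`.
#' @export
months_flowering <- function(records) {
  stopifnot(nrow(records) >= 1)
  m <- sort(unique(records$event_month))
  k <- length(m)
  if (k == 1 || k == 12) return(list(count = k, consecutive = TRUE))
  gaps <- diff(c(m, m[1] + 12))   # circular gaps, sum to 12
  consecutive <- (12 - max(gaps)) == (k - 1)
  list(count = k, consecutive = consecutive)
}

#' Cap the number of specimens per species per calendar day
#'
#' Keeps at most `max_per_day` records per (species, year, month, day),
#' retaining the lexicographically smallest occurrence ids so the result is
#' deterministic.
#'
#' @param records specimen-record data.frame.
#' @param max_per_day cap (>= 1).
#' @return filtered records.
#' @export
dedupe_per_day <- function(records, max_per_day) {
  stopifnot(max_per_day >= 1)
  if (nrow(records) == 0) return(records)
  key <- paste(records$species, records$event_year, records$event_month,
               records$event_day, sep = "\r")
  ord <- order(key, records$occurrence_id)
  rank_in_day <- stats::ave(seq_along(ord), key[ord], FUN = seq_along)
  keep_sorted <- rank_in_day <= max_per_day
  keep <- logical(nrow(records))
  keep[ord] <- keep_sorted
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply dataset inclusion criteria
#'
#' Filters records to any year window, applies the per-day cap, then keeps
#' species whose pooled flowering months, specimen count and year span
#' satisfy the criteria.
#'
#' @param records specimen-record data.frame.
#' @param criteria a [dataset_criteria()] object.
#' @return list with `species` (eligible labels), `records` (surviving
#'   records of eligible species) and `eligibility` (per-species summary
#'   with pass flags per criterion).
#' @export
apply_criteria <- function(records, criteria) {
  stopifnot(inherits(criteria, "dataset_criteria"))
  recs <- records
  if (!is.null(criteria$year_window)) {
    recs <- recs[recs$event_year >= criteria$year_window[1] &
                   recs$event_year <= criteria$year_window[2], , drop = FALSE]
  }
  if (!is.null(criteria$max_per_day)) {
    recs <- dedupe_per_day(recs, criteria$max_per_day)
  }
  sp <- sort(unique(recs$species))
  elig <- do.call(rbind, lapply(sp, function(s) {
    rows <- recs[recs$species == s, , drop = FALSE]
    mf <- months_flowering(rows)
    span <- max(rows$event_year) - min(rows$event_year)
    pass_months <- mf$count <= criteria$max_months_flowering &&
      (!criteria$require_consecutive_months || mf$consecutive)
    pass_n <- nrow(rows) >= criteria$min_specimens
    pass_span <- is.null(criteria$min_year_span) ||
      span >= criteria$min_year_span
    data.frame(species = s, months_flowering = mf$count,
               consecutive = mf$consecutive, n_specimens = nrow(rows),
               year_span = span, pass_months = pass_months,
               pass_specimens = pass_n, pass_span = pass_span,
               eligible = pass_months && pass_n && pass_span,
               stringsAsFactors = FALSE)
  }))
  if (is.null(elig)) {
    elig <- data.frame(species = character(), months_flowering = integer(),
                       consecutive = logical(), n_specimens = integer(),
                       year_span = integer(), pass_months = logical(),
                       pass_specimens = logical(), pass_span = logical(),
                       eligible = logical())
  }
  eligible <- elig$species[elig$eligible]
  if (length(eligible) == 0) {
    warning("no species satisfy the criteria")
  }
  out_recs <- recs[recs$species %in% eligible, , drop = FALSE]
  rownames(out_recs) <- NULL
  list(species = eligible, records = out_recs, eligibility = elig)
}
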