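#' Specification of one simulated species
#'
#' Describes the generative analog of the fitted circular regression: a mean
#' flowering day at a reference year, a linear drift in that mean, von Mises
#' scatter of individual collection dates around it, and a collection-effort
#' model (records per year, optionally depressed inside an effort-dip window
#' such as the 1914-1945 slump in worldwide collecting).
#'
#' @param species_id species label.
#' @param mean_doy_at_ref mean flowering day-of-year at the reference year
#'   (the midpoint of `year_range`), in \[1, 365\].
#' @param drift_days_per_decade signed true shift in mean flowering date,
#'   days per decade.
#' @param kappa von Mises concentration of flowering dates (> 0).
#' @param records_per_year_rate expected number of collections per year
#'   (>= 0); actual counts are Poisson.
#' @param year_range integer vector `c(first_year, last_year)`.
#' @param effort_dip optional `list(start_year=, end_year=, multiplier=)`
#'   with multiplier in \[0, 1\]: collection rate inside the window is
#'   multiplied by it.
#' @return object of class `sim_species_spec`.
#' @export
sim_species_spec <- function(species_id, mean_doy_at_ref,
                             drift_days_per_decade = 0, kappa = 20,
                             records_per_year_rate = 1,
                             year_range = c(1900, 2000),
                             effort_dip = NULL) {
  if (!is.finite(kappa) || kappa <= 0) {
    stop("kappa must be > 0 (got ", kappa, ")")
  }
  stopifnot(mean_doy_at_ref >= 1, mean_doy_at_ref <= 365,
            records_per_year_rate >= 0, length(year_range) == 2)
  if (year_range[1] >= year_range[2]) {
    stop("year_range must satisfy first_year < last_year")
  }
  if (!is.null(effort_dip)) {
    stopifnot(all(c("start_year", "end_year", "multiplier") %in%
                    names(effort_dip)))
    if (effort_dip$multiplier < 0 || effort_dip$multiplier > 1) {
      stop("effort_dip multiplier must lie in [0, 1]")
    }
  }
  structure(list(species_id = as.character(species_id),
                 mean_doy_at_ref = mean_doy_at_ref,
                 drift_days_per_decade = drift_days_per_decade,
                 kappa = kappa,
                 records_per_year_rate = records_per_year_rate,
                 year_range = as.integer(year_range),
                 effort_dip = effort_dip),
            class = "sim_species_spec")
}

#' Simulation configuration
#'
#' @param species list of [sim_species_spec()] objects.
#' @param seed master integer seed; the same config and seed yield an
#'   identical record table.
#' @param max_per_day optional cap on records per species per calendar day.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(species, seed = 1L, max_per_day = NULL) {
  if (inherits(species, "sim_species_spec")) species <- list(species)
  stopifnot(length(species) >= 1,
            all(vapply(species, inherits, TRUE, "sim_species_spec")))
  if (!is.null(max_per_day)) stopifnot(max_per_day >= 1)
  structure(list(species = species, seed = as.integer(seed),
                 max_per_day = max_per_day),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys `seed`, optional `max_per_day`, and `species`: a list of
#' blocks whose keys mirror the [sim_species_spec()] arguments.
#'
#' @param path YAML file path.
#' @return a [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- lapply(y$species, function(s) {
    do.call(sim_species_spec, s[intersect(names(s), names(formals(sim_species_spec)))])
  })
  sim_config(specs, seed = if (is.null(y$seed)) 1L else y$seed,
             max_per_day = y$max_per_day)
}

# stable small hash of a species label, so each species gets its own
# RNG substream and adding a species does not perturb the others
.species_hash <- function(id) {
  b <- utf8ToInt(id)
  h <- 0
  for (x in b) h <- (h * 131 + x) %% 1000003
  as.integer(h)
}

# per-year expected collection rates, with the effort-dip window applied
.effort_weights <- function(spec) {
  years <- seq(spec$year_range[1], spec$year_range[2])
  w <- rep(spec$records_per_year_rate, length(years))
  dip <- spec$effort_dip
  if (!is.null(dip)) {
    in_dip <- years >= dip$start_year & years <= dip$end_year
    w[in_dip] <- w[in_dip] * dip$multiplier
  }
  names(w) <- years
  w
}

#' Simulate herbarium specimen records
#'
#' For each species, the number of collections in each year is Poisson with
#' the effort-weighted rate; each record's flowering angle is drawn from a
#' von Mises centred on the drifting mean date (the drift line is anchored
#' at the midpoint of the year range) and converted back to a valid
#' Gregorian calendar date, wrapping across Dec 31 when the distribution
#' spills over the year boundary. Leap years get their extra day.
#'
#' @param config a [sim_config()] object.
#' @return specimen-record data.frame in the schema of
#'   [read_occurrences()], with attribute `"truth"`: per-species true drift
#'   and parameters.
#' @export
simulate_records <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  per_species <- lapply(config$species, function(spec) {
    sseed <- (config$seed + .species_hash(spec$species_id)) %% 2147483647L
    set.seed(sseed)
    years <- seq(spec$year_range[1], spec$year_range[2])
    ref_year <- mean(spec$year_range)
    w <- .effort_weights(spec)
    n_y <- stats::rpois(length(years), w)
    rows <- vector("list", length(years))
    for (i in seq_along(years)) {
      if (n_y[i] == 0) next
      y <- years[i]
      mean_doy <- spec$mean_doy_at_ref +
        spec$drift_days_per_decade * (y - ref_year) / 10
      mean_doy <- mean_doy %% 365               # wrap onto (0, 365]
      if (mean_doy == 0) mean_doy <- 365
      mu <- day_to_radians(mean_doy)
      theta <- rvonmises(n_y[i], mu, spec$kappa)
      doy <- radians_to_day(theta)
      ylen <- if (is_leap_year(y)) 366L else 365L
      ord <- pmin(ylen, pmax(1L, as.integer(round(doy * ylen / 365))))
      d <- as.Date(sprintf("%04d-01-01", y)) + (ord - 1L)
      rows[[i]] <- data.frame(
        species = spec$species_id,
        event_year = y,
        event_month = as.integer(format(d, "%m")),
        event_day = as.integer(format(d, "%d")),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(out)) return(NULL)
    out$occurrence_id <- sprintf("%s-%05d", spec$species_id, seq_len(nrow(out)))
    out
  })
  recs <- do.call(rbind, per_species[!vapply(per_species, is.null, TRUE)])
  if (is.null(recs)) {
    recs <- data.frame(species = character(), event_year = integer(),
                       event_month = integer(), event_day = integer(),
                       occurrence_id = character())
  }
  recs$basis_of_record <- rep("PRESERVED_SPECIMEN", nrow(recs))
  recs$latitude <- rep(NA_real_, nrow(recs))
  recs$longitude <- rep(NA_real_, nrow(recs))
  recs <- recs[, c("species", "occurrence_id", "event_year", "event_month",
                   "event_day", "basis_of_record", "latitude", "longitude")]
  rownames(recs) <- NULL
  if (!is.null(config$max_per_day)) {
    recs <- dedupe_per_day(recs, config$max_per_day)
  }
  attr(recs, "truth") <- data.frame(
    species = vapply(config$species, `[[`, "", "species_id"),
    drift_days_per_decade = vapply(config$species, `[[`, 0,
                                   "drift_days_per_decade"),
    mean_doy_at_ref = vapply(config$species, `[[`, 0, "mean_doy_at_ref"),
    kappa = vapply(config$species, `[[`, 0, "kappa")
  )
  recs
}

#' Simulate a trait under Brownian motion on a phylogeny
#'
#' Draws one multivariate-normal trait vector with covariance
#' `sigma2 * V`, where `V` is the phylogenetic covariance matrix of
#' shared root-to-tip path lengths.
#'
#' @param tree rooted `phylo` tree with positive branch lengths.
#' @param sigma2 Brownian rate (> 0).
#' @param seed integer seed; the same seed returns the same vector.
#' @return named numeric vector of tip trait values.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), sigma2 > 0)
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop("tree has missing or non-positive branch lengths; ",
         "assign lengths first, e.g. with grafen_branch_lengths()")
  }
  V <- phylo_vcv(tree)
  L <- chol(sigma2 * V)
  set.seed(as.integer(seed))
  z <- stats::rnorm(nrow(V))
  x <- drop(crossprod(L, z))
  names(x) <- rownames(V)
  x
}
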