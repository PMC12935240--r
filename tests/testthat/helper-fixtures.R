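# Fixtures are built in code at test time; no binary data ships with the
# package.

# a bare specimen-record row in the internal schema
record_row <- function(species, year, month, day, id,
                       basis = "PRESERVED_SPECIMEN") {
  data.frame(species = species, occurrence_id = id, event_year = year,
             event_month = month, event_day = day, basis_of_record = basis,
             latitude = NA_real_, longitude = NA_real_,
             stringsAsFactors = FALSE)
}

make_records <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# Six-species occurrence fixture whose eligibility under each of the six
# criteria presets is hand-countable:
#   compliant_all    Dec-Jan bloomer, 60 specimens (30 in 1920-1949, 30 in
#                    1960-1989), no same-day duplicates -> passes every set
#   six_month        Jan-Jun bloomer (6 months)        -> fails the month cap
#   sparse           Mar-May, only 10 specimens        -> fails the count
#   four_month_late  Feb-May, 40 specimens all 1965-1999 -> fails <=3 months
#                    and >50 specimens and the pre-1960 window
#   dupe_heavy       Jul-Aug, 24 specimens on 12 days (2/day; 12 before
#                    1960, 12 after) -> fails windowed counts and the
#                    1-per-day cap (12 < 20 after dedup)
#   noncontiguous    Jan + Jun (2 non-adjacent months) -> fails contiguity
filter_fixture <- function() {
  rows <- list()
  # compliant_all: one record per year; December in even years, January in
  # odd years, alternating so months pool to {12, 1}
  yrs <- c(1920:1949, 1960:1989)
  for (i in seq_along(yrs)) {
    m <- if (i %% 2 == 0) 12L else 1L
    rows[[length(rows) + 1]] <-
      record_row("compliant_all", yrs[i], m, 10L,
                 sprintf("A-%03d", i))
  }
  # six_month: months 1-6 cycling, 1930-1989
  yrs <- 1930:1989
  for (i in seq_along(yrs)) {
    rows[[length(rows) + 1]] <-
      record_row("six_month", yrs[i], ((i - 1) %% 6) + 1L, 15L,
                 sprintf("B-%03d", i))
  }
  # sparse: 10 specimens, months 3-5, 1950-2000
  yrs <- seq(1950, 2000, length.out = 10)
  for (i in seq_along(yrs)) {
    rows[[length(rows) + 1]] <-
      record_row("sparse", as.integer(round(yrs[i])), ((i - 1) %% 3) + 3L,
                 5L, sprintf("C-%03d", i))
  }
  # four_month_late: 40 specimens, months 2-5, 1965-1999, no dupes
  for (i in 1:40) {
    rows[[length(rows) + 1]] <-
      record_row("four_month_late", 1965L + ((i - 1) %% 35), ((i - 1) %% 4) + 2L,
                 (i %% 27) + 1L, sprintf("D-%03d", i))
  }
  # dupe_heavy: 12 days x 2 specimens; 6 days in 1930-1955, 6 in 1965-1990
  days <- data.frame(year = c(seq(1930, 1955, by = 5), seq(1965, 1990, by = 5)),
                     month = rep(c(7L, 8L), 6), day = rep(c(3L, 17L), 6))
  for (i in seq_len(nrow(days))) {
    for (j in 1:2) {
      rows[[length(rows) + 1]] <-
        record_row("dupe_heavy", days$year[i], days$month[i], days$day[i],
                   sprintf("E-%03d-%d", i, j))
    }
  }
  # noncontiguous: 30 specimens in Jan and Jun, 1940-1995
  yrs <- seq(1940, 1995, length.out = 30)
  for (i in seq_along(yrs)) {
    rows[[length(rows) + 1]] <-
      record_row("noncontiguous", as.integer(round(yrs[i])),
                 if (i %% 2 == 0) 1L else 6L, 20L, sprintf("F-%03d", i))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# hand-counted eligible species per criteria preset for filter_fixture()
filter_fixture_expected <- list(
  "1" = c("compliant_all", "dupe_heavy", "four_month_late"),
  "2" = c("compliant_all", "dupe_heavy"),
  "3" = c("compliant_all"),
  "4" = c("compliant_all", "four_month_late"),
  "5" = c("compliant_all"),
  "6" = c("compliant_all", "four_month_late")
)

# small MCMC settings for unit tests (defaults stay at 4 x 2500)
quick_config <- function(seed = 1L, n_chains = 2L, iterations = 800L,
                         burnin = 200L) {
  circglm_config(n_chains = n_chains, burnin = burnin,
                 iterations = iterations, seed = seed)
}

# fabricate a circglm_fit with known posterior draws, for unit-testing the
# downstream shift conversion without running MCMC
fake_fit <- function(beta1_draws, x_range = c(1950, 2000),
                     x_center = mean(x_range), beta0_draws = NULL,
                     kappa_draws = NULL) {
  n <- length(beta1_draws)
  if (is.null(beta0_draws)) beta0_draws <- rep(0, n)
  if (is.null(kappa_draws)) kappa_draws <- rep(10, n)
  structure(list(
    beta0_samples = beta0_draws, beta1_samples = beta1_draws,
    kappa_samples = kappa_draws,
    beta0_mean = phenocirc::circ_mean(beta0_draws),
    beta0_sd = phenocirc::circ_sd(beta0_draws),
    beta1_mean = mean(beta1_draws), beta1_sd = stats::sd(beta1_draws),
    kappa_mean = mean(kappa_draws),
    rhat = c(beta0 = 1, beta1 = 1, kappa = 1), converged = TRUE,
    x_center = x_center, x_range = x_range, n_obs = n
  ), class = "circglm_fit")
}

# write a Darwin Core style CSV from a data.frame of raw columns
write_dwc_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
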