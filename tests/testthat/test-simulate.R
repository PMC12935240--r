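# independent circular mean used as oracle for the generator checks
oracle_circ_mean_doy <- function(doy) {
  ang <- 2 * pi * doy / 365
  m <- atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi)
  365 * m / (2 * pi)
}

test_that("invalid generator parameters are rejected", {
  expect_error(sim_species_spec("s", 100, kappa = 0), "kappa")
  expect_error(sim_species_spec("s", 100, kappa = -2), "kappa")
  expect_error(sim_species_spec("s", 100, year_range = c(2000, 1990)),
               "year_range")
  expect_error(sim_species_spec("s", 100,
                                effort_dip = list(start_year = 1914,
                                                  end_year = 1945,
                                                  multiplier = 1.4)),
               "multiplier")
})

test_that("the same config and seed give identical record tables", {
  spec <- sim_species_spec("s", 200, drift_days_per_decade = 2, kappa = 10,
                           records_per_year_rate = 3,
                           year_range = c(1900, 1980))
  cfg <- sim_config(spec, seed = 99)
  r1 <- simulate_records(cfg)
  r2 <- simulate_records(cfg)
  expect_identical(r1, r2)
  # and a new species leaves the original stream untouched
  cfg2 <- sim_config(list(spec, sim_species_spec("t", 30, kappa = 5)),
                     seed = 99)
  r3 <- simulate_records(cfg2)
  r3s <- r3[r3$species == "s", , drop = FALSE]
  rownames(r3s) <- NULL
  attr(r1, "truth") <- NULL
  attr(r3s, "truth") <- NULL
  expect_identical(r1, r3s)
})

test_that("with no drift the circular mean day stays at the target", {
  spec <- sim_species_spec("s", 140, drift_days_per_decade = 0, kappa = 50,
                           records_per_year_rate = 10,
                           year_range = c(1950, 2000))
  recs <- simulate_records(sim_config(spec, seed = 5))
  expect_gt(nrow(recs), 400)
  doy <- day_of_year(recs$event_year, recs$event_month, recs$event_day)
  expect_lt(abs(oracle_circ_mean_doy(doy) - 140), 2)
})

test_that("a +3 days/decade drift moves the mean ~30 days over a century", {
  spec <- sim_species_spec("s", 170, drift_days_per_decade = 3, kappa = 15,
                           records_per_year_rate = 10,
                           year_range = c(1900, 2000))
  recs <- simulate_records(sim_config(spec, seed = 21))
  doy <- day_of_year(recs$event_year, recs$event_month, recs$event_day)
  first <- recs$event_year <= 1909
  last <- recs$event_year >= 1991
  shift <- oracle_circ_mean_doy(doy[last]) - oracle_circ_mean_doy(doy[first])
  # drift between decade midpoints is 3 * 9.05; von Mises scatter with
  # kappa = 15 and ~100 records per decade gives MC error ~ 2-3 days
  expect_lt(abs(shift - 27.2), 8)
})

test_that("record counts follow the effort-weighted expectation", {
  spec <- sim_species_spec("s", 100, kappa = 10, records_per_year_rate = 2,
                           year_range = c(1900, 1999),
                           effort_dip = list(start_year = 1914,
                                             end_year = 1945,
                                             multiplier = 0.25))
  recs <- simulate_records(sim_config(spec, seed = 13))
  # expected n = 2 * (100 - 32) + 0.5 * 32 = 152
  expected <- 2 * 68 + 2 * 0.25 * 32
  expect_lt(abs(nrow(recs) - expected), 3 * sqrt(expected))
  # dip window share of records ~ multiplier-weighted share of effort
  in_dip <- recs$event_year >= 1914 & recs$event_year <= 1945
  expect_lt(abs(mean(in_dip) - (0.25 * 32 * 2) / expected),
            3 * sqrt(0.25 * 0.75 / nrow(recs)) + 0.02)
})

test_that("simulated scatter matches the requested concentration", {
  spec <- sim_species_spec("s", 182, kappa = 12, records_per_year_rate = 20,
                           year_range = c(1950, 2000))
  recs <- simulate_records(sim_config(spec, seed = 3))
  doy <- day_of_year(recs$event_year, recs$event_month, recs$event_day)
  theta <- day_to_radians(doy)
  k_hat <- kappa_mle(circ_resultant(theta))
  expect_lt(abs(k_hat - 12) / 12, 0.2)
})

test_that("dates wrap across Dec 31 and stay valid Gregorian dates", {
  spec <- sim_species_spec("s", 360, kappa = 5, records_per_year_rate = 10,
                           year_range = c(1950, 2000))
  recs <- simulate_records(sim_config(spec, seed = 8))
  # a late-December mean with moderate scatter must yield January records
  expect_gt(sum(recs$event_month == 1), 0)
  expect_gt(sum(recs$event_month == 12), 0)
  # every generated date parses as a real date (Feb 29 only in leap years)
  expect_error(day_of_year(recs$event_year, recs$event_month,
                           recs$event_day), NA)
  # and the table round-trips through the Darwin Core writer/reader
  path <- tempfile(fileext = ".csv")
  write_occurrences(recs, path)
  back <- read_occurrences(path, quiet = TRUE)
  expect_equal(back$occurrence_id, recs$occurrence_id)
  expect_equal(back$event_month, recs$event_month)
})

test_that("the per-day cap thins the generated table deterministically", {
  spec <- sim_species_spec("s", 100, kappa = 80, records_per_year_rate = 30,
                           year_range = c(1990, 1995))
  capped <- simulate_records(sim_config(spec, seed = 2, max_per_day = 1))
  key <- paste(capped$event_year, capped$event_month, capped$event_day)
  expect_true(all(table(key) == 1))
})

test_that("Brownian traits have the phylogenetic covariance structure", {
  # star tree: tip values i.i.d. standard normal
  star <- ape::stree(20, "star")
  star$edge.length <- rep(1, 20)
  reps <- t(vapply(1:400, function(i) simulate_bm_trait(star, 1, seed = i),
                   numeric(20)))
  cc <- cor(reps)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.2)
  expect_lt(abs(mean(apply(reps, 2, var)) - 1), 0.15)

  # two sisters sharing 90% of the root-to-tip path: correlation ~ 0.9
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.9,c:1);")
  reps <- t(vapply(1:1000, function(i) simulate_bm_trait(tr, 1, seed = i),
                   numeric(3)))
  colnames(reps) <- tr$tip.label
  expect_lt(abs(cor(reps[, "a"], reps[, "b"]) - 0.9), 0.05)

  expect_identical(simulate_bm_trait(tr, 2, seed = 7),
                   simulate_bm_trait(tr, 2, seed = 7))
  bad <- tr
  bad$edge.length[2] <- 0
  expect_error(simulate_bm_trait(bad, 1, 1), "grafen_branch_lengths")
})
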