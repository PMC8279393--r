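delta_days <- function(age_past_105) floor(age_past_105 * 365.25)

test_that("a single life splits into exposure and one event by construction", {
  grid <- interval_grid(105, 0.5, 16L)
  # death ~0.75 years past the 105th birthday (rounded to whole days)
  d <- delta_days(0.75)
  exit <- 105 + d / 365.25
  rec <- make_records(lifespans = 0.75)
  cnt <- compute_events_exposures(rec, grid)
  expect_equal(cnt$events, c(0L, 1L, rep(0L, 14L)))
  expect_equal(cnt$exposures, c(0.5, exit - 105.5, rep(0, 14L)))
  expect_equal(cnt$at_risk, c(1L, 1L, rep(0L, 14L)))

  # right-censored exit ~0.25 years in: exposure, no event
  rec <- make_records(lifespans = 2, censored = TRUE)
  rec$last_seen_date <- add_years(rec$birth_date, 105L) + delta_days(0.25)
  cnt <- compute_events_exposures(rec, grid)
  expect_equal(sum(cnt$events), 0L)
  expect_equal(cnt$exposures[1L], delta_days(0.25) / 365.25)
  expect_equal(sum(cnt$exposures[-1L]), 0)
})

test_that("events and exposures match the daily-step Lexis oracle per record", {
  set.seed(51)
  grid <- interval_grid(105, 0.5, 16L)
  n <- 500L
  lifespans <- sample_lifespan(hazard_const(0.6), n)
  censored <- runif(n) < 0.3
  recs <- make_records(lifespans, censored = censored)
  agg_events <- integer(grid$J)
  agg_expo <- numeric(grid$J)
  tol <- 2 / 365.25
  for (i in seq_len(n)) {
    one <- structure(recs[i, , drop = FALSE], label = "test",
                     class = class(recs))
    got <- compute_events_exposures(one, grid)
    dead <- recs$scheme[i] == "FULLY_OBSERVED"
    end <- if (dead) recs$death_date[i] else recs$last_seen_date[i]
    want <- lexis_oracle_record(recs$birth_date[i], end, dead, grid)
    expect_identical(got$events, want$events)
    expect_true(all(abs(got$exposures - want$exposures) <= tol))
    agg_events <- agg_events + want$events
    agg_expo <- agg_expo + want$exposures
  }
  # the dataset-level call is the sum of the per-record contributions
  all_cnt <- compute_events_exposures(recs, grid)
  expect_identical(all_cnt$events, agg_events)
  expect_equal(sum(all_cnt$exposures), sum(agg_expo), tolerance = 1e-2)
})

test_that("counts obey conservation and the exposure bound", {
  set.seed(52)
  grid <- interval_grid(105, 0.5, 16L)
  recs <- make_records(sample_lifespan(hazard_const(0.7), 2000),
                       censored = runif(2000) < 0.2)
  cnt <- compute_events_exposures(recs, grid)
  dead <- recs$scheme == "FULLY_OBSERVED"
  death_age <- longevhaz:::grid_age(recs$birth_date[dead],
                                    recs$death_date[dead])
  in_span <- death_age >= 105 & death_age < 105 + 16 * 0.5
  expect_equal(sum(cnt$events), sum(in_span))
  expect_true(all(cnt$exposures <= cnt$at_risk * 0.5 + 1e-12))
  expect_true(all(diff(cnt$at_risk) <= 0L))
  expect_error(compute_events_exposures(
    degrade_to_interval_censored(make_records(1.2)), grid), "imputed")
})

test_that("central death rates are events over person-years, NA when empty", {
  grid <- interval_grid(105, 0.5, 2L)
  cnt <- structure(list(grid = grid, events = c(7L, 0L),
                        exposures = c(10, 5), at_risk = c(20L, 8L), n = 20L),
                   class = "interval_counts")
  est <- central_death_rates(cnt)
  expect_equal(est$rates, c(0.7, 0))
  cnt$exposures <- c(10, 0)
  expect_equal(central_death_rates(cnt)$rates, c(0.7, NA_real_))
})

test_that("estimated rates recover the generating hazard at n = 20,000", {
  set.seed(53)
  grid <- interval_grid(105, 0.5, 16L)
  mids <- longevhaz:::grid_breaks(grid)[-17L] + 0.25
  specs <- list(constant = hazard_const(0.7),
                gompertz = hazard_gompertz(0.6, 0.05),
                piecewise = hazard_piecewise(c(105, 108, 110),
                                             c(0.55, 0.7, 0.85)))
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    recs <- make_records(sample_lifespan(spec, 20000))
    est <- central_death_rates(compute_events_exposures(recs, grid))
    use <- est$at_risk >= 50
    se <- sqrt(est$events[use]) / est$exposures[use] # Poisson
    truth <- hazard_value(spec, mids[use])
    expect_true(all(abs(est$rates[use] - truth) < 3 * pmax(se, 1e-6)),
                info = nm)
  }
})

test_that("rates agree with Nelson-Aalen cumulative-hazard increments", {
  skip_if_not_installed("survival")
  set.seed(54)
  grid <- interval_grid(105, 0.5, 16L)
  n <- 1000L
  recs <- make_records(sample_lifespan(hazard_const(0.7), n),
                       censored = runif(n) < 0.25)
  est <- central_death_rates(compute_events_exposures(recs, grid))
  dead <- recs$scheme == "FULLY_OBSERVED"
  end <- recs$death_date
  end[!dead] <- recs$last_seen_date[!dead]
  exit <- longevhaz:::grid_age(recs$birth_date, end)
  sf <- survival::survfit(survival::Surv(exit - 105, dead) ~ 1)
  H <- stats::stepfun(sf$time, c(0, sf$cumhaz))
  br <- longevhaz:::grid_breaks(grid) - 105
  na_rates <- diff(H(br)) / 0.5
  use <- est$at_risk >= 50
  expect_true(all(abs(est$rates[use] - na_rates[use]) /
                    na_rates[use] < 0.05))
})

test_that("rate-to-probability transform matches its closed form", {
  grid <- interval_grid(105, 0.5, 2L)
  est <- structure(list(grid = grid, rates = c(0.7, 0.7),
                        events = c(NA, NA), exposures = c(NA, NA),
                        at_risk = c(NA, NA), n_total = 10L),
                   class = "hazard_estimate")
  q <- cumulative_death_probabilities(est)
  expect_equal(q$q[2L], 1 - exp(-0.7))
  expect_equal(round(q$q[2L], 1), 0.5)
  est$rates <- c(0, 0)
  expect_equal(cumulative_death_probabilities(est)$q, c(0, 0))
  # scalar closed form across a grid of (M, delta)
  for (M in c(0.1, 0.7, 1.5)) {
    for (d in c(0.25, 0.5, 1)) {
      g1 <- interval_grid(105, d, 1L)
      e1 <- structure(list(grid = g1, rates = M, events = NA,
                           exposures = NA, at_risk = NA, n_total = 5L),
                      class = "hazard_estimate")
      expect_equal(cumulative_death_probabilities(e1)$q, 1 - exp(-d * M))
    }
  }
  # mid-grid gaps are an error naming truncation; trailing gaps truncate
  est$rates <- c(NA, 0.7)
  expect_error(cumulative_death_probabilities(est), "truncate")
  est$rates <- c(0.7, NA)
  expect_equal(cumulative_death_probabilities(est)$grid$J, 1L)
})

test_that("probabilities back-transform to the exact input rates", {
  set.seed(55)
  for (i in 1:20) {
    J <- sample(2:16, 1L)
    d <- sample(c(0.25, 0.5), 1L)
    grid <- interval_grid(105, d, J)
    # keep the cohort non-extinct (cumulative hazard < ~5) so survival is
    # representable; at extinction the back-transform is undefined anyway
    rates <- runif(J, 0.05, min(1.5, 5 / (J * d)))
    est <- structure(list(grid = grid, rates = rates,
                          events = rep(NA, J), exposures = rep(NA, J),
                          at_risk = rep(NA, J), n_total = 1L),
                     class = "hazard_estimate")
    back <- rates_from_probabilities(cumulative_death_probabilities(est))
    expect_equal(back$rates, rates, tolerance = 1e-12)
  }
  # the spec'd numeric inverse: q = (0.2953, 0.5034) at delta 0.5 -> ~0.70
  back <- rates_from_probabilities(c(0.2953, 0.5034),
                                   interval_grid(105, 0.5, 2L))
  expect_equal(back$rates, c(0.6998, 0.7004), tolerance = 1e-3)
  # extinction: q reaching 1 leaves later rates absent and flags the result
  back <- rates_from_probabilities(c(0.5, 1, 1),
                                   interval_grid(105, 0.5, 3L))
  expect_false(is.na(back$rates[1L]))
  expect_true(all(is.na(back$rates[2:3])))
  expect_true(attr(back, "extinct"))
  expect_error(rates_from_probabilities(c(0.5, 0.4),
                                        interval_grid(105, 0.5, 2L)),
               "non-decreasing")
})

test_that("halving delta and averaging pairs reproduces the coarser rates", {
  set.seed(56)
  recs <- make_records(sample_lifespan(hazard_const(0.7), 50000))
  est2 <- central_death_rates(compute_events_exposures(
    recs, interval_grid(105, 0.5, 16L)))
  est4 <- central_death_rates(compute_events_exposures(
    recs, interval_grid(105, 0.25, 32L)))
  pair_avg <- (est4$rates[c(TRUE, FALSE)] + est4$rates[c(FALSE, TRUE)]) / 2
  use <- est2$at_risk >= 50
  se <- sqrt(est2$events[use]) / est2$exposures[use]
  expect_true(all(abs(pair_avg[use] - est2$rates[use]) < 3 * se))
})
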