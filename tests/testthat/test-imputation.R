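test_that("birth bounds reproduce the worked examples exactly", {
  b <- birth_bounds(1900, 2010, 109, 200)
  expect_equal(b$earliest, as.Date("1900-06-15"))
  expect_equal(b$latest, as.Date("1900-12-31"))
  b <- birth_bounds(1900, 2010, 110, 20)
  expect_equal(b$earliest, as.Date("1900-01-01"))
  expect_equal(b$latest, as.Date("1900-12-11"))
  # an exact whole-year age constrains nothing within the birth year
  b <- birth_bounds(1900, 2005, 105, 0)
  expect_equal(b$earliest, as.Date("1900-01-01"))
  expect_equal(b$latest, as.Date("1900-12-31"))
  expect_error(birth_bounds(1900, 2020, 105, 0), "inconsistent record")
})

test_that("bounds always contain the true birth date and match the
           every-day oracle", {
  set.seed(71)
  n <- 10000L
  lifespans <- sample_lifespan(hazard_const(0.7), n)
  recs <- make_records(lifespans,
                       birth_start = as.Date("1870-01-01"))
  truth <- recs$birth_date
  deg <- degrade_to_interval_censored(recs)
  bt <- longevhaz:::bounds_table(as.data.frame(deg))
  expect_true(all(truth >= bt$earliest))
  expect_true(all(truth <= bt$latest))
  expect_true(all(format(bt$earliest, "%Y") ==
                    sprintf("%04d", deg$birth_year)))
  expect_true(all(format(bt$latest, "%Y") ==
                    sprintf("%04d", deg$birth_year)))
  # exact support check against brute force on a subsample
  idx <- sample.int(n, 200L)
  for (i in idx) {
    want <- bounds_oracle(deg$birth_year[i], deg$death_year[i],
                          deg$age_years[i], deg$age_days[i])
    expect_equal(bt$earliest[i], want$earliest)
    expect_equal(bt$latest[i], want$latest)
  }
})

test_that("imputation draws uniformly over the bound range", {
  df <- data.frame(id = "u1", country = "US", sex = "F",
                   birth_date = "", death_date = "", last_seen_date = "",
                   birth_year = "1900", death_year = "2010",
                   age_years = "109", age_days = "200",
                   scheme = "INTERVAL_CENSORED_YEARS",
                   stringsAsFactors = FALSE)
  df <- df[rep(1L, 20000L), , drop = FALSE]
  df$id <- sprintf("u%05d", seq_len(20000L))
  rec <- longevity_records(df)
  set.seed(72)
  draws <- impute_birth(rec)$birth_date
  expect_true(all(draws >= as.Date("1900-06-15")))
  expect_true(all(draws <= as.Date("1900-12-31")))
  counts <- table(factor(as.integer(draws - as.Date("1900-06-15")),
                         levels = 0:199))
  chi <- chisq.test(as.vector(counts))
  expect_gt(chi$p.value, 1e-4)
  expect_lt(max(abs(as.vector(counts) - 100)) / sqrt(100 * 199 / 200), 5)
})

test_that("imputed records are consistent with their censored originals", {
  set.seed(73)
  recs <- make_records(sample_lifespan(hazard_const(0.7), 300))
  deg <- degrade_to_interval_censored(recs)
  imp <- impute_birth(deg)
  expect_true(all(imp$scheme == "FULLY_OBSERVED"))
  # re-degrading reproduces the original (birth year, death year, age) triple
  redeg <- degrade_to_interval_censored(imp)
  expect_identical(redeg$birth_year, deg$birth_year)
  expect_identical(redeg$death_year, deg$death_year)
  expect_identical(redeg$age_years, deg$age_years)
  expect_identical(redeg$age_days, deg$age_days)
  # a degenerate one-day range imputes that day with probability 1
  one <- structure(deg[1, , drop = FALSE], label = "t", class = class(deg))
  b <- birth_bounds(one$birth_year, one$death_year, one$age_years,
                    one$age_days)
  expect_error(impute_birth(recs), "INTERVAL_CENSORED_YEARS")
  expect_gte(as.integer(b$latest - b$earliest), 0L)
})

test_that("imputed estimation recovers the truth and reduces to m=k=1", {
  set.seed(74)
  grid <- interval_grid(105, 0.5, 16L)
  recs <- make_records(sample_lifespan(hazard_const(0.7), 2000))
  deg <- degrade_to_interval_censored(recs)
  one <- run_imputed_estimation(deg, grid, m = 1L, k = 1L, seed = 75)
  expect_s3_class(one$estimate, "hazard_estimate")
  expect_equal(one$ci$lower, one$ci$upper)

  res <- run_imputed_estimation(deg, grid, m = 20L, k = 50L, seed = 76)
  est <- central_death_rates(compute_events_exposures(recs, grid))
  use <- !is.na(res$estimate$rates) & res$estimate$at_risk >= 50
  # the exact age in days pins the death age to within a leap-day or two,
  # so the imputed point estimate must track the known-dates estimate
  J <- res$ci$grid$J
  expect_true(all(abs(res$estimate$rates[use] -
                        est$rates[seq_len(J)][use]) < 0.05))
  # in aggregate too: imputation neither adds nor removes mortality
  agg_imp <- sum(res$estimate$events) / sum(res$estimate$exposures)
  agg_known <- sum(est$events[seq_len(J)]) / sum(est$exposures[seq_len(J)])
  expect_lt(abs(agg_imp - agg_known), 0.01)

  # imputation bands at least as wide as known-dates bands (within MC noise)
  known <- empirical_ci(est, replicates = 1000L, seed = 77)
  J <- min(res$ci$grid$J, known$grid$J)
  wk <- known$upper[seq_len(J)] - known$lower[seq_len(J)]
  wi <- res$ci$upper[seq_len(J)] - res$ci$lower[seq_len(J)]
  ok <- !is.na(wk) & !is.na(wi)
  expect_true(all(wi[ok] >= wk[ok] - 0.1 * pmax(wk[ok], 0.05)))
})
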