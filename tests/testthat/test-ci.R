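cumprobs <- function(q, delta = 0.5) {
  structure(list(grid = interval_grid(105, delta, length(q)), q = q),
            class = "cum_probs")
}

const_estimate <- function(rate, J = 16L, delta = 0.5, n = 1000L) {
  structure(list(grid = interval_grid(105, delta, J),
                 rates = rep(rate, J), events = rep(NA_integer_, J),
                 exposures = rep(NA_real_, J), at_risk = rep(NA_integer_, J),
                 n_total = as.integer(n)),
            class = "hazard_estimate")
}

test_that("replicate simulation reproduces the generating probabilities", {
  # degenerate: everyone dies in the first interval
  r <- simulate_replicate(cumprobs(c(1, 1)), 50)
  expect_equal(r$q, c(1, 1))
  # law of large numbers at n = 1e6
  q <- cumulative_death_probabilities(const_estimate(0.7))$q
  set.seed(61)
  r <- simulate_replicate(cumprobs(q), 1e6)
  expect_true(all(abs(r$q - q) < 0.002))
  # determinism under a fixed seed
  set.seed(7)
  a <- simulate_replicate(cumprobs(q), 1000)
  set.seed(7)
  b <- simulate_replicate(cumprobs(q), 1000)
  expect_identical(a$q, b$q)
})

test_that("a single replicate gives a degenerate band", {
  est <- const_estimate(0.7, J = 4L)
  ci <- empirical_ci(est, n = 200, replicates = 1L, seed = 62)
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$n_defined, rep(1L, 4L))
})

test_that("first-interval band width matches the Poisson approximation", {
  # n as in the largest national series: 8,990 females at age 105
  n <- 8990L
  est <- const_estimate(0.7, n = n)
  ci <- empirical_ci(est, replicates = 2000L, seed = 63)
  width <- ci$upper[1L] - ci$lower[1L]
  # var(Mhat) ~ M / (n * delta * S) with S the survival to the interval
  approx_width <- 2 * 1.96 * sqrt(0.7 / (n * 0.5))
  expect_lt(abs(width - approx_width) / approx_width, 0.30)
})

test_that("band width shrinks like 1/sqrt(n)", {
  est1 <- const_estimate(0.7, n = 500L)
  est2 <- const_estimate(0.7, n = 2000L)
  ci1 <- empirical_ci(est1, replicates = 2000L, seed = 64)
  ci2 <- empirical_ci(est2, replicates = 2000L, seed = 65)
  ratio <- (ci2$upper[1L] - ci2$lower[1L]) / (ci1$upper[1L] - ci1$lower[1L])
  expect_lt(abs(ratio - 0.5), 0.125)
})

test_that("the point estimate lies inside its own band", {
  set.seed(66)
  recs <- make_records(sample_lifespan(hazard_const(0.7), 3000))
  est <- central_death_rates(compute_events_exposures(
    recs, interval_grid(105, 0.5, 16L)))
  ci <- empirical_ci(est, replicates = 1000L, seed = 67)
  ok <- ci$n_defined >= 0.9 * ci$replicates
  J <- ci$grid$J
  r <- est$rates[seq_len(J)]
  expect_true(all(r[ok] >= ci$lower[ok] & r[ok] <= ci$upper[ok]))
})

test_that("bands are reproducible and suppress sparse intervals", {
  est <- const_estimate(1.2, J = 16L, n = 20L) # tiny cohort, extinction likely
  ci1 <- empirical_ci(est, replicates = 500L, seed = 68)
  ci2 <- empirical_ci(est, replicates = 500L, seed = 68)
  expect_identical(ci1$lower, ci2$lower)
  expect_identical(ci1$upper, ci2$upper)
  # late intervals: most replicates extinct -> suppressed but reported
  expect_true(any(is.na(ci1$lower)))
  suppressed <- is.na(ci1$lower)
  expect_true(all(ci1$n_defined[suppressed] < 0.5 * 500))
  expect_true(all(ci1$lower[!suppressed] <= ci1$upper[!suppressed]))
})
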