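#' Bounds on the exact birth date of an interval-censored record
#'
#' A US-style record reveals only the year of birth, the year of death, and
#' the exact age at death (whole years Y plus D days). The death date is the
#' birth date advanced by Y calendar years and then D days, so the constraint
#' that the death falls inside the recorded death year, intersected with the
#' recorded birth year, bounds the birth date from both sides:
#' the earliest birth date is the later of January 1 of the birth year and
#' the date whose implied death is January 1 of the death year; the latest is
#' the earlier of December 31 of the birth year and the date whose implied
#' death is December 31 of the death year.
#'
#' @param birth_year,death_year integers.
#' @param age_years,age_days the exact age at death (Y years, D days).
#' @return a `birth_bounds` object: list with `earliest` and `latest`
#'   (`Date`), both within the birth year.
#' @examples
#' birth_bounds(1900, 2010, 109, 200) # 1900-06-15 .. 1900-12-31
#' birth_bounds(1900, 2010, 110, 20)  # 1900-01-01 .. 1900-12-11
#' @export
birth_bounds <- function(birth_year, death_year, age_years, age_days) {
  stopifnot(length(birth_year) == 1L, length(death_year) == 1L,
            length(age_years) == 1L, length(age_days) == 1L,
            age_days >= 0, age_days < 366)
  jan1 <- as.Date(sprintf("%04d-01-01", birth_year))
  dec31 <- as.Date(sprintf("%04d-12-31", birth_year))
  # smallest B with implied death >= Jan 1 of the death year
  a0 <- as.Date(sprintf("%04d-01-01", death_year)) - age_days
  earliest <- max(jan1, smallest_birth_reaching(a0, age_years))
  # largest B with implied death <= Dec 31 of the death year
  a1 <- as.Date(sprintf("%04d-12-31", death_year)) - age_days
  latest <- min(dec31, largest_birth_within(a1, age_years))
  if (earliest > latest) {
    stop(sprintf(
      "inconsistent record: no birth date in %d yields a death in %d at age %d years, %d days",
      birth_year, death_year, age_years, age_days), call. = FALSE)
  }
  structure(list(earliest = earliest, latest = latest),
            class = "birth_bounds")
}

# smallest birth date B with add_years(B, y) >= anniv (date of the y-th
# birthday); the year-shift guess can be off by a day around Feb 29, so
# correct by stepping.
smallest_birth_reaching <- function(anniv, y) {
  b <- shift_year_guess(anniv, -y)
  while (add_years(b, y) < anniv) b <- b + 1L
  while (add_years(b - 1L, y) >= anniv) b <- b - 1L
  b
}

largest_birth_within <- function(anniv, y) {
  b <- shift_year_guess(anniv, -y)
  while (add_years(b, y) > anniv) b <- b - 1L
  while (add_years(b + 1L, y) <= anniv) b <- b + 1L
  b
}

shift_year_guess <- function(date, years) {
  lt <- as.POSIXlt(date)
  out <- as.Date(sprintf("%04d-%02d-%02d", lt$year + 1900L + years,
                         lt$mon + 1L, lt$mday), format = "%Y-%m-%d")
  if (is.na(out)) out <- as.Date(sprintf("%04d-02-28",
                                         lt$year + 1900L + years))
  out
}

#' @export
print.birth_bounds <- function(x, ...) {
  cat(sprintf("<birth_bounds> %s .. %s (%d day(s))\n",
              format(x$earliest), format(x$latest),
              as.integer(x$latest - x$earliest) + 1L))
  invisible(x)
}

#' Randomly impute exact dates for interval-censored records
#'
#' Draws, for each interval-censored record, a birth date uniform over the
#' inclusive day range of its [birth_bounds()], recomputes the implied exact
#' death date (birth advanced by the recorded whole years, then days), and
#' returns the dataset with those records fully observed. Repeating the
#' imputation and pooling estimates propagates the birthdate uncertainty;
#' see [run_imputed_estimation()].
#'
#' @param dataset a [longevity_records] data.frame; all records must be
#'   `INTERVAL_CENSORED_YEARS`.
#' @param bounds optional precomputed bounds table from an earlier round
#'   (internal use; bounds depend only on the records, not on the draw).
#' @return a [longevity_records] data.frame of `FULLY_OBSERVED` records.
#' @export
impute_birth <- function(dataset, bounds = NULL) {
  stopifnot(inherits(dataset, "longevity_records"))
  if (!all(dataset$scheme == "INTERVAL_CENSORED_YEARS")) {
    stop("impute_birth() expects only INTERVAL_CENSORED_YEARS records",
         call. = FALSE)
  }
  df <- as.data.frame(dataset)
  n <- nrow(df)
  if (is.null(bounds)) bounds <- bounds_table(df)
  u <- stats::runif(n)
  birth <- bounds$earliest + floor(u * bounds$span)
  death <- add_years(birth, df$age_years) + df$age_days
  df$birth_date <- birth
  df$death_date <- death
  df$birth_year <- NA_integer_
  df$death_year <- NA_integer_
  df$age_years <- NA_integer_
  df$age_days <- NA_integer_
  df$scheme <- "FULLY_OBSERVED"
  longevity_records(df, label = attr(dataset, "label"))
}

# birth_bounds() for every row of an interval-censored data.frame
bounds_table <- function(df) {
  bb <- lapply(seq_len(nrow(df)), function(i) {
    birth_bounds(df$birth_year[i], df$death_year[i],
                 df$age_years[i], df$age_days[i])
  })
  earliest <- as.Date(vapply(bb, function(b) as.numeric(b$earliest), 0))
  latest <- as.Date(vapply(bb, function(b) as.numeric(b$latest), 0))
  list(earliest = earliest, latest = latest,
       span = as.integer(latest - earliest) + 1L)
}

#' Multiply-imputed estimation for interval-censored populations
#'
#' The full pipeline for US-style data: repeat the birthdate imputation `m`
#' times; in each round, estimate interval rates from the imputed (now fully
#' observed) records, transform them to cumulative death probabilities, and
#' simulate `k` replicate probability sets of `n` individuals as in
#' [empirical_ci()]. The m*k replicate sets are pooled; confidence bands are
#' their per-interval percentiles, so they carry both the sampling
#' uncertainty and the additional uncertainty from the imputation. The point
#' estimate back-transforms the mean of the `m` per-round cumulative
#' probability sets (combination of the rounds' point estimates).
#'
#' @param dataset a [longevity_records] data.frame, all records
#'   `INTERVAL_CENSORED_YEARS`.
#' @param grid an [interval_grid()].
#' @param m imputation rounds (default 1000).
#' @param k replicate probability sets per round (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return list with `estimate` (a `hazard_estimate`; exposure and event
#'   fields are the means over rounds) and `ci` (a `ci_bands`).
#' @export
run_imputed_estimation <- function(dataset, grid = interval_grid(),
                                   m = 1000L, k = 10000L, level = 0.95,
                                   seed = NULL) {
  stopifnot(inherits(dataset, "longevity_records"), m >= 1, k >= 1)
  if (!all(dataset$scheme == "INTERVAL_CENSORED_YEARS")) {
    stop("run_imputed_estimation() expects only INTERVAL_CENSORED_YEARS records",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # computing all bounds up front also validates every record before any
  # simulation is spent
  bounds <- bounds_table(as.data.frame(dataset))
  n <- nrow(dataset)
  J <- grid$J
  qmat_all <- vector("list", m)
  q_rounds <- matrix(NA_real_, nrow = J, ncol = m)
  events_acc <- numeric(J)
  expo_acc <- numeric(J)
  at_risk_acc <- numeric(J)
  J_min <- J
  for (r in seq_len(m)) {
    imputed <- impute_birth(dataset, bounds = bounds)
    est <- central_death_rates(compute_events_exposures(imputed, grid))
    qobs <- cumulative_death_probabilities(est)
    J_min <- min(J_min, qobs$grid$J)
    q_rounds[seq_len(qobs$grid$J), r] <- qobs$q
    events_acc <- events_acc + est$events
    expo_acc <- expo_acc + est$exposures
    at_risk_acc <- at_risk_acc + est$at_risk
    qmat_all[[r]] <- replicate_q_matrix(qobs$q, n, k)[seq_len(J_min), ,
                                                      drop = FALSE]
  }
  # pool on the grid span every round could estimate
  grid_use <- if (J_min < J) interval_grid(grid$start_age, grid$delta, J_min)
              else grid
  qbar <- rowMeans(q_rounds[seq_len(J_min), , drop = FALSE])
  point <- rates_from_probabilities(qbar, grid_use)
  point$events <- events_acc[seq_len(J_min)] / m
  point$exposures <- expo_acc[seq_len(J_min)] / m
  point$at_risk <- at_risk_acc[seq_len(J_min)] / m
  point$n_total <- n
  qmat <- do.call(cbind, lapply(qmat_all, function(x)
    x[seq_len(J_min), , drop = FALSE]))
  bands <- rate_percentile_bands(qmat, grid_use, level)
  ci <- structure(c(list(grid = grid_use), bands,
                    list(replicates = as.integer(m * k), level = level,
                         n = as.integer(n))),
                  class = "ci_bands")
  list(estimate = point, ci = ci)
}
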