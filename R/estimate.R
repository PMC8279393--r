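#' Age grid of estimation intervals
#'
#' The estimator partitions ages into `J` contiguous intervals of length
#' `delta` years starting at `start_age`:
#' \eqn{[x, x + \delta)} for \eqn{x \in \{105, 105 + \delta, \dots\}}.
#' Intervals are left-closed, right-open, so a death exactly at a boundary
#' counts in the interval opening at that boundary. The default grid covers
#' ages 105-113 in six-month steps.
#'
#' @param start_age first interval's left edge (decimal years, >= 105).
#' @param delta interval length in years (> 0).
#' @param J number of intervals (>= 1).
#' @return an `interval_grid` object.
#' @export
interval_grid <- function(start_age = 105, delta = 0.5, J = 16L) {
  stopifnot(is.numeric(start_age), start_age >= 105,
            is.numeric(delta), delta > 0, J >= 1)
  structure(list(start_age = start_age, delta = delta, J = as.integer(J)),
            class = "interval_grid")
}

#' @export
print.interval_grid <- function(x, ...) {
  cat(sprintf("<interval_grid> %d interval(s) of %g year(s): ages %g-%g\n",
              x$J, x$delta, x$start_age, x$start_age + x$J * x$delta))
  invisible(x)
}

grid_breaks <- function(grid) grid$start_age + grid$delta * (0:grid$J)

#' Events and exposures on the age grid
#'
#' The sufficient statistics of the non-parametric estimator. Every record
#' enters observation at age 105 (the truncation age) and exits at its death
#' age (fully observed) or last-seen age (right-censored), both measured as
#' 105 plus days past the 105th birthday at 365.25 days/year. Within each
#' interval \eqn{[x, x + \delta)} the record contributes the person-years it
#' lived there; a death is tallied in the interval containing the exact death
#' age; a censored exit adds exposure but no event. `at_risk` counts the
#' individuals still under observation at each interval's start.
#'
#' Interval-censored records carry no exact dates and must be imputed first
#' (see [impute_birth()] / [run_imputed_estimation()]); their presence is an
#' error.
#'
#' @param dataset a [longevity_records] data.frame.
#' @param grid an [interval_grid()].
#' @return an `interval_counts` object: list with `grid`, integer `events`,
#'   numeric `exposures` (person-years), integer `at_risk`, and `n` (records
#'   contributing).
#' @export
compute_events_exposures <- function(dataset, grid = interval_grid()) {
  stopifnot(inherits(dataset, "longevity_records"),
            inherits(grid, "interval_grid"))
  if (any(dataset$scheme == "INTERVAL_CENSORED_YEARS")) {
    stop("interval-censored records must be imputed before estimation; ",
         "see run_imputed_estimation()", call. = FALSE)
  }
  n <- nrow(dataset)
  br <- grid_breaks(grid)
  J <- grid$J
  if (n == 0L) {
    return(structure(list(grid = grid, events = integer(J),
                          exposures = numeric(J), at_risk = integer(J),
                          n = 0L),
                     class = "interval_counts"))
  }
  dead <- dataset$scheme == "FULLY_OBSERVED"
  end_date <- dataset$death_date
  end_date[!dead] <- dataset$last_seen_date[!dead]
  exit <- grid_age(dataset$birth_date, end_date)
  entry <- rep(105, n)

  events <- integer(J)
  exposures <- numeric(J)
  at_risk <- integer(J)
  death_bin <- findInterval(exit[dead], br, rightmost.closed = FALSE)
  death_bin <- death_bin[death_bin >= 1L & death_bin <= J]
  ev <- tabulate(death_bin, nbins = J)
  for (j in seq_len(J)) {
    lo <- br[j]; hi <- br[j + 1L]
    exposures[j] <- sum(pmax(0, pmin(exit, hi) - pmax(entry, lo)))
    at_risk[j] <- sum(exit > lo & entry <= lo)
  }
  structure(list(grid = grid, events = as.integer(ev),
                 exposures = exposures, at_risk = at_risk, n = n),
            class = "interval_counts")
}

#' @export
print.interval_counts <- function(x, ...) {
  cat(sprintf("<interval_counts> %d record(s), %d event(s) on the grid\n",
              x$n, sum(x$events)))
  print(data.frame(age_start = grid_breaks(x$grid)[-(x$grid$J + 1L)],
                   events = x$events,
                   exposure_py = round(x$exposures, 2),
                   at_risk = x$at_risk))
  invisible(x)
}

#' Central death rates per age interval
#'
#' The non-parametric estimate of the risk of dying: within each interval,
#' deaths divided by person-years of exposure. With a small interval length
#' this occurrence/exposure rate is a quasi-continuous estimate of the
#' hazard \eqn{\mu(x)}. Intervals with zero exposure have no estimate and
#' are `NA`, not zero.
#'
#' @param counts an `interval_counts` object from
#'   [compute_events_exposures()].
#' @return a `hazard_estimate` object: list with `grid`, `rates` (per year),
#'   `events`, `exposures`, `at_risk`, `n_total`.
#' @export
central_death_rates <- function(counts) {
  stopifnot(inherits(counts, "interval_counts"))
  rates <- ifelse(counts$exposures > 0, counts$events / counts$exposures,
                  NA_real_)
  structure(list(grid = counts$grid, rates = rates, events = counts$events,
                 exposures = counts$exposures, at_risk = counts$at_risk,
                 n_total = counts$n),
            class = "hazard_estimate")
}

#' @export
print.hazard_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("<hazard_estimate> %d record(s); delta = %g year(s)\n",
              x$n_total, x$grid$delta))
  print(data.frame(age_start = grid_breaks(x$grid)[-(x$grid$J + 1L)],
                   rate = round(x$rates, digits), at_risk = x$at_risk))
  invisible(x)
}

#' Cumulative death probabilities from interval rates
#'
#' Assuming the hazard is constant within each interval, the probability of
#' having died by the end of interval \eqn{x}, conditional on being alive at
#' the grid start, is
#' \eqn{{}_{\delta}q_x = 1 - \exp(-\sum_{i \le x} \delta \cdot {}_{\delta}M_i)}.
#' Trailing intervals with no estimate are dropped (the grid is truncated);
#' an undefined rate followed by a defined one is an error, because the
#' cumulation cannot skip an interval.
#'
#' @param estimate a `hazard_estimate` from [central_death_rates()].
#' @return a `cum_probs` object: list with (possibly truncated) `grid` and
#'   non-decreasing `q` in `[0, 1]`.
#' @export
cumulative_death_probabilities <- function(estimate) {
  stopifnot(inherits(estimate, "hazard_estimate"))
  rates <- estimate$rates
  defined <- !is.na(rates)
  J_use <- if (any(defined)) max(which(defined)) else 0L
  if (J_use == 0L) stop("no interval has a defined rate", call. = FALSE)
  if (any(!defined[seq_len(J_use)])) {
    stop("rate undefined in mid-grid interval(s) ",
         paste(which(!defined[seq_len(J_use)]), collapse = ", "),
         "; truncate the grid before the first gap", call. = FALSE)
  }
  grid <- estimate$grid
  if (J_use < grid$J) grid <- interval_grid(grid$start_age, grid$delta, J_use)
  q <- -expm1(-cumsum(grid$delta * rates[seq_len(J_use)]))
  structure(list(grid = grid, q = q), class = "cum_probs")
}

#' Back-transform cumulative death probabilities into rates
#'
#' Inverse of [cumulative_death_probabilities()]: the rate on interval
#' \eqn{x} is \eqn{-\log[(1 - q_x) / (1 - q_{x-\delta})] / \delta}, with
#' \eqn{q = 0} at the grid start. Once \eqn{q} reaches 1 (everyone has
#' died), rates are undefined from that interval onward and returned as
#' `NA`, with attribute `extinct = TRUE` on the result. Decreasing `q` is an
#' error.
#'
#' @param q a `cum_probs` object (or numeric vector of cumulative
#'   probabilities with `grid` supplied).
#' @param grid the [interval_grid()] when `q` is a bare numeric vector.
#' @return a `hazard_estimate` with the recovered `rates` (counts fields
#'   `NA`).
#' @export
rates_from_probabilities <- function(q, grid = NULL) {
  if (inherits(q, "cum_probs")) {
    grid <- q$grid
    q <- q$q
  }
  stopifnot(inherits(grid, "interval_grid"), length(q) == grid$J)
  if (any(q < 0 | q > 1)) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  if (any(diff(c(0, q)) < 0)) {
    stop("cumulative probabilities must be non-decreasing", call. = FALSE)
  }
  log_surv <- log1p(-c(0, q)) # log S is better conditioned than S near q = 1
  rates <- -diff(log_surv) / grid$delta
  extinct <- q >= 1
  rates[extinct] <- NA_real_
  structure(list(grid = grid, rates = rates,
                 events = rep(NA_integer_, grid$J),
                 exposures = rep(NA_real_, grid$J),
                 at_risk = rep(NA_integer_, grid$J),
                 n_total = NA_integer_),
            class = "hazard_estimate", extinct = any(extinct))
}
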