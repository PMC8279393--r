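#' Simulate one replicate set of death probabilities
#'
#' Draws `n` individuals whose interval of death follows the per-interval
#' death probabilities implied by `q` (first differences of the cumulative
#' probabilities; the remaining mass survives past the grid) and returns the
#' replicate's empirical cumulative death proportions on the same grid. This
#' is the building block of the simulation-based empirical confidence
#' intervals.
#'
#' @param q a `cum_probs` object from [cumulative_death_probabilities()].
#' @param n number of simulated individuals.
#' @return a `cum_probs` object with the replicate's empirical proportions.
#' @export
simulate_replicate <- function(q, n) {
  stopifnot(inherits(q, "cum_probs"), n >= 1)
  qhat <- replicate_q_matrix(q$q, n, 1L)[, 1L]
  structure(list(grid = q$grid, q = qhat), class = "cum_probs")
}

# J x R matrix of empirical cumulative death proportions: each column one
# replicate of n individuals multinomially assigned to the J death intervals
# or to survival past the grid.
replicate_q_matrix <- function(q, n, R) {
  p <- diff(c(0, q))
  p_beyond <- 1 - q[length(q)]
  counts <- stats::rmultinom(R, n, c(p, p_beyond))
  J <- length(q)
  deaths <- counts[seq_len(J), , drop = FALSE]
  apply(deaths, 2L, cumsum) / n
}

#' Simulation-based empirical confidence intervals for interval rates
#'
#' The percentile procedure for uncertainty around the non-parametric rate
#' trajectory: the estimated rates are transformed to cumulative death
#' probabilities, `replicates` cohorts of `n` individuals are simulated from
#' those probabilities, each replicate's empirical probabilities are
#' back-transformed to rates, and the per-interval band is the empirical
#' (1-level)/2 and 1-(1-level)/2 quantiles across replicates. Standard
#' CLT-based intervals are avoided because observations at the highest ages
#' are scarce.
#'
#' In a replicate where all `n` simulated individuals have died before an
#' interval, the rate there is undefined; such replicates are excluded from
#' that interval's percentiles. `n_defined` reports how many replicates
#' contributed per interval, and bands are suppressed (`NA`) where fewer
#' than half did. Individuals surviving past the grid are censored at the
#' grid end, exactly as in the observed-data transform.
#'
#' @param estimate a `hazard_estimate` from [central_death_rates()] with a
#'   defined first-interval rate.
#' @param n simulated individuals per replicate; defaults to the number of
#'   records behind `estimate`, matching the observed cohort size.
#' @param replicates number of replicate cohorts (default 10000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed optional integer seed for the simulation stream.
#' @return a `ci_bands` object: list with `grid` (truncated to the defined
#'   rates), `lower`, `upper` (rates per year), `n_defined`, `replicates`,
#'   `level`, `n`.
#' @export
empirical_ci <- function(estimate, n = estimate$n_total, replicates = 10000L,
                         level = 0.95, seed = NULL) {
  stopifnot(inherits(estimate, "hazard_estimate"),
            replicates >= 1, level > 0, level < 1)
  if (is.na(n) || n < 1) {
    stop("`n` (simulated individuals per replicate) must be a positive count",
         call. = FALSE)
  }
  if (is.na(estimate$rates[1L])) {
    stop("rate undefined at the first interval; nothing to simulate from",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  qobs <- cumulative_death_probabilities(estimate)
  qmat <- replicate_q_matrix(qobs$q, n, replicates)
  bands <- rate_percentile_bands(qmat, qobs$grid, level)
  structure(c(list(grid = qobs$grid), bands,
              list(replicates = as.integer(replicates), level = level,
                   n = as.integer(n))),
            class = "ci_bands")
}

# Back-transform each replicate column of cumulative proportions to rates
# and take per-interval percentile bands over the replicates with a defined
# rate. Suppresses intervals where fewer than `floor_frac` of the columns
# have one.
rate_percentile_bands <- function(qmat, grid, level, floor_frac = 0.5) {
  delta <- grid$delta
  surv <- 1 - rbind(0, qmat)
  J <- grid$J
  rates <- -log(surv[-1L, , drop = FALSE] /
                  surv[-(J + 1L), , drop = FALSE]) / delta
  rates[surv[-1L, , drop = FALSE] <= 0] <- NA_real_
  n_defined <- as.integer(rowSums(!is.na(rates)))
  alpha <- (1 - level) / 2
  lower <- upper <- rep(NA_real_, J)
  R <- ncol(qmat)
  for (j in seq_len(J)) {
    rj <- rates[j, ]
    rj <- rj[!is.na(rj)]
    if (length(rj) >= max(1L, floor_frac * R)) {
      qs <- stats::quantile(rj, c(alpha, 1 - alpha), names = FALSE, type = 7)
      lower[j] <- qs[1L]
      upper[j] <- qs[2L]
    }
  }
  list(lower = lower, upper = upper, n_defined = n_defined)
}

#' @export
print.ci_bands <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<ci_bands> %g%% empirical bands; %d replicate(s) of n = %d\n",
    100 * x$level, x$replicates, x$n))
  print(data.frame(age_start = grid_breaks(x$grid)[-(x$grid$J + 1L)],
                   lower = round(x$lower, digits),
                   upper = round(x$upper, digits),
                   n_defined = x$n_defined))
  invisible(x)
}
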