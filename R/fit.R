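#' Fit the non-parametric risk-of-dying trajectory above age 105
#'
#' The package's central fitting function. Given individual longevity
#' records, it tallies deaths and person-years on a grid of short age
#' intervals, estimates the central death rate in each (a quasi-continuous,
#' fully non-parametric estimate of the hazard \eqn{\mu(x)}), and attaches
#' simulation-based empirical confidence intervals. Datasets made up
#' entirely of interval-censored (US-style) records are routed through the
#' bounds-based multiple imputation of birth dates
#' ([run_imputed_estimation()]); mixing interval-censored records with other
#' schemes in one fit is not supported — analyse such populations
#' separately, as registries report them.
#'
#' @param data a [longevity_records] data.frame (or a plain data.frame with
#'   the same columns).
#' @param sex optional `"F"` or `"M"` to restrict the fit; `NULL` pools the
#'   sexes.
#' @param delta age-interval length in years (default 0.5, i.e. six months).
#' @param age_min,age_max grid span in years (defaults 105-113; estimates
#'   past 113 rest on very few survivors).
#' @param min_at_risk reporting threshold: rates and bands at intervals with
#'   fewer individuals at risk are suppressed in printed and exported
#'   output (default 10).
#' @param conf compute empirical confidence bands (default `TRUE`).
#' @param replicates replicate cohorts for the bands (default 10000); for
#'   interval-censored data, the per-round `k`.
#' @param level confidence level (default 0.95).
#' @param m imputation rounds for interval-censored data (default 1000).
#' @param seed optional integer seed covering all simulation in the fit.
#' @return an object of class `plateau_hazard`; see
#'   [as.data.frame.plateau_hazard()], [coef.plateau_hazard()],
#'   [confint.plateau_hazard()], [plot.plateau_hazard()].
#' @examples
#' pop <- simulate_population(cohort_config(2000, seed = 42))
#' fit <- plateau_hazard(pop, sex = "F", replicates = 200, seed = 1)
#' fit
#' coef(fit)
#' @export
plateau_hazard <- function(data, sex = NULL, delta = 0.5, age_min = 105,
                           age_max = 113, min_at_risk = 10, conf = TRUE,
                           replicates = 10000L, level = 0.95, m = 1000L,
                           seed = NULL) {
  if (!inherits(data, "longevity_records")) {
    data <- longevity_records(data)
  }
  stopifnot(delta > 0, age_max > age_min, age_min >= 105)
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("F", "M"))
    keep <- data$sex == sex
    data <- structure(data[keep, , drop = FALSE],
                      label = attr(data, "label"),
                      class = class(data))
  }
  J <- round((age_max - age_min) / delta)
  if (abs(J * delta - (age_max - age_min)) > 1e-9) {
    stop("`age_max - age_min` must be a whole number of intervals",
         call. = FALSE)
  }
  grid <- interval_grid(age_min, delta, J)
  if (nrow(data) == 0L) {
    warning("no records after filtering; returning an empty fit",
            call. = FALSE)
    est <- central_death_rates(compute_events_exposures(data, grid))
    return(new_plateau_hazard(est, NULL, data, sex, min_at_risk, level))
  }
  if (!is.null(seed)) set.seed(seed)
  ic <- data$scheme == "INTERVAL_CENSORED_YEARS"
  if (any(ic) && !all(ic)) {
    stop("cannot mix interval-censored records with other schemes in one ",
         "fit; analyse them as a separate population", call. = FALSE)
  }
  if (all(ic)) {
    res <- run_imputed_estimation(data, grid, m = m, k = replicates,
                                  level = level)
    return(new_plateau_hazard(res$estimate, if (conf) res$ci else NULL,
                              data, sex, min_at_risk, level,
                              imputed = TRUE, m = m, k = replicates))
  }
  est <- central_death_rates(compute_events_exposures(data, grid))
  ci <- NULL
  if (conf && !is.na(est$rates[1L])) {
    ci <- empirical_ci(est, n = est$n_total, replicates = replicates,
                       level = level)
  }
  new_plateau_hazard(est, ci, data, sex, min_at_risk, level)
}

new_plateau_hazard <- function(estimate, ci, data, sex, min_at_risk, level,
                               imputed = FALSE, m = NA_integer_,
                               k = NA_integer_) {
  structure(list(estimate = estimate, ci = ci,
                 grid = estimate$grid,
                 n = estimate$n_total,
                 label = attr(data, "label"), sex = sex,
                 min_at_risk = min_at_risk, level = level,
                 imputed = imputed, m = m, k = k,
                 call = sys.call(-1L)),
            class = "plateau_hazard")
}

#' Tabulate a fitted risk-of-dying trajectory
#'
#' One row per age interval: `age_start`, `age_end`, `events`,
#' `exposure_py` (person-years), `at_risk`, `rate` (per year) and, when
#' bands were computed, `ci_lower`, `ci_upper`, `n_defined`. Rates and bands
#' at intervals with fewer than `min_at_risk` individuals at risk are
#' suppressed (`NA`); the counts remain visible so the scarcity is evident.
#'
#' @param x a `plateau_hazard` fit.
#' @param row.names,optional ignored (present for the generic).
#' @param suppress apply the `min_at_risk` reporting rule (default `TRUE`).
#' @param ... ignored.
#' @return a data.frame.
#' @export
as.data.frame.plateau_hazard <- function(x, row.names = NULL,
                                         optional = FALSE,
                                         suppress = TRUE, ...) {
  est <- x$estimate
  br <- grid_breaks(est$grid)
  J <- est$grid$J
  out <- data.frame(age_start = br[-(J + 1L)], age_end = br[-1L],
                    events = est$events, exposure_py = est$exposures,
                    at_risk = est$at_risk, rate = est$rates)
  if (!is.null(x$ci)) {
    ciJ <- x$ci$grid$J
    out$ci_lower <- c(x$ci$lower, rep(NA_real_, J - ciJ))
    out$ci_upper <- c(x$ci$upper, rep(NA_real_, J - ciJ))
    out$n_defined <- c(x$ci$n_defined, rep(NA_integer_, J - ciJ))
  }
  if (suppress) {
    low <- !is.na(out$at_risk) & out$at_risk < x$min_at_risk
    out$rate[low] <- NA_real_
    if (!is.null(x$ci)) {
      out$ci_lower[low] <- NA_real_
      out$ci_upper[low] <- NA_real_
    }
  }
  out
}

#' @export
print.plateau_hazard <- function(x, digits = 3, ...) {
  cat("Non-parametric risk of dying above age", x$grid$start_age, "\n")
  cat(sprintf("  population: %s%s, n = %d record(s)\n",
              x$label, if (!is.null(x$sex)) paste0(" (", x$sex, ")") else "",
              x$n))
  if (x$imputed) {
    cat(sprintf("  interval-censored data: %d imputation round(s) x %d replicate(s)\n",
                x$m, x$k))
  }
  cat(sprintf("  grid: delta = %g year(s), ages %g-%g\n", x$grid$delta,
              x$grid$start_age, x$grid$start_age + x$grid$J * x$grid$delta))
  tab <- as.data.frame(x)
  tab$exposure_py <- round(tab$exposure_py, 1)
  num <- intersect(c("rate", "ci_lower", "ci_upper"), names(tab))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  if (any(!is.na(tab$at_risk) & tab$at_risk < x$min_at_risk)) {
    cat(sprintf("  (rates suppressed where fewer than %d at risk)\n",
                x$min_at_risk))
  }
  invisible(x)
}

#' @export
summary.plateau_hazard <- function(object, ...) {
  tab <- as.data.frame(object)
  structure(list(fit = object, table = tab,
                 total_events = sum(tab$events, na.rm = TRUE),
                 total_exposure = sum(tab$exposure_py, na.rm = TRUE)),
            class = "summary.plateau_hazard")
}

#' @export
print.summary.plateau_hazard <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  totals: %d death(s), %.1f person-year(s) on the grid\n",
              x$total_events, x$total_exposure))
  invisible(x)
}

#' Extract interval death rates from a fit
#'
#' @param object a `plateau_hazard` fit.
#' @param suppress apply the `min_at_risk` reporting rule (default `TRUE`).
#' @param ... ignored.
#' @return named numeric vector of rates per year; names are the interval
#'   start ages.
#' @export
coef.plateau_hazard <- function(object, suppress = TRUE, ...) {
  tab <- as.data.frame(object, suppress = suppress)
  stats::setNames(tab$rate, format(tab$age_start))
}

#' Confidence bands of a fitted trajectory
#'
#' Returns the empirical confidence bands computed at fit time, or computes
#' them on demand (for non-imputed fits) when the fit was made with
#' `conf = FALSE` or a different level is requested.
#'
#' @param object a `plateau_hazard` fit.
#' @param parm ignored (present for the generic).
#' @param level confidence level; defaults to the fit's.
#' @param ... passed to [empirical_ci()] when bands must be recomputed.
#' @return a data.frame with `age_start`, `lower`, `upper`, `n_defined`.
#' @export
confint.plateau_hazard <- function(object, parm = NULL,
                                   level = object$level, ...) {
  ci <- object$ci
  if (is.null(ci) || level != object$level) {
    if (object$imputed) {
      stop("bands for imputed fits are computed at fit time; refit with ",
           "`conf = TRUE`", call. = FALSE)
    }
    ci <- empirical_ci(object$estimate, n = object$n, level = level, ...)
  }
  br <- grid_breaks(ci$grid)
  data.frame(age_start = br[-(ci$grid$J + 1L)], lower = ci$lower,
             upper = ci$upper, n_defined = ci$n_defined)
}

#' Plot a fitted risk-of-dying trajectory
#'
#' Step plot of the interval rates with the empirical confidence band as a
#' shaded ribbon, the standard display for occurrence/exposure rates at
#' extreme ages. Suppressed intervals (below `min_at_risk`) are omitted.
#'
#' @param x a `plateau_hazard` fit.
#' @param ylim y-axis limits; defaults to covering the band.
#' @param col line colour.
#' @param band_col band fill colour.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.plateau_hazard <- function(x, ylim = NULL, col = "firebrick",
                                band_col = grDevices::adjustcolor(col, 0.2),
                                ...) {
  tab <- as.data.frame(x)
  has_ci <- !is.null(x$ci)
  if (all(is.na(tab$rate))) stop("nothing to plot: all rates suppressed",
                                 call. = FALSE)
  if (is.null(ylim)) {
    hi <- if (has_ci) max(tab$ci_upper, tab$rate, na.rm = TRUE)
          else max(tab$rate, na.rm = TRUE)
    ylim <- c(0, 1.05 * hi)
  }
  mid <- (tab$age_start + tab$age_end) / 2
  graphics::plot(mid, tab$rate, type = "n", ylim = ylim,
                 xlab = "age (years)", ylab = "risk of dying (per year)",
                 ...)
  if (has_ci) {
    ok <- !is.na(tab$ci_lower) & !is.na(tab$ci_upper)
    if (any(ok)) {
      graphics::polygon(c(mid[ok], rev(mid[ok])),
                        c(tab$ci_lower[ok], rev(tab$ci_upper[ok])),
                        col = band_col, border = NA)
    }
  }
  ok <- !is.na(tab$rate)
  graphics::segments(tab$age_start[ok], tab$rate[ok], tab$age_end[ok],
                     tab$rate[ok], col = col, lwd = 2)
  graphics::points(mid[ok], tab$rate[ok], pch = 16, col = col)
  invisible(x)
}
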