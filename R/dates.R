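#' Advance a calendar date by whole years
#'
#' Adds `years` calendar years to a date, keeping month and day. A February 29
#' anniversary falls on February 28 in non-leap years (the common civil
#' convention). Dates are proleptic Gregorian, as in base R's [Date] class.
#'
#' @param date a `Date` vector.
#' @param years integer vector of whole years to add (may be negative);
#'   recycled against `date`.
#' @return a `Date` vector.
#' @examples
#' add_years(as.Date("1900-01-01"), 105)
#' add_years(as.Date("1896-02-29"), 1) # -> 1897-02-28
#' @export
add_years <- function(date, years) {
  stopifnot(inherits(date, "Date"))
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L + as.integer(years)
  m <- lt$mon + 1L
  d <- lt$mday
  out <- as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d")
  # only Feb 29 -> non-leap year can fail to parse
  bad <- is.na(out) & !is.na(date)
  if (any(bad)) out[bad] <- as.Date(sprintf("%04d-02-28", y[bad]))
  out
}

#' Exact age in whole years and remaining days
#'
#' The exact age at `event_date` of someone born on `birth_date`: the largest
#' number of whole calendar years `y` such that the `y`-th birthday is on or
#' before `event_date`, plus the day count from that birthday to `event_date`.
#' This is the convention in which an age of "109 years and 200 days" means
#' the 109th birthday plus 200 days.
#'
#' @param birth_date,event_date `Date` vectors (recycled to a common length);
#'   `event_date` must be strictly after `birth_date`.
#' @return a data.frame with integer columns `years` and `days`
#'   (0 <= days < 366).
#' @examples
#' exact_age(as.Date("1900-01-01"), as.Date("2010-01-21")) # 110 years, 20 days
#' @export
exact_age <- function(birth_date, event_date) {
  stopifnot(inherits(birth_date, "Date"), inherits(event_date, "Date"))
  n <- max(length(birth_date), length(event_date))
  birth_date <- rep_len(birth_date, n)
  event_date <- rep_len(event_date, n)
  if (any(event_date <= birth_date)) {
    stop("`event_date` must be strictly after `birth_date`", call. = FALSE)
  }
  # initial guess from calendar years, then correct by at most one
  yb <- as.POSIXlt(birth_date)$year
  ye <- as.POSIXlt(event_date)$year
  y <- ye - yb
  anniv <- add_years(birth_date, y)
  over <- anniv > event_date
  if (any(over)) {
    y[over] <- y[over] - 1L
    anniv[over] <- add_years(birth_date[over], y[over])
  }
  data.frame(years = as.integer(y),
             days = as.integer(event_date - anniv))
}

#' Age in decimal years
#'
#' Elapsed time between two dates expressed in years of 365.25 days. This is
#' the package's day-count convention for continuous ages; see also
#' [exact_age()] for the calendar (whole years + days) convention.
#'
#' @inheritParams exact_age
#' @return numeric vector of decimal years.
#' @export
decimal_age_years <- function(birth_date, event_date) {
  stopifnot(inherits(birth_date, "Date"), inherits(event_date, "Date"))
  if (any(event_date <= birth_date)) {
    stop("`event_date` must be strictly after `birth_date`", call. = FALSE)
  }
  as.numeric(event_date - birth_date) / 365.25
}

# Age on the analysis grid: exactly 105 at the 105th birthday, then days
# lived past that birthday counted at 365.25 days/year. Keeps entry into the
# left-truncated cohort at exactly 105.0 regardless of leap-year layout.
grid_age <- function(birth_date, event_date) {
  b105 <- add_years(birth_date, 105L)
  if (any(event_date < b105)) {
    stop("event before the 105th birthday", call. = FALSE)
  }
  105 + as.numeric(event_date - b105) / 365.25
}
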