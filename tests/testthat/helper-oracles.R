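# Independent oracles and fixture builders shared across the tests.
# Everything here is deliberately brute-force and separate from the code
# paths it checks.

# Build a fully observed / right-censored dataset directly from lifespans
# (in years past the 105th birthday). Censored records get a last-seen time
# uniform on [0, lifespan].
make_records <- function(lifespans, censored = rep(FALSE, length(lifespans)),
                         sex = rep("F", length(lifespans)),
                         birth_start = as.Date("1880-01-01"),
                         label = "test") {
  n <- length(lifespans)
  birth <- birth_start + sample.int(3650L, n, replace = TRUE) - 1L
  b105 <- add_years(birth, 105L)
  days <- floor(lifespans * 365.25)
  death <- b105 + days
  last_seen <- as.Date(rep(NA_real_, n))
  if (any(censored)) {
    u <- floor(runif(sum(censored)) * (days[censored] + 1L))
    last_seen[censored] <- b105[censored] + u
  }
  df <- data.frame(
    id = sprintf("t%05d", seq_len(n)), country = label, sex = sex,
    birth_date = birth,
    death_date = as.Date(ifelse(censored, NA, death)),
    last_seen_date = last_seen,
    birth_year = NA_integer_, death_year = NA_integer_,
    age_years = NA_integer_, age_days = NA_integer_,
    scheme = ifelse(censored, "RIGHT_CENSORED", "FULLY_OBSERVED"),
    stringsAsFactors = FALSE)
  longevity_records(df, label = label)
}

# Daily-step Lexis oracle for ONE record: walks the life day by day from the
# 105th birthday to exit, binning each day's 1/365.25 person-years into the
# age interval containing the day's start, and the death (if any) into the
# interval containing the exact exit age.
lexis_oracle_record <- function(birth, end_date, dead, grid) {
  br <- longevhaz:::grid_breaks(grid)
  J <- grid$J
  b105 <- add_years(birth, 105L)
  days <- as.integer(end_date - b105)
  expo <- numeric(J)
  if (days > 0) {
    day_age <- 105 + (seq_len(days) - 1L) / 365.25
    bin <- findInterval(day_age, br)
    ok <- bin >= 1L & bin <= J
    expo <- tabulate(bin[ok], nbins = J) / 365.25
  }
  events <- integer(J)
  if (dead) {
    exit_age <- 105 + days / 365.25
    bin <- findInterval(exit_age, br)
    if (bin >= 1L && bin <= J) events[bin] <- 1L
  }
  list(events = events, exposures = expo)
}

# Brute-force birth-bounds oracle: try every day of the birth year and keep
# those whose implied death date falls in the recorded death year.
bounds_oracle <- function(birth_year, death_year, age_years, age_days) {
  start <- as.Date(sprintf("%04d-01-01", birth_year))
  end <- as.Date(sprintf("%04d-12-31", birth_year))
  days <- seq(start, end, by = "day")
  death <- add_years(days, age_years) + age_days
  ok <- format(death, "%Y") == sprintf("%04d", death_year)
  if (!any(ok)) return(NULL)
  list(earliest = min(days[ok]), latest = max(days[ok]))
}

# Closed-form survival past 105 implied by a hazard_spec, S(t).
spec_survival <- function(spec, t) {
  exp(-longevhaz:::cumulative_hazard(spec, t))
}
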