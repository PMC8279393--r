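#' Configuration of a synthetic semi-supercentenarian cohort
#'
#' Describes an IDL-like population of individuals who all survived to age
#' 105: cohort size, birth-cohort range, sex composition, one ground-truth
#' hazard regime per sex, and the mix of observation schemes. Defaults
#' emulate the structure of large national series in longevity registries:
#' birth cohorts 1870-1912, 90% female, a constant mortality plateau of
#' 0.7/year for both sexes, and a record mix dominated by fully observed
#' cases (85% fully observed, 10% right-censored, 5% interval-censored).
#'
#' @param n number of individuals (>= 1).
#' @param birth_year_range integer `c(first, last)` birth years.
#' @param proportion_female fraction of females in `[0, 1]`.
#' @param hazard_female,hazard_male [hazard_spec][hazard_const] objects.
#' @param scheme_mix named numeric vector of proportions over
#'   `FULLY_OBSERVED`, `RIGHT_CENSORED`, `INTERVAL_CENSORED_YEARS`, summing
#'   to 1.
#' @param sampling_window optional `c(start, end)` `Date` pair; individuals
#'   whose death (or last-seen) date falls outside it are excluded,
#'   emulating right truncation by a registry's collection window.
#' @param seed integer seed for the cohort's random stream, or `NULL` to use
#'   the current RNG state.
#' @return a `cohort_config` list.
#' @seealso [simulate_population()]
#' @export
cohort_config <- function(n,
                          birth_year_range = c(1870L, 1912L),
                          proportion_female = 0.9,
                          hazard_female = hazard_const(0.7),
                          hazard_male = hazard_const(0.7),
                          scheme_mix = c(FULLY_OBSERVED = 0.85,
                                         RIGHT_CENSORED = 0.10,
                                         INTERVAL_CENSORED_YEARS = 0.05),
                          sampling_window = NULL,
                          seed = NULL) {
  stopifnot(n >= 1, length(birth_year_range) == 2L,
            birth_year_range[1] <= birth_year_range[2],
            proportion_female >= 0, proportion_female <= 1,
            inherits(hazard_female, "hazard_spec"),
            inherits(hazard_male, "hazard_spec"))
  if (!all(obs_schemes() %in% names(scheme_mix))) {
    stop("`scheme_mix` must be named with the three scheme tags",
         call. = FALSE)
  }
  scheme_mix <- scheme_mix[obs_schemes()]
  if (any(scheme_mix < 0) || abs(sum(scheme_mix) - 1) > 1e-12) {
    stop("`scheme_mix` proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!is.null(sampling_window)) {
    sampling_window <- as.Date(sampling_window)
    stopifnot(length(sampling_window) == 2L,
              sampling_window[1] < sampling_window[2])
  }
  structure(list(n = as.integer(n),
                 birth_year_range = as.integer(birth_year_range),
                 proportion_female = proportion_female,
                 hazard_female = hazard_female,
                 hazard_male = hazard_male,
                 scheme_mix = scheme_mix,
                 sampling_window = sampling_window,
                 seed = seed),
            class = "cohort_config")
}

#' Simulate an IDL-like population with known ground truth
#'
#' Generates `config$n` individuals: a uniform birth date within a uniform
#' birth year, sex by `proportion_female`, and a lifespan past the 105th
#' birthday drawn from the sex's hazard regime by inverse transform. Each
#' individual is then assigned an observation scheme from `scheme_mix`:
#' fully observed records keep their death date; right-censored records
#' replace it with a last-seen date uniform between the 105th birthday and
#' death; interval-censored records are degraded with
#' [degrade_to_interval_censored()]. If a `sampling_window` is set,
#' individuals whose death (or last-seen) date falls outside it are dropped
#' (right truncation as a registry's collection window would impose it; the
#' estimator itself applies no truncation correction).
#'
#' @param config a [cohort_config()].
#' @param label population label for the resulting dataset.
#' @return a [longevity_records] data.frame.
#' @examples
#' pop <- simulate_population(cohort_config(200, seed = 1))
#' table(pop$scheme)
#' @export
simulate_population <- function(config, label = "synthetic") {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  yr <- config$birth_year_range
  birth_year <- sample(seq(yr[1], yr[2]), n, replace = TRUE)
  jan1 <- as.Date(sprintf("%04d-01-01", birth_year))
  year_len <- as.numeric(as.Date(sprintf("%04d-01-01", birth_year + 1L)) - jan1)
  birth <- jan1 + floor(stats::runif(n) * year_len)
  sex <- ifelse(stats::runif(n) < config$proportion_female, "F", "M")
  lifespan <- numeric(n)
  for (s in c("F", "M")) {
    idx <- which(sex == s)
    spec <- if (s == "F") config$hazard_female else config$hazard_male
    if (length(idx)) lifespan[idx] <- sample_lifespan(spec, length(idx))
  }
  b105 <- add_years(birth, 105L)
  days_past <- floor(lifespan * 365.25)
  death <- b105 + days_past
  scheme <- sample(obs_schemes(), n, replace = TRUE,
                   prob = config$scheme_mix)

  df <- data.frame(id = sprintf("%s-%05d", label, seq_len(n)),
                   country = label, sex = sex,
                   birth_date = birth, death_date = death,
                   last_seen_date = as.Date(NA),
                   birth_year = NA_integer_, death_year = NA_integer_,
                   age_years = NA_integer_, age_days = NA_integer_,
                   scheme = "FULLY_OBSERVED",
                   stringsAsFactors = FALSE)

  rc <- which(scheme == "RIGHT_CENSORED")
  if (length(rc)) {
    seen <- b105[rc] + floor(stats::runif(length(rc)) * (days_past[rc] + 1))
    df$last_seen_date[rc] <- seen
    df$death_date[rc] <- as.Date(NA)
    df$scheme[rc] <- "RIGHT_CENSORED"
  }

  if (!is.null(config$sampling_window)) {
    event <- df$death_date
    event[rc] <- df$last_seen_date[rc]
    keep <- event >= config$sampling_window[1] &
      event <= config$sampling_window[2]
    df <- df[keep, , drop = FALSE]
    scheme <- scheme[keep]
    if (!nrow(df)) {
      warning("sampling window excludes every simulated individual",
              call. = FALSE)
    }
  }

  out <- longevity_records(df, label = label)
  ic <- which(scheme == "INTERVAL_CENSORED_YEARS")
  if (length(ic)) out <- degrade_to_interval_censored(out, rows = ic)
  out
}

#' Degrade fully observed records to US-style interval censoring
#'
#' Replaces exact birth and death dates with the year of birth, year of
#' death, and the exact age at death in whole years and days — the form in
#' which US records are released. The inverse problem (recovering plausible
#' birth dates from this triple) is handled by [birth_bounds()] and
#' [impute_birth()].
#'
#' @param dataset a [longevity_records] data.frame.
#' @param rows indices of the records to degrade (default: all). All
#'   selected records must be `FULLY_OBSERVED`.
#' @return the dataset with the selected records interval-censored.
#' @export
degrade_to_interval_censored <- function(dataset, rows = seq_len(nrow(dataset))) {
  stopifnot(inherits(dataset, "longevity_records"))
  if (!length(rows)) return(dataset)
  if (any(dataset$scheme[rows] != "FULLY_OBSERVED")) {
    stop("only FULLY_OBSERVED records can be interval-censored", call. = FALSE)
  }
  df <- as.data.frame(dataset)
  age <- exact_age(df$birth_date[rows], df$death_date[rows])
  df$birth_year[rows] <- as.integer(format(df$birth_date[rows], "%Y"))
  df$death_year[rows] <- as.integer(format(df$death_date[rows], "%Y"))
  df$age_years[rows] <- age$years
  df$age_days[rows] <- age$days
  df$birth_date[rows] <- as.Date(NA)
  df$death_date[rows] <- as.Date(NA)
  df$scheme[rows] <- "INTERVAL_CENSORED_YEARS"
  longevity_records(df, label = attr(dataset, "label"))
}
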