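#' @title Individual longevity records
#'
#' @description
#' The unit of analysis is one validated individual who survived to age 105
#' (the cohort is left-truncated at 105). A record is observed under one of
#' three schemes, mirroring how longevity registries such as the IDL report
#' their cases:
#'
#' * `FULLY_OBSERVED` — exact dates of birth and death are known.
#' * `RIGHT_CENSORED` — exact birth date and a last-seen-alive date are known;
#'   the death date is not.
#' * `INTERVAL_CENSORED_YEARS` — only the years of birth and death plus the
#'   exact age at death in whole years and days are known (US-style records,
#'   where exact dates are withheld for confidentiality).
#'
#' A `longevity_records` object is a data.frame with columns `id`, `country`,
#' `sex` (`"F"`/`"M"`), `birth_date`, `death_date`, `last_seen_date` (Date,
#' `NA` when absent), `birth_year`, `death_year`, `age_years`, `age_days`
#' (integer, `NA` when absent) and `scheme`, plus a `label` attribute naming
#' the population. Fields present or absent must match the scheme exactly.
#'
#' @param data a data.frame with the columns above (date columns may be ISO
#'   8601 strings).
#' @param label population label (country/region name).
#' @return a validated `longevity_records` data.frame.
#' @seealso [read_records()], [write_records()], [simulate_population()]
#' @export
longevity_records <- function(data, label = "population") {
  cols <- c("id", "country", "sex", "birth_date", "death_date",
            "last_seen_date", "birth_year", "death_year", "age_years",
            "age_days", "scheme")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(data)[cols]
  for (col in c("id", "country", "sex", "scheme")) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c("birth_date", "death_date", "last_seen_date")) {
    df[[col]] <- parse_iso_date(df[[col]], col)
  }
  for (col in c("birth_year", "death_year", "age_years", "age_days")) {
    df[[col]] <- parse_int(df[[col]], col)
  }
  rownames(df) <- NULL
  validate_records(df)
  structure(df, label = label,
            class = c("longevity_records", "data.frame"))
}

#' @export
print.longevity_records <- function(x, ...) {
  cat(sprintf("<longevity_records> %s: %d record(s)\n",
              attr(x, "label"), nrow(x)))
  tab <- table(scheme = x$scheme, sex = x$sex)
  if (nrow(x)) print(tab)
  invisible(x)
}

obs_schemes <- function() {
  c("FULLY_OBSERVED", "RIGHT_CENSORED", "INTERVAL_CENSORED_YEARS")
}

parse_iso_date <- function(x, field) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  out <- as.Date(rep(NA_real_, length(x)))
  ok <- !is.na(x)
  if (any(ok)) {
    if (!all(grepl("^\\d{4}-\\d{2}-\\d{2}$", x[ok]))) {
      bad <- which(ok & !grepl("^\\d{4}-\\d{2}-\\d{2}$", x))[1L]
      stop(sprintf("row %d: field '%s' is not an ISO 8601 date: '%s'",
                   bad, field, x[bad]), call. = FALSE)
    }
    parsed <- as.Date(x[ok], format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      bad <- which(ok)[which(is.na(parsed))[1L]]
      stop(sprintf("row %d: field '%s' is not a valid calendar date: '%s'",
                   bad, field, x[bad]), call. = FALSE)
    }
    out[ok] <- parsed
  }
  out
}

parse_int <- function(x, field) {
  if (is.character(x)) x[!is.na(x) & !nzchar(trimws(x))] <- NA
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("row %d: field '%s' is not an integer: '%s'",
                 bad[1L], field, as.character(x[bad[1L]])), call. = FALSE)
  }
  out
}

# Longest documented lifespan (122 years, 164 days); older ages are flagged.
MAX_PLAUSIBLE_AGE <- c(years = 122L, days = 164L)

req_err <- function(rows, field, what) {
  sprintf("row %d: field '%s' %s", rows, field, what)
}

#' Validate longevity records
#'
#' Checks every record against its observation scheme's requirements: the
#' right fields present and absent, dates ordered, and the left-truncation
#' condition (age at death or last observation at least 105). All violations
#' are collected and reported together; no partially valid record is kept.
#' Records at or beyond the longest documented human lifespan (122 years and
#' 164 days) are accepted but flagged with a warning.
#'
#' @param df a data.frame shaped as in [longevity_records()].
#' @return invisibly `TRUE`; stops with a per-row message otherwise.
#' @export
validate_records <- function(df) {
  errs <- character(0)
  if (anyDuplicated(df$id)) {
    dup <- df$id[duplicated(df$id)][1L]
    errs <- c(errs, sprintf("duplicated record id '%s'", dup))
  }
  bad_sex <- which(!df$sex %in% c("F", "M"))
  errs <- c(errs, req_err(bad_sex, "sex", "must be 'F' or 'M'"))
  bad_scheme <- which(!df$scheme %in% obs_schemes())
  errs <- c(errs, req_err(bad_scheme, "scheme", "is not a known scheme tag"))

  ok_scheme <- df$scheme %in% obs_schemes()
  need <- list(
    FULLY_OBSERVED = c("birth_date", "death_date"),
    RIGHT_CENSORED = c("birth_date", "last_seen_date"),
    INTERVAL_CENSORED_YEARS = c("birth_year", "death_year",
                                "age_years", "age_days")
  )
  all_fields <- c("birth_date", "death_date", "last_seen_date",
                  "birth_year", "death_year", "age_years", "age_days")
  for (sch in obs_schemes()) {
    rows <- which(ok_scheme & df$scheme == sch)
    if (!length(rows)) next
    for (f in need[[sch]]) {
      miss <- rows[is.na(df[[f]][rows])]
      errs <- c(errs, req_err(miss, f, sprintf("is required for %s", sch)))
    }
    for (f in setdiff(all_fields, need[[sch]])) {
      extra <- rows[!is.na(df[[f]][rows])]
      errs <- c(errs, req_err(extra, f, sprintf("must be absent for %s", sch)))
    }
  }
  if (length(errs)) {
    stop(paste(c("invalid longevity records:", errs), collapse = "\n  "),
         call. = FALSE)
  }

  # ordering + truncation checks (fields are now known present)
  age_flag <- logical(nrow(df))
  ic <- which(df$scheme == "INTERVAL_CENSORED_YEARS")
  if (length(ic)) {
    bad <- ic[df$age_days[ic] < 0L | df$age_days[ic] >= 366L]
    errs <- c(errs, req_err(bad, "age_days", "must be in [0, 365]"))
    bad <- ic[df$death_year[ic] < df$birth_year[ic]]
    errs <- c(errs, req_err(bad, "death_year", "precedes birth_year"))
    bad <- ic[df$age_years[ic] < 105L]
    errs <- c(errs, req_err(bad, "age_years", "is below 105"))
    age_flag[ic] <- df$age_years[ic] > MAX_PLAUSIBLE_AGE[["years"]] |
      (df$age_years[ic] == MAX_PLAUSIBLE_AGE[["years"]] &
         df$age_days[ic] >= MAX_PLAUSIBLE_AGE[["days"]])
  }
  for (sch in c("FULLY_OBSERVED", "RIGHT_CENSORED")) {
    rows <- which(df$scheme == sch)
    if (!length(rows)) next
    end_field <- if (sch == "FULLY_OBSERVED") "death_date" else "last_seen_date"
    end <- df[[end_field]][rows]
    not_after <- end <= df$birth_date[rows]
    errs <- c(errs, req_err(rows[not_after], end_field,
                            "is not after birth_date"))
    ok <- rows[!not_after]
    if (length(ok)) {
      age <- exact_age(df$birth_date[ok], df[[end_field]][ok])
      errs <- c(errs, req_err(ok[age$years < 105L], end_field,
                              "implies age below 105"))
      age_flag[ok] <- age$years > MAX_PLAUSIBLE_AGE[["years"]] |
        (age$years == MAX_PLAUSIBLE_AGE[["years"]] &
           age$days >= MAX_PLAUSIBLE_AGE[["days"]])
    }
  }
  if (length(errs)) {
    stop(paste(c("invalid longevity records:", errs), collapse = "\n  "),
         call. = FALSE)
  }
  if (any(age_flag)) {
    warning(sprintf(
      "record(s) %s at or beyond the longest documented lifespan (122 years, 164 days)",
      paste(df$id[age_flag], collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read longevity records from CSV
#'
#' Reads the package's CSV dialect: header required, comma-separated, UTF-8,
#' dates in ISO 8601 (`YYYY-MM-DD`), absent fields as empty strings. Columns:
#' `id, country, sex, birth_date, death_date, last_seen_date, birth_year,
#' death_year, age_years, age_days, scheme`. Every row is validated against
#' its observation scheme; the first offending row and field are named in the
#' error.
#'
#' @param path path to a CSV file.
#' @param label population label; defaults to the file name without extension.
#' @return a [longevity_records] data.frame.
#' @export
read_records <- function(path, label = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0), encoding = "UTF-8")
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  longevity_records(raw, label = label)
}

#' Write longevity records to CSV
#'
#' Inverse of [read_records()]: fixed column order, ISO 8601 dates, absent
#' fields serialized as empty strings. `read_records(write_records(x))` is
#' the identity field by field.
#'
#' @param dataset a [longevity_records] data.frame.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_records <- function(dataset, path) {
  stopifnot(inherits(dataset, "longevity_records"))
  out <- as.data.frame(dataset)
  for (col in c("birth_date", "death_date", "last_seen_date")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], "%Y-%m-%d"))
  }
  for (col in c("birth_year", "death_year", "age_years", "age_days")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", as.character(out[[col]]))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
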