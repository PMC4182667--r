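# Cohort table: column contract, eligibility filtering, random index dates and
# follow-up/censoring semantics for a primary-care style cohort.

# Required columns of a cohort table and their types. Dates are ISO-8601 in CSV,
# missing values are empty fields. `smoking`, `sbp`, `chol_hdl_ratio` and `bmi`
# may be missing (the imputation targets); `ethnicity` carries an explicit
# "unknown" level instead.
COHORT_COLUMNS <- c(
  person_id = "character", sex = "factor", birth_year = "integer",
  registration_start = "Date", data_end = "Date",
  temporary_registration = "logical",
  index_date = "Date", age_at_index = "numeric",
  ethnicity = "factor", deprivation_quintile = "integer",
  smoking = "factor", cigs_per_day = "factor",
  sbp = "numeric", chol_hdl_ratio = "numeric", bmi = "numeric",
  treated_hypertension = "logical", diabetes = "logical",
  atrial_fibrillation = "logical", chronic_renal_disease = "logical",
  rheumatoid_arthritis = "logical", lvh = "logical",
  family_history_chd = "logical", records_prior_year = "integer",
  statin_start = "Date", cvd_event_date = "Date", death_date = "Date",
  death_cause = "factor"
)

SEX_LEVELS <- c("male", "female")
ETHNICITY_LEVELS <- c("white", "black", "indian", "other", "unknown")
SMOKING_LEVELS <- c("never", "past", "current")
CIGS_LEVELS <- c("none", "1-10", "11-20", "21+")
DEATH_CAUSE_LEVELS <- c("none", "cvd", "other")
EVENT_LEVELS <- c("censored", "cvd", "death_other")

#' Validate a cohort table
#'
#' Checks the fixed column contract (names, types, factor levels) and basic
#' value constraints, coercing compatible columns. Unknown columns are kept but
#' flagged with a warning so schema drift is visible.
#'
#' @param x a data.frame with the cohort columns.
#' @return the validated cohort (class `cohort`, a data.frame).
#' @export
as_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(COHORT_COLUMNS), names(x))
  if (length(missing_cols) > 0)
    stop("cohort is missing required columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(x), names(COHORT_COLUMNS))
  if (length(extra) > 0)
    warning("cohort has unknown columns (kept as-is): ", paste(extra, collapse = ", "))

  x$person_id <- as.character(x$person_id)
  if (anyDuplicated(x$person_id)) stop("person_id values must be unique")
  for (col in names(COHORT_COLUMNS)[COHORT_COLUMNS == "Date"])
    x[[col]] <- as.Date(x[[col]])
  for (col in names(COHORT_COLUMNS)[COHORT_COLUMNS == "logical"])
    x[[col]] <- as.logical(x[[col]])
  for (col in names(COHORT_COLUMNS)[COHORT_COLUMNS == "numeric"])
    x[[col]] <- as.numeric(x[[col]])
  for (col in c("birth_year", "deprivation_quintile", "records_prior_year"))
    x[[col]] <- as.integer(x[[col]])

  x$sex <- factor(as.character(x$sex), levels = SEX_LEVELS)
  x$ethnicity <- factor(as.character(x$ethnicity), levels = ETHNICITY_LEVELS)
  x$smoking <- factor(as.character(x$smoking), levels = SMOKING_LEVELS)
  x$cigs_per_day <- factor(as.character(x$cigs_per_day), levels = CIGS_LEVELS)
  dc <- as.character(x$death_cause)
  dc[is.na(dc)] <- "none"
  x$death_cause <- factor(dc, levels = DEATH_CAUSE_LEVELS)

  if (any(is.na(x$sex))) stop("sex must be male or female")
  bad_dep <- !is.na(x$deprivation_quintile) &
    (x$deprivation_quintile < 1 | x$deprivation_quintile > 5)
  if (any(bad_dep)) stop("deprivation_quintile must be in 1..5")
  if (any(!is.na(x$records_prior_year) & x$records_prior_year < 0))
    stop("records_prior_year must be non-negative")

  class(x) <- c("cohort", "data.frame")
  x
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d persons (%d male, %d female)\n", nrow(x),
              sum(x$sex == "male"), sum(x$sex == "female")))
  cat(sprintf("  index dates %s .. %s\n",
              format(min(x$index_date)), format(max(x$index_date))))
  miss <- vapply(x[c("smoking", "sbp", "chol_hdl_ratio", "bmi")],
                 function(v) mean(is.na(v)), numeric(1))
  cat(sprintf("  missing: smoking %.1f%%, sbp %.1f%%, chol/HDL %.1f%%, bmi %.1f%%\n",
              100 * miss[1], 100 * miss[2], 100 * miss[3], 100 * miss[4]))
  invisible(x)
}

#' Read / write a cohort CSV
#'
#' ISO-8601 dates, empty fields for missing values, fixed column names.
#' `read_cohort` validates the schema via [as_cohort()] and warns on unknown
#' columns.
#'
#' @param path CSV file path.
#' @return `read_cohort`: a validated `cohort`.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  as_cohort(x)
}

#' @rdname read_cohort
#' @param cohort a cohort table.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in names(out)) if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Randomly select an index date within each person's eligible window
#'
#' The eligible window runs from one year after the start of the person's data
#' collection or 1998-01-01, whichever is later, to the end of data collection.
#' The date is drawn uniformly over whole days in the closed window. Draws are
#' reproducible from a single global seed combined with a per-person identifier
#' hash, so they do not depend on cohort order.
#'
#' @param registration_start,data_end `Date` vectors.
#' @param seed integer seed.
#' @param person_id identifiers hashed into the per-person stream
#'   (defaults to element position).
#' @return a `Date` vector of index dates.
#' @export
select_index_date <- function(registration_start, data_end, seed,
                              person_id = seq_along(registration_start)) {
  registration_start <- as.Date(registration_start)
  data_end <- as.Date(data_end)
  stopifnot(length(data_end) == length(registration_start))
  win_start <- pmax(add_years(registration_start, 1), as.Date("1998-01-01"))
  ndays <- as.numeric(data_end - win_start)
  if (any(is.na(ndays))) stop("registration_start/data_end contain missing dates")
  if (any(ndays < 0))
    stop("ineligible person(s): empty index-date window at positions ",
         paste(utils::head(which(ndays < 0), 5), collapse = ", "))
  u <- hash_uniform(seed, person_id)
  offs <- pmin(floor(u * (ndays + 1)), ndays)
  win_start + offs
}

#' Apply the cohort eligibility rules
#'
#' Excludes persons aged outside 35-74 at the index date, persons with a CVD
#' event on or before the index date, persons with a statin prescription on or
#' before the index date, temporary registrations, persons whose index date
#' falls outside the eligible window, and persons with missing key dates.
#' Optional logical columns `prior_cvd` / `prior_statin` (history known but
#' undated) also exclude when TRUE. Filtering is idempotent.
#'
#' @param cohort a cohort table.
#' @return the filtered cohort; attribute `"exclusions"` tallies reasons.
#' @export
apply_eligibility <- function(cohort) {
  x <- cohort
  n <- nrow(x)
  flag <- function(col) if (col %in% names(x)) isTRUE_v(x[[col]]) else rep(FALSE, n)

  missing_dates <- is.na(x$index_date) | is.na(x$registration_start) | is.na(x$data_end)
  age_out <- !missing_dates & (is.na(x$age_at_index) | x$age_at_index < 35 | x$age_at_index > 74)
  prior_cvd <- flag("prior_cvd") |
    (!is.na(x$cvd_event_date) & !missing_dates & x$cvd_event_date <= x$index_date) |
    (x$death_cause == "cvd" & !is.na(x$death_date) & !missing_dates & x$death_date <= x$index_date)
  prior_statin <- flag("prior_statin") |
    (!is.na(x$statin_start) & !missing_dates & x$statin_start <= x$index_date)
  temp_reg <- isTRUE_v(x$temporary_registration)
  win_start <- pmax(add_years(x$registration_start, 1), as.Date("1998-01-01"))
  window_bad <- !missing_dates & (x$index_date < win_start | x$index_date > x$data_end)
  early_death <- !missing_dates & !is.na(x$death_date) & x$death_cause != "cvd" &
    x$death_date < x$index_date

  drop <- missing_dates | age_out | prior_cvd | prior_statin | temp_reg |
    window_bad | early_death
  out <- x[!drop, , drop = FALSE]
  attr(out, "exclusions") <- c(
    missing_dates = sum(missing_dates), age_out_of_range = sum(age_out),
    prior_cvd = sum(prior_cvd), prior_statin = sum(prior_statin),
    temporary_registration = sum(temp_reg), index_outside_window = sum(window_bad),
    death_before_index = sum(early_death), retained = nrow(out))
  out
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' Derive follow-up time and event type
#'
#' Follow-up runs from the index date to the earliest of the first CVD event
#' (including death from CVD), death from another cause, the first statin
#' prescription, and the end of data collection. Statin initiation and the end
#' of data collection censor follow-up. Same-day ties are resolved with
#' precedence CVD event > other death > censoring, so a CVD event on the day of
#' a statin prescription still counts as an event.
#'
#' @param cohort an eligibility-filtered cohort.
#' @return data.frame `person_id`, `time` (years, > 0), `event` (factor
#'   censored/cvd/death_other).
#' @export
derive_followup <- function(cohort) {
  x <- cohort
  idx <- as.numeric(x$index_date)
  cvd_d <- as.numeric(x$cvd_event_date)
  death_d <- as.numeric(x$death_date)
  cvd_time <- pmin(cvd_d, ifelse(x$death_cause == "cvd", death_d, NA_real_), na.rm = TRUE)
  cvd_time[is.infinite(cvd_time)] <- NA_real_
  other_death_time <- ifelse(x$death_cause == "other", death_d, NA_real_)
  cens_time <- pmin(as.numeric(x$statin_start), as.numeric(x$data_end), na.rm = TRUE)

  cand <- cbind(cvd = cvd_time, death_other = other_death_time, censored = cens_time)
  tmin <- suppressWarnings(apply(cand, 1, min, na.rm = TRUE))
  if (any(!is.finite(tmin))) stop("corrupt record: no candidate end-of-follow-up date")
  if (any(tmin < idx))
    stop("corrupt record: end-of-follow-up date before index date for person(s) ",
         paste(utils::head(x$person_id[tmin < idx], 5), collapse = ", "))
  # precedence at ties: cvd > death_other > censored (column order)
  event <- EVENT_LEVELS[ifelse(!is.na(cvd_time) & cvd_time == tmin, 2L,
                        ifelse(!is.na(other_death_time) & other_death_time == tmin, 3L, 1L))]
  # whole-day data: a terminal date equal to the index date contributes half a day
  time <- pmax(tmin - idx, 0.5) / DAYS_PER_YEAR
  data.frame(person_id = x$person_id, time = time,
             event = factor(event, levels = EVENT_LEVELS),
             stringsAsFactors = FALSE)
}
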