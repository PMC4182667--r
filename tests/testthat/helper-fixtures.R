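# Handcrafted cohort fixtures built in code.

toy_person <- function(person_id = "p1", sex = "male", birth_year = 1950L,
                       registration_start = "1995-01-01",
                       data_end = "2010-12-31",
                       temporary_registration = FALSE,
                       index_date = "2000-06-15",
                       ethnicity = "white", deprivation_quintile = 3L,
                       smoking = "never", cigs_per_day = "none",
                       sbp = 130, chol_hdl_ratio = 4, bmi = 26,
                       treated_hypertension = FALSE, diabetes = FALSE,
                       atrial_fibrillation = FALSE, chronic_renal_disease = FALSE,
                       rheumatoid_arthritis = FALSE, lvh = FALSE,
                       family_history_chd = FALSE, records_prior_year = 8L,
                       statin_start = NA, cvd_event_date = NA, death_date = NA,
                       death_cause = "none", age_at_index = NULL) {
  idx <- as.Date(index_date)
  if (is.null(age_at_index))
    age_at_index <- as.integer(format(idx, "%Y")) - birth_year
  data.frame(
    person_id = person_id, sex = sex, birth_year = birth_year,
    registration_start = as.Date(registration_start),
    data_end = as.Date(data_end),
    temporary_registration = temporary_registration,
    index_date = idx, age_at_index = age_at_index,
    ethnicity = ethnicity, deprivation_quintile = deprivation_quintile,
    smoking = smoking, cigs_per_day = cigs_per_day,
    sbp = sbp, chol_hdl_ratio = chol_hdl_ratio, bmi = bmi,
    treated_hypertension = treated_hypertension, diabetes = diabetes,
    atrial_fibrillation = atrial_fibrillation,
    chronic_renal_disease = chronic_renal_disease,
    rheumatoid_arthritis = rheumatoid_arthritis, lvh = lvh,
    family_history_chd = family_history_chd,
    records_prior_year = records_prior_year,
    statin_start = as.Date(statin_start),
    cvd_event_date = as.Date(cvd_event_date),
    death_date = as.Date(death_date),
    death_cause = death_cause, stringsAsFactors = FALSE
  )
}

toy_cohort <- function(...) {
  rows <- list(...)
  as_cohort(do.call(rbind, rows))
}

followup_table <- function(time, event, person_id = as.character(seq_along(time))) {
  data.frame(person_id = person_id, time = time,
             event = factor(event, levels = c("censored", "cvd", "death_other")),
             stringsAsFactors = FALSE)
}

# A minimal hand-built cause-specific fit with no covariates, for exact
# product-integral arithmetic in tests.
hand_fit <- function(cause, times, cum_hazard) {
  structure(list(
    cause = cause, stratum = "all", covariates = character(0), fp = list(),
    xlevels = list(), coef = stats::setNames(numeric(0), character(0)),
    means = stats::setNames(numeric(0), character(0)), dropped = character(0),
    baseline = data.frame(time = times, hazard = cum_hazard),
    n = 10L, nevent = length(times), loglik = c(0, 0), converged = TRUE
  ), class = "cause_specific_fit")
}

# Small generated cohort shared by several tests (cached per session).
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_persons = 4000, seed = 2024)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})
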