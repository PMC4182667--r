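# Synthetic primary-care cohort generator with known ground-truth cause-specific
# hazards, calendar trends, censoring and configurable missingness. The defaults
# are fixtures loosely matched to the covariate mix of a large UK primary-care
# cohort; they are study conditions, not estimates.

#' Generator configuration
#'
#' Builds a validated configuration for [generate_cohort()]. Components can be
#' overridden by passing named elements which are merged recursively into the
#' defaults (e.g. `true_model = list(cvd = list(baseline = list(rates = 0.02)))`).
#'
#' Ground truth is a pair of cause-specific proportional hazards
#' `h_k(t|x) = h0k(t) * exp(lp_k(x))` with piecewise-constant baselines
#' (`breaks` are interior cut points in years since index, `rates` has one more
#' element). Calendar year at the index date enters the linear predictor as a
#' covariate (`calendar`, per-year log rate ratio), which is what lets a
#' downstream secular-trend analysis recover a known trend. The optional
#' `nonattender` block creates a latent trait that raises the CVD log-hazard by
#' `log_hr_cvd` and can drive missingness: a person whose risk factors are
#' unmeasured because they rarely attend is also at different risk, the
#' informative-missingness mechanism.
#'
#' @param n_persons number of persons (>= 1).
#' @param seed integer seed; regeneration with the same seed is bit-identical.
#' @param ... named overrides merged into the defaults.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_persons = 10000, seed = 1, ...) {
  cfg <- list(
    n_persons = n_persons,
    seed = seed,
    covariates = list(
      p_male = 0.5,
      age_mean = 50, age_sd = 12, age_range = c(35, 74),
      ethnicity_p = c(white = 0.53, black = 0.015, indian = 0.010,
                      other = 0.022, unknown = 0.423),
      deprivation_p = c(0.250, 0.245, 0.196, 0.183, 0.126),
      smoking_p = c(never = 0.55, past = 0.18, current = 0.27),
      cigs_p = c("1-10" = 0.45, "11-20" = 0.35, "21+" = 0.20),
      sbp_mean = 130, sbp_sd = 17,
      chol_mean = 4.1, chol_sd = 1.3,
      bmi_mean = 26.5, bmi_sd = 4.5,
      comorbidity_p = c(treated_hypertension = 0.088, diabetes = 0.020,
                        atrial_fibrillation = 0.0065, chronic_renal_disease = 0.0065,
                        rheumatoid_arthritis = 0.0085, lvh = 0.002),
      p_family_history = 0.12,
      records_mu = 13, records_size = 0.8
    ),
    followup_window = list(
      registration_range = c("1988-01-01", "2008-01-01"),
      admin_years_range = c(3, 22),
      data_end_cap = "2011-11-01"
    ),
    true_model = list(
      cvd = list(
        coef = c(age = 0.075, sex_male = 0.40,
                 smoking_past = 0.15, smoking_current = 0.65,
                 sbp = 0.012, chol_hdl_ratio = 0.15, bmi = 0.02,
                 treated_hypertension = 0.35, diabetes = 0.65,
                 atrial_fibrillation = 0.45, chronic_renal_disease = 0.35,
                 rheumatoid_arthritis = 0.20, lvh = 0.45,
                 family_history_chd = 0.25, deprivation = 0.06,
                 ethnicity_black = -0.05, ethnicity_indian = 0.30,
                 ethnicity_other = 0.05, ethnicity_unknown = -0.80,
                 records_log = 0.30, calendar = -0.04),
        baseline = list(breaks = numeric(0), rates = 0.006)
      ),
      death_other = list(
        coef = c(age = 0.09, sex_male = 0.35,
                 smoking_past = 0.20, smoking_current = 0.55,
                 bmi = -0.01, records_log = 0.35, calendar = -0.015,
                 ethnicity_unknown = -0.30),
        baseline = list(breaks = numeric(0), rates = 0.006)
      )
    ),
    references = c(age = 55, sbp = 130, chol_hdl_ratio = 4, bmi = 26,
                   deprivation = 3, records_log = log1p(8), calendar = 2004),
    statin_rate = 0.02,
    nonattender = list(prevalence = 0, log_hr_cvd = 0),
    missingness = default_missingness()
  )
  over <- list(...)
  if (length(over) > 0) cfg <- modify_deep(cfg, over)
  validate_generator_config(cfg)
}

# Calendar-sloped missingness defaults anchored to observed 1998 and 2010
# missing-data fractions for each variable (logit-linear in calendar year).
default_missingness <- function() {
  anchor <- function(p1998, p2010)
    list(intercept = stats::qlogis(p1998),
         slope = (stats::qlogis(p2010) - stats::qlogis(p1998)) / 12,
         event_logodds = 0, nonattender_logodds = 0, trait_only = FALSE)
  list(sbp = anchor(0.334, 0.223),
       chol_hdl_ratio = anchor(0.978, 0.722),
       bmi = anchor(0.473, 0.327),
       smoking = anchor(0.473, 0.143))
}

modify_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) && !is.null(names(over[[nm]])))
      base[[nm]] <- modify_deep(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

validate_generator_config <- function(cfg) {
  bad <- character(0)
  chk <- function(cond, field) if (!isTRUE(cond)) bad <<- c(bad, field)
  chk(is.numeric(cfg$n_persons) && cfg$n_persons >= 1, "n_persons")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed")
  cv <- cfg$covariates
  sum1 <- function(p) abs(sum(p) - 1) < 1e-6 && all(p >= 0)
  chk(sum1(cv$ethnicity_p), "covariates$ethnicity_p")
  chk(sum1(cv$deprivation_p), "covariates$deprivation_p")
  chk(sum1(cv$smoking_p), "covariates$smoking_p")
  chk(sum1(cv$cigs_p), "covariates$cigs_p")
  chk(all(cv$comorbidity_p >= 0 & cv$comorbidity_p <= 1), "covariates$comorbidity_p")
  for (cause in c("cvd", "death_other")) {
    b <- cfg$true_model[[cause]]$baseline
    chk(all(b$rates >= 0), paste0("true_model$", cause, "$baseline$rates"))
    chk(length(b$rates) == length(b$breaks) + 1,
        paste0("true_model$", cause, "$baseline length"))
    chk(is.null(b$breaks) || !is.unsorted(b$breaks, strictly = TRUE),
        paste0("true_model$", cause, "$baseline$breaks"))
  }
  chk(cfg$statin_rate >= 0, "statin_rate")
  na <- cfg$nonattender
  chk(na$prevalence >= 0 && na$prevalence <= 1, "nonattender$prevalence")
  if (length(bad) > 0)
    stop("invalid generator config field(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "generator_config")
}

# Linear predictor of the ground-truth model for a fully observed cohort.
# Unnamed/missing coefficients default to zero; covariates are centred at the
# configured reference values so exp(lp) ~ 1 for a typical person.
true_linear_predictor <- function(df, coef, refs, nonattender = NULL) {
  c0 <- function(nm) if (nm %in% names(coef)) unname(coef[nm]) else 0
  year <- calendar_year_of(df$index_date)
  lp <- c0("age") * (df$age_at_index - refs[["age"]]) +
    c0("sex_male") * (df$sex == "male") +
    c0("smoking_past") * (df$smoking == "past") +
    c0("smoking_current") * (df$smoking == "current") +
    c0("sbp") * (df$sbp - refs[["sbp"]]) +
    c0("chol_hdl_ratio") * (df$chol_hdl_ratio - refs[["chol_hdl_ratio"]]) +
    c0("bmi") * (df$bmi - refs[["bmi"]]) +
    c0("treated_hypertension") * df$treated_hypertension +
    c0("diabetes") * df$diabetes +
    c0("atrial_fibrillation") * df$atrial_fibrillation +
    c0("chronic_renal_disease") * df$chronic_renal_disease +
    c0("rheumatoid_arthritis") * df$rheumatoid_arthritis +
    c0("lvh") * df$lvh +
    c0("family_history_chd") * df$family_history_chd +
    c0("deprivation") * (df$deprivation_quintile - refs[["deprivation"]]) +
    c0("ethnicity_black") * (df$ethnicity == "black") +
    c0("ethnicity_indian") * (df$ethnicity == "indian") +
    c0("ethnicity_other") * (df$ethnicity == "other") +
    c0("ethnicity_unknown") * (df$ethnicity == "unknown") +
    c0("records_log") * (log1p(df$records_prior_year) - refs[["records_log"]]) +
    c0("calendar") * (year - refs[["calendar"]])
  if (!is.null(nonattender)) lp <- lp + c0("nonattender") * nonattender
  as.numeric(lp)
}

pw_rate <- function(baseline, t) {
  baseline$rates[findInterval(t, c(0, baseline$breaks))]
}

# Latent competing event times by inversion of the all-cause cumulative hazard;
# the cause at the drawn time is assigned with probability h_k / (h_1 + h_2).
# Exact for piecewise-constant baselines.
sim_competing_times <- function(e1, e2, b1, b2) {
  n <- length(e1)
  edges <- sort(unique(c(0, b1$breaks, b2$breaks)))
  E <- stats::rexp(n)
  H <- numeric(n)
  t_out <- rep(Inf, n)
  cause <- rep(NA_integer_, n)
  u <- stats::runif(n)
  for (i in seq_along(edges)) {
    a <- edges[i]
    width <- if (i < length(edges)) edges[i + 1] - a else Inf
    r1 <- pw_rate(b1, a) * e1
    r2 <- pw_rate(b2, a) * e2
    rt <- r1 + r2
    dH <- ifelse(rt > 0, rt * width, 0)
    hit <- is.infinite(t_out) & rt > 0 & E <= H + dH
    if (any(hit)) {
      t_out[hit] <- a + (E[hit] - H[hit]) / rt[hit]
      cause[hit] <- ifelse(u[hit] < (r1 / rt)[hit], 1L, 2L)
    }
    H <- H + dH
  }
  list(time = t_out, cause = cause)
}

# Closed-form cumulative incidence under piecewise-constant cause-specific
# hazards: F_k(t) = sum over segments of (r_k / r_tot) (S(a) - S(b)).
cif_competing <- function(e1, e2, b1, b2, horizon) {
  edges <- sort(unique(c(0, b1$breaks, b2$breaks)))
  edges <- c(edges[edges < horizon], horizon)
  F1 <- F2 <- numeric(length(e1))
  H <- numeric(length(e1))
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    r1 <- pw_rate(b1, a) * e1
    r2 <- pw_rate(b2, a) * e2
    rt <- r1 + r2
    Sa <- exp(-H)
    Sb <- exp(-(H + rt * (b - a)))
    pos <- rt > 0
    F1[pos] <- F1[pos] + (r1 / rt * (Sa - Sb))[pos]
    F2[pos] <- F2[pos] + (r2 / rt * (Sa - Sb))[pos]
    H <- H + rt * (b - a)
  }
  list(cvd = F1, death_other = F2)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates from the configured marginals, latent cause-specific event
#' times from the ground-truth hazards, and censoring from statin initiation
#' and the administrative end of data collection. The returned cohort is fully
#' observed (use [inject_missingness()] afterwards) and carries a `"truth"`
#' attribute with each person's linear predictors, latent event time/cause and
#' closed-form 10-year cumulative incidence per cause, for oracle testing.
#'
#' @param config a [generator_config()].
#' @return a `cohort` with attribute `"truth"`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_generator_config(config)
  set.seed(child_seed(cfg$seed, 1))
  n <- as.integer(cfg$n_persons)
  cv <- cfg$covariates

  fw <- cfg$followup_window
  reg_lo <- as.Date(fw$registration_range[1])
  reg_hi <- as.Date(fw$registration_range[2])
  reg_start <- reg_lo + floor(stats::runif(n) * (as.numeric(reg_hi - reg_lo) + 1))
  admin_years <- stats::runif(n, fw$admin_years_range[1], fw$admin_years_range[2])
  data_end <- pmin(reg_start + round(admin_years * DAYS_PER_YEAR),
                   as.Date(fw$data_end_cap))
  win_start <- pmax(add_years(reg_start, 1), as.Date("1998-01-01"))
  data_end <- pmax(data_end, win_start)

  index_date <- select_index_date(reg_start, data_end, seed = cfg$seed,
                                  person_id = seq_len(n))
  year <- calendar_year_of(index_date)

  ages <- seq(cv$age_range[1], cv$age_range[2])
  age <- sample(ages, n, replace = TRUE,
                prob = stats::dnorm(ages, cv$age_mean, cv$age_sd))
  sex <- factor(ifelse(stats::runif(n) < cv$p_male, "male", "female"),
                levels = SEX_LEVELS)
  ethnicity <- factor(sample(names(cv$ethnicity_p), n, replace = TRUE,
                             prob = cv$ethnicity_p), levels = ETHNICITY_LEVELS)
  deprivation <- sample(1:5, n, replace = TRUE, prob = cv$deprivation_p)
  smoking <- factor(sample(names(cv$smoking_p), n, replace = TRUE,
                           prob = cv$smoking_p), levels = SMOKING_LEVELS)
  cigs <- factor(rep("none", n), levels = CIGS_LEVELS)
  cur <- smoking == "current"
  cigs[cur] <- factor(sample(names(cv$cigs_p), sum(cur), replace = TRUE,
                             prob = cv$cigs_p), levels = CIGS_LEVELS)
  sbp <- pmin(pmax(stats::rnorm(n, cv$sbp_mean, cv$sbp_sd), 70), 250)
  chol <- pmin(pmax(stats::rnorm(n, cv$chol_mean, cv$chol_sd), 1.5), 12)
  bmi <- pmin(pmax(stats::rnorm(n, cv$bmi_mean, cv$bmi_sd), 15), 60)
  flags <- lapply(cv$comorbidity_p, function(p) stats::runif(n) < p)
  family_history <- stats::runif(n) < cv$p_family_history
  records <- stats::rnbinom(n, mu = cv$records_mu, size = cv$records_size)
  nonatt <- as.integer(stats::runif(n) < cfg$nonattender$prevalence)

  df <- data.frame(
    person_id = as.character(seq_len(n)), sex = sex,
    birth_year = as.integer(year - age),
    registration_start = reg_start, data_end = data_end,
    temporary_registration = FALSE,
    index_date = index_date, age_at_index = as.numeric(age),
    ethnicity = ethnicity, deprivation_quintile = as.integer(deprivation),
    smoking = smoking, cigs_per_day = cigs,
    sbp = sbp, chol_hdl_ratio = chol, bmi = bmi,
    treated_hypertension = flags$treated_hypertension,
    diabetes = flags$diabetes,
    atrial_fibrillation = flags$atrial_fibrillation,
    chronic_renal_disease = flags$chronic_renal_disease,
    rheumatoid_arthritis = flags$rheumatoid_arthritis,
    lvh = flags$lvh, family_history_chd = family_history,
    records_prior_year = as.integer(records),
    statin_start = as.Date(NA), cvd_event_date = as.Date(NA),
    death_date = as.Date(NA),
    death_cause = factor("none", levels = DEATH_CAUSE_LEVELS),
    stringsAsFactors = FALSE
  )

  coef_cvd <- cfg$true_model$cvd$coef
  coef_cvd["nonattender"] <- cfg$nonattender$log_hr_cvd
  lp1 <- true_linear_predictor(df, coef_cvd, cfg$references, nonattender = nonatt)
  lp2 <- true_linear_predictor(df, cfg$true_model$death_other$coef, cfg$references)
  b1 <- cfg$true_model$cvd$baseline
  b2 <- cfg$true_model$death_other$baseline

  latent <- sim_competing_times(exp(lp1), exp(lp2), b1, b2)
  cif10 <- cif_competing(exp(lp1), exp(lp2), b1, b2, horizon = 10)

  statin_time <- if (cfg$statin_rate > 0) stats::rexp(n, cfg$statin_rate) else rep(Inf, n)
  admin_y <- as.numeric(data_end - index_date) / DAYS_PER_YEAR
  admin_days <- as.numeric(data_end - index_date)

  # a statin prescription is only recordable while the person is alive and
  # within the data-collection window
  statin_ok <- statin_time < admin_y &
    !(!is.na(latent$cause) & latent$cause == 2L & latent$time <= statin_time)
  statin_day <- pmax(1, ceiling(statin_time * DAYS_PER_YEAR))
  df$statin_start[statin_ok] <- index_date[statin_ok] +
    pmin(statin_day[statin_ok], admin_days[statin_ok])

  # latent event observed if it precedes both censoring mechanisms
  observed <- !is.infinite(latent$time) &
    latent$time <= pmin(statin_time, admin_y)
  ev_day <- pmin(pmax(1, ceiling(latent$time * DAYS_PER_YEAR)), admin_days)
  is_cvd <- observed & latent$cause == 1L
  is_death <- observed & latent$cause == 2L
  df$cvd_event_date[is_cvd] <- index_date[is_cvd] + ev_day[is_cvd]
  df$death_date[is_death] <- index_date[is_death] + ev_day[is_death]
  df$death_cause[is_death] <- "other"

  cohort <- as_cohort(df)
  attr(cohort, "truth") <- data.frame(
    person_id = df$person_id, lp_cvd = lp1, lp_death = lp2,
    cif10_cvd = cif10$cvd, cif10_death = cif10$death_other,
    latent_time = latent$time,
    latent_cause = c("cvd", "death_other")[latent$cause],
    latent_cvd10 = !is.na(latent$cause) & latent$cause == 1L & latent$time <= 10,
    nonattender = nonatt, stringsAsFactors = FALSE
  )
  cohort
}

#' Retrieve the ground truth of a generated cohort
#' @param cohort a cohort produced by [generate_cohort()].
#' @return data.frame with per-person linear predictors, latent event
#'   time/cause and closed-form 10-year cumulative incidences.
#' @export
cohort_truth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) stop("cohort carries no ground truth (not generated by generate_cohort)")
  tr
}

#' Write the parallel ground-truth table as CSV
#' @inheritParams cohort_truth
#' @param path output CSV path.
#' @export
write_truth <- function(cohort, path) {
  utils::write.csv(cohort_truth(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Set risk-factor values missing
#'
#' Applies per-variable logistic missingness models to a fully observed cohort.
#' Each model has a logit intercept anchored at calendar year 1998, a per-year
#' slope (data recording improved over time), and two informative options: an
#' additional log-odds shift for persons whose latent CVD event occurs within
#' 10 years (`event_logodds`), and a shift for latent non-attenders
#' (`nonattender_logodds`, or `trait_only = TRUE` to make the variable missing
#' exactly for non-attenders). Setting `smoking` missing also blanks the
#' cigarettes-per-day band.
#'
#' @param cohort a fully observed cohort from [generate_cohort()].
#' @param missingness per-variable config list; defaults to the generator's
#'   calendar-anchored models.
#' @param seed integer seed.
#' @return the cohort with NAs injected; ground-truth attribute preserved.
#' @export
inject_missingness <- function(cohort, missingness = default_missingness(), seed = 1) {
  truth <- attr(cohort, "truth")
  set.seed(child_seed(seed, 2))
  year <- calendar_year_of(cohort$index_date)
  n <- nrow(cohort)
  realized <- numeric(0)
  for (var in names(missingness)) {
    mc <- missingness[[var]]
    if (isTRUE(mc$trait_only)) {
      if (is.null(truth)) stop("trait_only missingness needs a generated cohort with ground truth")
      miss <- truth$nonattender == 1
    } else {
      eta <- mc$intercept + mc$slope * (year - 1998)
      if ((mc$event_logodds %||% 0) != 0) {
        if (is.null(truth)) stop("event-informative missingness needs ground truth")
        eta <- eta + mc$event_logodds * truth$latent_cvd10
      }
      if ((mc$nonattender_logodds %||% 0) != 0) {
        if (is.null(truth)) stop("non-attender missingness needs ground truth")
        eta <- eta + mc$nonattender_logodds * truth$nonattender
      }
      miss <- stats::runif(n) < stats::plogis(eta)
    }
    cohort[[var]][miss] <- NA
    if (var == "smoking") cohort$cigs_per_day[miss] <- NA
    realized[var] <- mean(miss)
  }
  attr(cohort, "truth") <- truth
  attr(cohort, "missingness_realized") <- realized
  cohort
}
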