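test_that("the Cox partial-likelihood maximiser matches a grid search", {
  # 4 subjects, event times 1 < 2 < 3 < 4 (no ties), binary covariate 1,0,1,0
  x <- c(1, 0, 1, 0)
  fu <- followup_table(time = 1:4, event = rep("cvd", 4))
  co <- toy_cohort(toy_person("1", sbp = x[1]), toy_person("2", sbp = x[2]),
                   toy_person("3", sbp = x[3]), toy_person("4", sbp = x[4]))
  fit <- fit_cause_specific(fu, co, "cvd", covariates = "sbp")

  # independent oracle: the written-out partial likelihood on a fine 1-D grid
  grid <- seq(-4, 4, by = 1e-5)
  riskset <- list(1:4, 2:4, 3:4, 4)
  pll <- rep(0, length(grid))
  for (i in 1:4)
    pll <- pll + grid * x[i] - log(colSums(exp(outer(x[riskset[[i]]], grid))))
  beta_grid <- grid[which.max(pll)]
  expect_lt(abs(unname(fit$coef["sbp"]) - beta_grid), 1e-4)
})

test_that("a constant covariate is reported as degenerate with zero coefficient", {
  fu <- followup_table(time = c(1, 2, 3, 4, 5), event = c("cvd", "cvd", "censored", "cvd", "censored"))
  co <- toy_cohort(toy_person("1"), toy_person("2"), toy_person("3"),
                   toy_person("4"), toy_person("5"))
  expect_warning(fit <- fit_cause_specific(fu, co, "cvd", covariates = "sbp"),
                 "degenerate")
  expect_true("sbp" %in% fit$dropped)
  expect_false("sbp" %in% names(fit$coef))
  expect_error(fit_cause_specific(followup_table(5, "censored"),
                                  toy_cohort(toy_person("1")), "cvd",
                                  covariates = "sbp"),
               "no events")
})

test_that("a simulated log hazard ratio is recovered within Monte-Carlo error", {
  n <- 8000
  cfg <- generator_config(n_persons = n, seed = 91,
    covariates = list(p_male = 0.5),
    true_model = list(
      cvd = list(coef = c(sex_male = 0.5), baseline = list(rates = 0.02)),
      death_other = list(coef = c(sex_male = 0), baseline = list(rates = 0.01))),
    statin_rate = 0,
    followup_window = list(registration_range = c("1988-01-01", "1996-01-01"),
                           admin_years_range = c(12, 18),
                           data_end_cap = "2020-01-01"))
  cfg$true_model$cvd$coef <- c(sex_male = 0.5)
  cfg$true_model$death_other$coef <- c(sex_male = 0)
  ch <- generate_cohort(cfg)
  fit <- fit_cause_specific(derive_followup(ch), ch, "cvd", covariates = "sex")
  # the sex dummy is coded for the second level (female), so its sign flips
  b <- -unname(fit$coef["sex=female"])
  se <- unname(fit$se["sex=female"])
  expect_lt(abs(b - 0.5), 3 * se)
})

test_that("fractional-polynomial bases follow the power conventions", {
  expect_equal(unname(fp_basis(1, 0)[1, 1]), 0)          # power 0 is log
  expect_equal(unname(fp_basis(2, c(0, 0))[1, ]), c(log(2), log(2)^2))
  expect_equal(unname(fp_basis(2, c(2, 2))[1, ]), c(4, 4 * log(2)))
  expect_equal(unname(fp_basis(4, c(-0.5, 3))[1, ]), c(0.5, 64))
  expect_error(fp_basis(-1, 1), "strictly positive")
  # shift makes the input positive
  expect_silent(fp_basis(c(-1, 0, 2), 0.5, shift = 2))
})

test_that("the closed test keeps a truly linear effect linear most of the time", {
  reps <- 30
  picked <- character(reps)
  for (r in seq_len(reps)) {
    cfg <- generator_config(n_persons = 4000, seed = 300 + r,
                            statin_rate = 0.02)
    cfg$true_model$cvd$coef <- c(age = 0.06)
    cfg$true_model$death_other$coef <- c(age = 0.05)
    ch <- generate_cohort(cfg)
    fp <- select_fractional_polynomial(derive_followup(ch), ch, "age_at_index",
                                       cause = "cvd")
    picked[r] <- fp$selected
  }
  expect_gte(mean(picked == "linear"), 0.85)
})

test_that("the product-integral prediction reproduces hand arithmetic exactly", {
  # baseline increments: cvd 0.10 at t=1, 0.20 at t=3; death 0.05 at t=2
  fc <- hand_fit("cvd", times = c(1, 3), cum_hazard = c(0.10, 0.30))
  fd <- hand_fit("death_other", times = 2, cum_hazard = 0.05)
  co <- toy_cohort(toy_person())
  pr <- predict_cif(fc, fd, co, horizon = 10)
  # S(1-)=1, F_cvd gains 0.10; S(2-)=0.90, F_death gains 0.045;
  # S(3-)=0.90*0.95=0.855, F_cvd gains 0.855*0.20=0.171
  expect_equal(pr$cif_cvd, 0.10 + 0.171, tolerance = 1e-15)
  expect_equal(pr$cif_death, 0.045, tolerance = 1e-15)
  expect_equal(pr$cif_cvd + pr$cif_death + pr$surv, 1, tolerance = 1e-12)
  expect_true(pr$extrapolated)  # horizon 10 beyond the last step at t=3

  # horizon below the first step: nothing accumulated
  pr0 <- predict_cif(fc, fd, co, horizon = 0.5)
  expect_equal(pr0$cif_cvd, 0)

  # a zero CVD hazard gives zero cumulative incidence
  f0 <- hand_fit("cvd", times = c(1, 3), cum_hazard = c(0, 0))
  expect_equal(predict_cif(f0, fd, co, horizon = 10)$cif_cvd, 0)
})

test_that("without a competing cause the prediction is the Kaplan-Meier complement", {
  ch <- shared_cohort()
  fu <- derive_followup(ch)
  fu$event[fu$event == "death_other"] <- "censored"  # single-cause data
  fit <- fit_cause_specific(fu, ch, "cvd", covariates = character(0))
  pr <- predict_cif(fit, NULL, ch[1, ], horizon = 10)
  km <- survival::survfit(survival::Surv(fu$time, fu$event == "cvd") ~ 1)
  km10 <- summary(km, times = 10, extend = TRUE)$surv
  # Efron tie handling perturbs tied baseline increments relative to the d/n
  # product-limit jumps, so agreement is near-exact rather than exact here;
  # the tie-free reduction is exact in the hand-arithmetic test above
  expect_equal(pr$cif_cvd, 1 - km10, tolerance = 1e-4)
  # and it is close to (but not exactly) the exponentiated cumulative hazard
  H10 <- max(fit$baseline$hazard[fit$baseline$time <= 10])
  expect_equal(pr$cif_cvd, 1 - exp(-H10), tolerance = 0.01)
})

test_that("predicted cumulative incidence is monotone in the horizon and conserved", {
  ch <- shared_cohort()[1:2000, ]
  fu <- derive_followup(ch)
  f1 <- fit_cause_specific(fu, ch, "cvd", covariates = c("age_at_index", "sex"))
  f2 <- fit_cause_specific(fu, ch, "death_other", covariates = c("age_at_index", "sex"))
  hs <- c(2, 5, 8, 10)
  # exact grid (no coarsening) so horizons share the same event-time steps
  prs <- lapply(hs, function(h)
    predict_cif(f1, f2, ch[1:50, ], horizon = h, max_steps = 100000L))
  for (i in seq_along(hs))
    expect_lt(max(abs(prs[[i]]$cif_cvd + prs[[i]]$cif_death + prs[[i]]$surv - 1)), 1e-12)
  for (i in 2:length(hs))
    expect_true(all(prs[[i]]$cif_cvd >= prs[[i - 1]]$cif_cvd - 1e-15))
})

test_that("grid coarsening changes predictions only negligibly", {
  ch <- shared_cohort()
  fu <- derive_followup(ch)
  f1 <- fit_cause_specific(fu, ch, "cvd", covariates = c("age_at_index", "sex"))
  f2 <- fit_cause_specific(fu, ch, "death_other", covariates = c("age_at_index", "sex"))
  exact <- predict_cif(f1, f2, ch[1:100, ], horizon = 10, max_steps = 100000L)
  coarse <- predict_cif(f1, f2, ch[1:100, ], horizon = 10, max_steps = 256L)
  expect_lt(max(abs(exact$cif_cvd - coarse$cif_cvd)), 5e-4)
})

test_that("the Aalen-Johansen estimate equals the long-hand product integral", {
  # 6 subjects: cvd@1, death@2, censored@3, cvd@4, censored@5, cvd@6
  fu <- followup_table(time = 1:6,
                       event = c("cvd", "death_other", "censored",
                                 "cvd", "censored", "cvd"))
  # by hand: F(4.5) = 1/6 + (2/3)(1/3) = 7/18
  aj <- observed_risk_aalen_johansen(fu, horizon = 4.5)
  expect_equal(aj$estimate, 7 / 18, tolerance = 1e-12)
  expect_gt(aj$se, 0)

  # no events at all
  expect_equal(observed_risk_aalen_johansen(
    followup_table(c(1, 2), c("censored", "censored")), 10)$estimate, 0)

  # no censoring, no competing events: the empirical fraction by t
  fu2 <- followup_table(time = c(1, 2, 3, 4), event = rep("cvd", 4))
  expect_equal(observed_risk_aalen_johansen(fu2, 2.5)$estimate, 0.5, tolerance = 1e-12)

  # single-cause data: equals the Kaplan-Meier complement
  ch <- shared_cohort()[1:1500, ]
  fu3 <- derive_followup(ch)
  fu3$event[fu3$event == "death_other"] <- "censored"
  aj3 <- observed_risk_aalen_johansen(fu3, 10)
  km <- survival::survfit(survival::Surv(fu3$time, fu3$event == "cvd") ~ 1)
  expect_equal(aj3$estimate, 1 - summary(km, times = 10, extend = TRUE)$surv,
               tolerance = 1e-12)
})

test_that("fits survive JSON persistence with identical predictions", {
  ch <- shared_cohort()[1:2000, ]
  fu <- derive_followup(ch)
  fit <- fit_cause_specific(fu, ch, "cvd",
                            covariates = c("age_at_index", "sex", "smoking"),
                            fp = list(age_at_index = list(powers = c(0, 0))))
  path <- withr::local_tempfile(fileext = ".json")
  write_cr_fit(fit, path)
  back <- read_cr_fit(path)
  a <- predict_cif(fit, NULL, ch[1:20, ], horizon = 10)
  b <- predict_cif(back, NULL, ch[1:20, ], horizon = 10)
  expect_equal(b$cif_cvd, a$cif_cvd, tolerance = 1e-12)
})

test_that("non-converged fits refuse to predict", {
  f <- hand_fit("cvd", times = 1, cum_hazard = 0.1)
  f$converged <- FALSE
  expect_error(predict_cif(f, NULL, toy_cohort(toy_person()), 10), "converge")
})
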