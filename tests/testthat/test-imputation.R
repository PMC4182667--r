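test_that("a complete cohort is returned unchanged by imputation", {
  ch <- shared_cohort()[1:300, ]
  iset <- impute(ch, m = 2, seed = 1, cycles = 2)
  for (d in iset$datasets)
    expect_equal(as.data.frame(d), as.data.frame(ch), ignore_attr = TRUE)
})

test_that("MCAR imputation recovers the marginal mean and preserves observed values", {
  ch <- shared_cohort()
  truth_mean <- mean(ch$sbp)
  mis <- inject_missingness(ch, missingness = list(
    sbp = list(intercept = stats::qlogis(0.3), slope = 0)), seed = 21)
  iset <- suppressWarnings(impute(mis, m = 3, seed = 22, targets = "sbp", cycles = 5))

  # observed values are bit-exact in every completed dataset
  keep <- !is.na(mis$sbp)
  for (d in iset$datasets) {
    expect_identical(d$sbp[keep], mis$sbp[keep])
    expect_false(anyNA(d$sbp))
    # untouched columns identical across datasets
    expect_identical(d$bmi, mis$bmi)
  }

  pooled_mean <- mean(vapply(iset$datasets, function(d) mean(d$sbp), numeric(1)))
  se <- stats::sd(ch$sbp) / sqrt(sum(!keep))
  expect_lt(abs(pooled_mean - truth_mean), 3 * se)
})

test_that("imputation under covariate-dependent missingness reduces bias", {
  set.seed(31)
  ch <- shared_cohort()
  # make SBP strongly age-dependent, then delete it preferentially in the old
  ch$sbp <- 90 + 0.8 * ch$age_at_index + stats::rnorm(nrow(ch), 0, 8)
  truth_mean <- mean(ch$sbp)
  mis <- ch
  p_miss <- stats::plogis(-3 + 0.06 * ch$age_at_index)
  mis$sbp[stats::runif(nrow(ch)) < p_miss] <- NA
  cc_bias <- abs(mean(mis$sbp, na.rm = TRUE) - truth_mean)
  iset <- suppressWarnings(impute(mis, m = 3, seed = 32, targets = "sbp", cycles = 5))
  mi_mean <- mean(vapply(iset$datasets, function(d) mean(d$sbp), numeric(1)))
  expect_lt(abs(mi_mean - truth_mean), cc_bias)
})

test_that("smoking is imputed as a categorical with a conditional cigarette band", {
  ch <- shared_cohort()
  mis <- inject_missingness(ch, missingness = list(
    smoking = list(intercept = stats::qlogis(0.35), slope = 0)), seed = 41)
  iset <- suppressWarnings(impute(mis, m = 2, seed = 42, targets = "smoking", cycles = 3))
  for (d in iset$datasets) {
    expect_false(anyNA(d$smoking))
    expect_false(anyNA(d$cigs_per_day))
    # band is none iff not a current smoker
    expect_true(all((d$cigs_per_day == "none") == (d$smoking != "current")))
  }
  # imputed marginal roughly matches the observed smoking distribution
  obs <- prop.table(table(mis$smoking[!is.na(mis$smoking)]))
  imp_rows <- is.na(mis$smoking)
  imp <- prop.table(table(iset$datasets[[1]]$smoking[imp_rows]))
  expect_lt(max(abs(obs - imp)), 0.1)
})

test_that("predictive-mean matching only imputes observed donor values", {
  ch <- shared_cohort()
  mis <- inject_missingness(ch, missingness = list(
    sbp = list(intercept = stats::qlogis(0.3), slope = 0)), seed = 51)
  iset <- suppressWarnings(impute(mis, m = 2, seed = 52, targets = "sbp",
                                  cycles = 3, method = "pmm"))
  obs_vals <- unique(mis$sbp[!is.na(mis$sbp)])
  for (d in iset$datasets)
    expect_true(all(d$sbp[is.na(mis$sbp)] %in% obs_vals))
})

test_that("an all-missing target is refused", {
  ch <- shared_cohort()[1:100, ]
  ch$bmi <- NA_real_
  expect_error(impute(ch, m = 2, seed = 1, targets = "bmi"), "no observed values")
})

test_that("Rubin's rules reproduce the hand-computed fixture", {
  pe <- pool_rubin(c(0.1, 0.2, 0.3), c(0.01, 0.01, 0.01))
  expect_equal(pe$point, 0.2)
  expect_equal(pe$within_var, 0.01)
  expect_equal(pe$between_var, 0.01)
  expect_equal(pe$total_var, 0.01 + (4 / 3) * 0.01)

  # identical estimates: no between-imputation variance
  pe0 <- pool_rubin(rep(0.4, 5), rep(0.02, 5))
  expect_equal(pe0$between_var, 0)
  expect_equal(pe0$total_var, pe0$within_var)
  expect_equal(pe0$dof, Inf)

  # zero within-variance: T = (1 + 1/m) B exactly
  peb <- pool_rubin(c(1, 2, 3, 4), rep(0, 4))
  expect_equal(peb$total_var, (1 + 1 / 4) * stats::var(c(1, 2, 3, 4)))

  expect_error(pool_rubin(0.5, 0.1), "m >= 2")
  expect_error(pool_rubin(c(1, 2), c(0.1, -0.1)), "non-negative")
})

test_that("the total-variance identity holds for pooled quantities from real chains", {
  ch <- shared_cohort()[1:800, ]
  mis <- inject_missingness(ch, missingness = list(
    sbp = list(intercept = stats::qlogis(0.4), slope = 0)), seed = 61)
  iset <- suppressWarnings(impute(mis, m = 4, seed = 62, targets = "sbp", cycles = 3))
  est <- vapply(iset$datasets, function(d) mean(d$sbp), numeric(1))
  va <- vapply(iset$datasets, function(d) stats::var(d$sbp) / nrow(d), numeric(1))
  pe <- pool_rubin(est, va)
  expect_equal(pe$total_var, pe$within_var + (1 + 1 / 4) * pe$between_var)
  expect_gte(pe$total_var, pe$within_var)
})

test_that("pooled confidence intervals attain nominal coverage under MCAR", {
  # scaled-down property check: 200 replicates at small n, one target, the
  # package's own chains end to end
  n <- 400
  reps <- 200
  true_mean <- 130  # generator marginal mean of SBP
  covered <- 0
  for (r in seq_len(reps)) {
    ch <- generate_cohort(generator_config(n_persons = n, seed = 7000 + r))
    mis <- inject_missingness(ch, missingness = list(
      sbp = list(intercept = stats::qlogis(0.3), slope = 0)), seed = r)
    iset <- suppressWarnings(impute(mis, m = 5, seed = r, targets = "sbp", cycles = 3))
    est <- vapply(iset$datasets, function(d) mean(d$sbp), numeric(1))
    va <- vapply(iset$datasets, function(d) stats::var(d$sbp) / n, numeric(1))
    pe <- pool_rubin(est, va)
    if (pe$ci95[1] <= true_mean && true_mean <= pe$ci95[2]) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.92)
  expect_lte(covered / reps, 0.98)
})

test_that("prediction pooling averages per person across datasets", {
  t1 <- data.frame(person_id = c("a", "b"), s = c(0.1, 0.3))
  t2 <- data.frame(person_id = c("a", "b"), s = c(0.2, 0.5))
  expect_equal(pool_predictions(list(t1, t2))$s, c(0.15, 0.4))
  expect_equal(pool_predictions(list(t1, t1))$s, t1$s)

  # 3 datasets x 4 persons, element-wise oracle
  set.seed(3)
  tabs <- lapply(1:3, function(i)
    data.frame(person_id = letters[1:4], x = stats::runif(4), y = stats::runif(4)))
  pooled <- pool_predictions(tabs)
  expect_equal(pooled$x, (tabs[[1]]$x + tabs[[2]]$x + tabs[[3]]$x) / 3)

  bad <- data.frame(person_id = c("a", "z"), s = c(0.1, 0.2))
  expect_error(pool_predictions(list(t1, bad)), "person sets differ")
})

test_that("imputation chains are reproducible from the seed", {
  ch <- shared_cohort()[1:500, ]
  mis <- inject_missingness(ch, seed = 81)
  a <- suppressWarnings(impute(mis, m = 2, seed = 82, cycles = 2))
  b <- suppressWarnings(impute(mis, m = 2, seed = 82, cycles = 2))
  for (j in 1:2)
    expect_identical(as.data.frame(a$datasets[[j]]), as.data.frame(b$datasets[[j]]))
})
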