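test_that("the pairwise ICC matches a long-hand two-way mean-squares oracle", {
  # 4 persons x 2 methods fixture
  x <- c(0.10, 0.20, 0.30, 0.40)
  y <- c(0.12, 0.16, 0.34, 0.36)
  m <- cbind(a = x, b = y)
  icc <- icc_agreement(m)

  # independent oracle: write out the ANOVA decomposition term by term
  n <- 4; k <- 2
  grand <- mean(c(x, y))
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * ((mean(x) - grand)^2 + (mean(y) - grand)^2) / (k - 1)
  sse <- sum((m - grand)^2) - k * sum((rowMeans(m) - grand)^2) -
    n * sum((colMeans(m) - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(icc["a", "b"], oracle, tolerance = 1e-10)
  expect_equal(icc["a", "b"], icc["b", "a"])
  expect_equal(diag(icc), c(a = 1, b = 1))
})

test_that("the ICC penalises a constant offset that Pearson ignores", {
  x <- c(0.05, 0.10, 0.15, 0.22, 0.30)
  y <- x + 0.05
  icc <- icc_agreement(cbind(x = x, y = y))["x", "y"]
  expect_equal(stats::cor(x, y), 1)
  expect_lt(icc, 1)
  expect_gt(icc, 0)
  # identical columns agree perfectly
  expect_equal(icc_agreement(cbind(x, x))[1, 2], 1)
  # agreement never exceeds correlation for shifted-but-correlated columns
  expect_lt(icc, stats::cor(x, y))
})

test_that("zero total variance is flagged rather than returned as a number", {
  m <- cbind(a = rep(0.2, 5), b = rep(0.2, 5))
  icc <- icc_agreement(m)
  expect_true(is.na(icc["a", "b"]))
  expect_equal(attr(icc, "degenerate"), "a:b")
})

test_that("difference bands follow the documented half-open edges", {
  b <- rep(0, 10)
  d_pp <- c(-11, -7, -3, 0, 0, 1, 3, 6, 11, 2)
  a <- d_pp / 100
  row <- difference_band_table(a, b)
  got <- as.numeric(row[paste0("pct_", c("<=-10", "(-10,-5]", "(-5,-2]", "(-2,+2)",
                                          "[+2,+5)", "[+5,+10)", ">=+10"))])
  expect_equal(got, 100 * c(1, 1, 1, 3, 2, 1, 1) / 10)
  expect_equal(row$mean_difference, mean(d_pp))
  expect_equal(sum(got), 100)

  # boundary membership: -10 in the lowest band, exactly 2 in [+2,+5)
  expect_equal(as.character(riskconcord:::diff_band(c(-10, -5, -2, 2, 5, 10))),
               c("<=-10", "(-10,-5]", "(-5,-2]", "[+2,+5)", "[+5,+10)", ">=+10"))

  # A = B: everything in the central band
  same <- difference_band_table(b, b)
  expect_equal(same$`pct_(-2,+2)`, 100)
  # A = B + 3 points: everything in [+2,+5)
  up3 <- difference_band_table(rep(0.03, 10), b)
  expect_equal(up3$`pct_[+2,+5)`, 100)
})

test_that("swapping the two methods mirrors the band distribution", {
  set.seed(5)
  a <- stats::runif(200, 0, 0.5)
  b <- pmin(pmax(a + stats::rnorm(200, 0, 0.06), 0), 1)
  ab <- difference_band_table(a, b)
  ba <- difference_band_table(b, a)
  pct_ab <- as.numeric(ab[grep("^pct_", names(ab))])
  pct_ba <- as.numeric(ba[grep("^pct_", names(ba))])
  expect_equal(pct_ab, rev(pct_ba))
  expect_equal(ab$mean_difference, -ba$mean_difference)
})

test_that("vigintile grouping is stable, balanced and reproducible", {
  # n = 20 distinct risks: one person per vigintile
  p <- data.frame(person_id = sprintf("p%02d", 1:20), risk = (1:20) / 40)
  fu <- followup_table(time = rep(10, 20), event = rep("censored", 20),
                       person_id = p$person_id)
  cal <- vigintile_calibration(p, fu, horizon = 5)
  expect_equal(cal$n, rep(1, 20))
  expect_equal(cal$mean_predicted, 100 * p$risk)

  # heavy ties: groups filled by stable order, sizes within 1
  p2 <- data.frame(person_id = sprintf("q%03d", 1:103), risk = rep(0.1, 103))
  g <- riskconcord:::vigintile_groups(p2$risk, p2$person_id, 20)
  expect_true(max(table(g)) - min(table(g)) <= 1)
  g2 <- riskconcord:::vigintile_groups(p2$risk, p2$person_id, 20)
  expect_identical(g, g2)
})

test_that("self-calibration holds when predictions come from the true model", {
  ch <- generate_cohort(generator_config(
    n_persons = 20000, seed = 500, statin_rate = 0.01,
    followup_window = list(registration_range = c("1988-01-01", "1998-01-01"),
                           admin_years_range = c(8, 20),
                           data_end_cap = "2018-01-01")))
  tr <- cohort_truth(ch)
  fu <- derive_followup(ch)
  pred <- data.frame(person_id = ch$person_id, risk = tr$cif10_cvd)
  cal <- vigintile_calibration(pred, fu, horizon = 10, groups = 10)
  within <- abs(cal$difference) <= 3 * cal$se_observed
  expect_gte(sum(within), 8)
})

test_that("stratified differences reduce to group-by arithmetic", {
  co <- shared_cohort()[1:100, ]
  d_pp <- ifelse(co$sex == "male", 1, 5)
  a <- rep(0.2, 100) + d_pp / 100
  b <- rep(0.2, 100)
  tab <- stratified_differences(a, b, co, "sex")
  expect_equal(tab$mean_difference[tab$level == "male"], 1)
  expect_equal(tab$mean_difference[tab$level == "female"], 5)
  expect_equal(tab$pct_within_2[tab$level == "male"], 100)
  expect_equal(tab$pct_within_2[tab$level == "female"], 0)

  # a single-level factor reproduces the overall mean difference
  co$onelevel <- factor(rep("all", 100))
  t1 <- stratified_differences(a, b, co, "onelevel")
  expect_equal(t1$mean_difference, mean(d_pp))

  # group-by oracle on a real factor
  t2 <- stratified_differences(a, b, co, "ethnicity")
  for (lev in t2$level) {
    sel <- as.character(co$ethnicity) == lev
    expect_equal(t2$mean_difference[t2$level == lev], mean(d_pp[sel]))
  }
})

test_that("threshold consistency counts agreeing methods exactly", {
  # all columns identical: everyone in the "all others agree" cell
  m <- cbind(a = c(0.3, 0.1, 0.4), b = c(0.3, 0.1, 0.4), c = c(0.3, 0.1, 0.4))
  hi <- threshold_consistency(m, 0.2, "ge")
  expect_equal(hi$pct_agree_2, rep(100, 3))

  # two columns with disjoint positives: all in the "0 others" cell
  m2 <- cbind(a = c(0.3, 0.1), b = c(0.1, 0.3))
  expect_equal(threshold_consistency(m2, 0.2, "ge")$pct_agree_0, c(100, 100))

  # 6-person, 3-method enumerated fixture (threshold .20, direction >=):
  # person: a,b,c positive?
  #  1: T T T -> a sees 2; 2: T T F -> a sees 1; 3: T F F -> a sees 0
  #  4: F T T; 5: F F T; 6: F F F
  m3 <- cbind(a = c(.25, .30, .22, .10, .05, .01),
              b = c(.21, .28, .10, .35, .15, .02),
              c = c(.40, .18, .12, .27, .33, .03))
  tab <- threshold_consistency(m3, 0.20, "ge")
  expect_equal(unlist(tab[tab$reference == "a", c("pct_agree_0", "pct_agree_1", "pct_agree_2")],
                      use.names = FALSE), 100 * c(1, 1, 1) / 3)
  expect_equal(tab$n_positive, c(3, 3, 3))
  # rows sum to 100
  expect_equal(rowSums(tab[grep("pct_", names(tab))]), rep(100, 3),
               ignore_attr = TRUE)

  # low-risk direction
  lo <- threshold_consistency(m3, 0.15, "lt")
  expect_equal(rowSums(lo[grep("pct_", names(lo))]), rep(100, 3),
               ignore_attr = TRUE)

  # reference with no positives is flagged
  m4 <- cbind(a = c(0.1, 0.1), b = c(0.3, 0.1))
  hi4 <- threshold_consistency(m4, 0.2, "ge")
  expect_true(is.na(hi4$pct_agree_0[1]))
  expect_equal(attr(hi4, "empty_reference"), "a")
})

test_that("case capture bins cases by their index-date prediction", {
  fu <- followup_table(time = rep(2, 8),
                       event = c(rep("cvd", 6), "censored", "death_other"))
  m <- cbind(s = c(0.25, 0.15, 0.05, 0.101, 0.199, 0.21, 0.5, 0.5))
  tab <- case_capture(m, fu)
  expect_equal(tab$n_cases, 6)
  # cases: .25 ->>=20; .15 -> 15-20 (left-closed); .05 -> <10; .101 -> 10-15;
  # .199 -> 15-20; .21 -> >=20
  expect_equal(as.numeric(tab[paste0("n_", c("<10", "10-15", "15-20", ">=20"))]),
               c(1, 1, 2, 2))
  expect_equal(sum(tab[paste0("pct_", c("<10", "10-15", "15-20", ">=20"))]), 100)

  # all cases at 25%: everything in the top bin
  fu2 <- followup_table(time = c(1, 2), event = c("cvd", "cvd"))
  tab2 <- case_capture(cbind(s = c(0.25, 0.25)), fu2)
  expect_equal(tab2$`pct_>=20`, 100)

  expect_error(case_capture(m, followup_table(rep(1, 8), rep("censored", 8))),
               "no CVD cases")
})

test_that("a null calendar trend yields rate ratios compatible with 1", {
  cfg <- generator_config(n_persons = 20000, seed = 600)
  cfg$true_model$cvd$coef["calendar"] <- 0
  cfg$true_model$death_other$coef["calendar"] <- 0
  ch <- generate_cohort(cfg)
  fu <- derive_followup(ch)
  tr <- secular_trend(fu, ch)
  expect_equal(tr$rr[1], 1)
  expect_true(is.na(tr$se_log[1]))
  z <- abs(log(tr$rr[-1])) / tr$se_log[-1]
  # no more than one >3 SD excursion among ~13 null tests
  expect_lte(sum(z > 3), 1)

  # a single calendar year cannot define a trend
  one_year <- toy_cohort(toy_person("a"), toy_person("b", sex = "female"))
  fu1 <- followup_table(c(2, 3), c("cvd", "censored"),
                        person_id = c("a", "b"))
  expect_error(secular_trend(fu1, one_year), "two calendar years")
})

test_that("imputed-versus-measured hazard is null under MCAR and errors without events", {
  ch <- generate_cohort(generator_config(n_persons = 15000, seed = 700))
  fu <- derive_followup(ch)
  mis <- inject_missingness(ch, missingness = list(
    bmi = list(intercept = stats::qlogis(0.4), slope = 0)), seed = 701)
  tab <- imputed_vs_measured(fu, mis, variables = "bmi")
  expect_lt(abs(log(tab$hr)) / tab$se_log, 3)

  nofu <- followup_table(rep(1, 10), rep("censored", 10),
                         person_id = ch$person_id[1:10])
  expect_error(imputed_vs_measured(nofu, mis[1:10, ], variables = "bmi"),
               "no CVD events")
})

test_that("rounded percentage rows sum to exactly 100", {
  p <- c(33.333, 33.333, 33.334)
  expect_equal(sum(round_percent_100(p)), 100)
  q <- c(14.2857, 14.2857, 14.2857, 14.2857, 14.2857, 14.2857, 14.2858)
  expect_equal(sum(round_percent_100(q)), 100)
  expect_equal(round_percent_100(c(100)), 100)
})
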