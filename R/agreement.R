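# Individual-level evaluation analytics: intraclass correlation between risk
# methods, risk-difference band tables, vigintile calibration against the
# Aalen-Johansen observed risk, stratified mean differences, threshold
# consistency and case capture, plus the two bias analyses (secular trend and
# imputed-versus-measured hazard).
#
# Inputs are per-person risks on the probability scale; all emitted tables use
# percentage points, matching how such results are usually printed.

DIFF_BAND_LABELS <- c("<=-10", "(-10,-5]", "(-5,-2]", "(-2,+2)",
                      "[+2,+5)", "[+5,+10)", ">=+10")

# Band assignment for a difference in percentage points. Half-open bins:
# (-Inf,-10], (-10,-5], (-5,-2], (-2,+2), [+2,+5), [+5,+10), [+10,Inf) —
# exactly anti-symmetric under a sign flip.
diff_band <- function(d) {
  idx <- ifelse(d <= -10, 1L,
         ifelse(d <= -5, 2L,
         ifelse(d <= -2, 3L,
         ifelse(d < 2, 4L,
         ifelse(d < 5, 5L,
         ifelse(d < 10, 6L, 7L))))))
  factor(DIFF_BAND_LABELS[idx], levels = DIFF_BAND_LABELS)
}

RISK_BIN_LABELS <- c("<10", "10-15", "15-20", ">=20")

# Left-closed risk bins in percentage points: [0,10), [10,15), [15,20), [20,100].
risk_bin <- function(risk_pct) {
  cut(risk_pct, breaks = c(-Inf, 10, 15, 20, Inf), right = FALSE,
      labels = RISK_BIN_LABELS)
}

icc_a1_pair <- function(x, y) {
  n <- length(x); k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0) return(NA_real_)
  (msr - mse) / denom
}

#' Pairwise intraclass correlation between risk methods
#'
#' Two-way, absolute-agreement, single-measure ICC (the ICC(A,1) case) computed
#' per pair from the mean squares of the two-way persons-by-methods layout.
#' Unlike the Pearson correlation, this penalises a systematic offset between
#' two methods — the relevant property when a fixed treatment threshold is
#' applied to either one.
#'
#' @param scores n x k numeric matrix (or data.frame) of per-person risks, one
#'   column per method, no missing entries, n >= 3.
#' @return symmetric k x k matrix with unit diagonal; pairs with zero total
#'   variance are `NA` and listed in the `"degenerate"` attribute.
#' @export
icc_agreement <- function(scores) {
  m <- as.matrix(scores)
  if (nrow(m) < 3) stop("ICC needs at least 3 persons")
  if (anyNA(m)) stop("scores contain missing entries")
  k <- ncol(m)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(m), colnames(m))
  degenerate <- character(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- icc_a1_pair(m[, i], m[, j])
    if (is.na(v)) degenerate <- c(degenerate, paste(colnames(m)[i], colnames(m)[j], sep = ":"))
    out[i, j] <- out[j, i] <- v
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Concordance of two risk methods as difference bands
#'
#' Differences `A - B` in percentage points are tabulated into the seven fixed
#' bands; the row carries the mean predicted risk of each method, the mean
#' difference and the percentage of persons per band. Swapping A and B mirrors
#' the bands exactly.
#'
#' @param risks_a,risks_b aligned per-person risks (probability scale).
#' @param comparator,reference method labels for the output row.
#' @return one-row data.frame with means and one `pct_*` column per band.
#' @export
difference_band_table <- function(risks_a, risks_b,
                                  comparator = "A", reference = "B") {
  if (length(risks_a) != length(risks_b))
    stop("risk vectors are not aligned")
  d <- 100 * (risks_a - risks_b)
  bands <- table(diff_band(d))
  pct <- 100 * as.numeric(bands) / length(d)
  out <- data.frame(comparator = comparator, reference = reference,
                    mean_comparator = 100 * mean(risks_a),
                    mean_reference = 100 * mean(risks_b),
                    mean_difference = mean(d),
                    stringsAsFactors = FALSE)
  for (i in seq_along(DIFF_BAND_LABELS)) out[[paste0("pct_", DIFF_BAND_LABELS[i])]] <- pct[i]
  out
}

# Equal-frequency group assignment by stable (risk, person_id) order; sizes
# differ by at most 1 and ties never straddle groups non-deterministically.
vigintile_groups <- function(risk, person_id, groups = 20) {
  n <- length(risk)
  ord <- order(risk, person_id)
  sizes <- rep(n %/% groups, groups) + (seq_len(groups) <= n %% groups)
  g <- integer(n)
  g[ord] <- rep(seq_len(groups), times = sizes)
  g
}

#' Calibration by vigintiles of predicted risk
#'
#' Ranks persons by predicted risk into `groups` equal-frequency groups and
#' compares the mean predicted risk with the observed Aalen-Johansen cumulative
#' incidence at the horizon in each group.
#'
#' @param predicted data.frame `person_id`, `risk` (probability scale), or a
#'   named numeric vector.
#' @param followup follow-up table aligned by `person_id`.
#' @param horizon years.
#' @param groups number of equal-frequency groups (default 20 vigintiles).
#' @return data.frame per group: `vigintile`, `n`, `mean_predicted`,
#'   `observed`, `se_observed`, `difference` (all in percentage points).
#' @export
vigintile_calibration <- function(predicted, followup, horizon = 10, groups = 20) {
  pr <- normalize_pred(predicted)
  if (nrow(pr) < groups) stop("need at least one person per group")
  ord <- match(pr$person_id, followup$person_id)
  if (anyNA(ord)) stop("predictions contain persons absent from follow-up")
  fu <- followup[ord, , drop = FALSE]
  g <- vigintile_groups(pr$risk, pr$person_id, groups)
  rows <- lapply(seq_len(groups), function(i) {
    sel <- g == i
    aj <- observed_risk_aalen_johansen(fu[sel, , drop = FALSE], horizon)
    data.frame(vigintile = i, n = sum(sel),
               mean_predicted = 100 * mean(pr$risk[sel]),
               observed = 100 * aj$estimate, se_observed = 100 * aj$se,
               difference = 100 * mean(pr$risk[sel]) - 100 * aj$estimate)
  })
  do.call(rbind, rows)
}

#' Per-vigintile difference-band profile for a pair of methods
#'
#' The distribution of the comparator-minus-reference difference over the seven
#' bands, within each vigintile of the reference method's predicted risk (the
#' ranking can be switched with `rank_by`).
#'
#' @param pred_comparator,pred_reference per-person risks (probability scale),
#'   data.frames `person_id`,`risk` or named vectors, aligned person sets.
#' @param groups number of vigintiles.
#' @param rank_by `"reference"` (default) or `"comparator"`.
#' @return tidy data.frame `vigintile`, `band`, `percentage`.
#' @export
vigintile_band_profile <- function(pred_comparator, pred_reference, groups = 20,
                                   rank_by = c("reference", "comparator")) {
  rank_by <- match.arg(rank_by)
  pc <- normalize_pred(pred_comparator)
  pr <- normalize_pred(pred_reference)
  ord <- match(pc$person_id, pr$person_id)
  if (anyNA(ord)) stop("person sets differ between methods")
  pr <- pr[ord, , drop = FALSE]
  rank_risk <- if (rank_by == "reference") pr$risk else pc$risk
  g <- vigintile_groups(rank_risk, pc$person_id, groups)
  d <- 100 * (pc$risk - pr$risk)
  bands <- diff_band(d)
  rows <- lapply(seq_len(groups), function(i) {
    tab <- table(bands[g == i])
    data.frame(vigintile = i, band = factor(DIFF_BAND_LABELS, levels = DIFF_BAND_LABELS),
               percentage = 100 * as.numeric(tab) / sum(g == i))
  })
  do.call(rbind, rows)
}

#' Mean risk differences stratified by risk-factor levels
#'
#' For each level of each listed factor: the mean comparator-minus-reference
#' difference in percentage points and the percentage of persons whose absolute
#' difference is below 2 points. Derived banded factors (`age_band`,
#' `records_band`, `bmi_band`, `calendar_period`, plus `smoking`/`ethnicity`
#' with an explicit unknown level) are available by name.
#'
#' @param risks_a,risks_b aligned per-person risks (probability scale).
#' @param cohort cohort table aligned with the risk vectors.
#' @param factors character vector of cohort column names or derived factors.
#' @return data.frame `factor`, `level`, `n`, `mean_difference`, `pct_within_2`.
#' @export
stratified_differences <- function(risks_a, risks_b, cohort, factors) {
  stopifnot(length(risks_a) == nrow(cohort), length(risks_b) == nrow(cohort))
  d <- 100 * (risks_a - risks_b)
  fr <- as.data.frame(cohort)
  fr$age_band <- age_band(cohort$age_at_index)
  fr$records_band <- records_band(cohort$records_prior_year)
  fr$bmi_band <- bmi_band(cohort$bmi)
  fr$calendar_period <- calendar_period(calendar_year_of(cohort$index_date))
  fr$smoking <- with_unknown(cohort$smoking)
  rows <- list()
  for (f in factors) {
    x <- fr[[f]]
    if (is.null(x)) stop("unknown stratification factor: ", f)
    x <- with_unknown(x)
    for (lev in levels(x)) {
      sel <- x == lev
      if (!any(sel)) { warning("empty level ", f, "=", lev, " omitted"); next }
      rows[[length(rows) + 1]] <- data.frame(
        factor = f, level = lev, n = sum(sel),
        mean_difference = mean(d[sel]),
        pct_within_2 = 100 * mean(abs(d[sel]) < 2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Consistency of a threshold classification across methods
#'
#' For each method taken as reference: among the persons it classifies positive
#' (at or above the threshold for `direction = "ge"`, strictly below for
#' `"lt"`), the percentage for whom 0, 1, ..., k-1 of the other methods agree.
#'
#' @param scores n x k matrix/data.frame of per-person risks (probability
#'   scale), k >= 2, columns named by method.
#' @param threshold probability threshold (e.g. 0.20 for high, 0.15 for low).
#' @param direction `"ge"` (high risk) or `"lt"` (low risk).
#' @return data.frame per reference method: `n_positive` and `pct_agree_0` ...
#'   `pct_agree_<k-1>`; rows sum to 100. A reference with no positives yields
#'   an NA row flagged in `"empty_reference"`.
#' @export
threshold_consistency <- function(scores, threshold, direction = c("ge", "lt")) {
  direction <- match.arg(direction)
  m <- as.matrix(scores)
  k <- ncol(m)
  if (k < 2) stop("need at least two methods")
  pos <- if (direction == "ge") m >= threshold else m < threshold
  empty <- character(0)
  rows <- lapply(seq_len(k), function(j) {
    sel <- pos[, j]
    out <- data.frame(reference = colnames(m)[j], n_positive = sum(sel))
    agree <- rowSums(pos[sel, -j, drop = FALSE])
    tab <- table(factor(agree, levels = 0:(k - 1)))
    pct <- if (sum(sel) > 0) 100 * as.numeric(tab) / sum(sel) else rep(NA_real_, k)
    if (sum(sel) == 0) empty <<- c(empty, colnames(m)[j])
    for (i in 0:(k - 1)) out[[paste0("pct_agree_", i)]] <- pct[i + 1]
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "empty_reference") <- empty
  out
}

#' Predicted risk at the index date for persons who later developed CVD
#'
#' Restricts to cases (follow-up event = CVD) and tabulates their predicted
#' 10-year risks over the bins <10, 10-15, 15-20, >=20 percentage points
#' (left-closed) per method.
#'
#' @param scores n x k matrix/data.frame of per-person risks (probability
#'   scale) aligned with `followup`.
#' @param followup follow-up table.
#' @return data.frame per method: `n_cases`, count and percentage per bin.
#' @export
case_capture <- function(scores, followup) {
  m <- as.matrix(scores)
  stopifnot(nrow(m) == nrow(followup))
  cases <- followup$event == "cvd"
  if (!any(cases)) stop("no CVD cases in follow-up")
  rows <- lapply(seq_len(ncol(m)), function(j) {
    bins <- table(risk_bin(100 * m[cases, j]))
    out <- data.frame(method = colnames(m)[j], n_cases = sum(cases))
    for (b in RISK_BIN_LABELS) {
      out[[paste0("n_", b)]] <- as.numeric(bins[b])
      out[[paste0("pct_", b)]] <- 100 * as.numeric(bins[b]) / sum(cases)
    }
    out
  })
  do.call(rbind, rows)
}

#' Secular trend in CVD incidence by calendar year
#'
#' Age- and sex-adjusted rate ratios of CVD per calendar year of the index
#' date, relative to the earliest year, from a cause-specific proportional
#' hazards model with calendar-year indicators.
#'
#' @param followup follow-up table.
#' @param cohort aligned cohort (provides calendar year and adjusters).
#' @param adjusters covariates kept in the model (default age and sex).
#' @param cause event of interest.
#' @return data.frame `year`, `rr`, `lower`, `upper`, `se_log` (reference year
#'   has rr = 1 and NA interval).
#' @export
secular_trend <- function(followup, cohort, adjusters = c("age_at_index", "sex"),
                          cause = "cvd") {
  ord <- match(followup$person_id, cohort$person_id)
  if (anyNA(ord)) stop("followup contains persons absent from the cohort")
  co <- cohort[ord, , drop = FALSE]
  year <- calendar_year_of(co$index_date)
  years <- sort(unique(year))
  if (length(years) < 2) stop("secular trend needs at least two calendar years")
  fy <- factor(year, levels = years)
  frame <- cr_covariate_frame(co)
  adj <- build_design(frame, adjusters)$X
  X <- cbind(stats::model.matrix(~ fy)[, -1, drop = FALSE], adj)
  status <- as.integer(followup$event == cause)
  fit <- survival::coxph(survival::Surv(followup$time, status) ~ X, ties = "efron",
                         control = survival::coxph.control(iter.max = 50))
  cf <- stats::coef(fit)[seq_len(length(years) - 1)]
  se <- sqrt(diag(fit$var))[seq_len(length(years) - 1)]
  data.frame(
    year = years,
    rr = c(1, exp(cf)),
    lower = c(NA, exp(cf - 1.96 * se)),
    upper = c(NA, exp(cf + 1.96 * se)),
    se_log = c(NA, se), row.names = NULL)
}

#' Compare CVD incidence between imputed-value and measured-value persons
#'
#' Adjusted hazard ratio of CVD for persons whose value of each variable is
#' missing (hence imputed downstream) versus measured. Under missingness that
#' is random given the adjusters the ratio should be compatible with 1; under
#' informative missingness it should not.
#'
#' @param followup follow-up table.
#' @param cohort aligned cohort *before* imputation (carries the NAs).
#' @param variables variables whose missingness indicator is tested.
#' @param adjusters covariates kept in the model.
#' @return data.frame per variable: `n_missing`, `n_measured`, `hr`, `lower`,
#'   `upper`, `se_log`.
#' @export
imputed_vs_measured <- function(followup, cohort,
                                variables = c("bmi", "sbp", "chol_hdl_ratio", "smoking"),
                                adjusters = c("age_at_index", "sex")) {
  ord <- match(followup$person_id, cohort$person_id)
  if (anyNA(ord)) stop("followup contains persons absent from the cohort")
  co <- cohort[ord, , drop = FALSE]
  status <- as.integer(followup$event == "cvd")
  if (sum(status) == 0) stop("no CVD events; hazard ratio undefined")
  frame <- cr_covariate_frame(co)
  adj <- build_design(frame, adjusters)$X
  y <- survival::Surv(followup$time, status)
  rows <- lapply(variables, function(v) {
    miss <- as.numeric(is.na(co[[v]]))
    if (all(miss == 0) || all(miss == 1))
      stop("variable '", v, "': one of the missing/measured groups is empty")
    X <- cbind(missing = miss, adj)
    fit <- survival::coxph(y ~ X, ties = "efron")
    b <- stats::coef(fit)[1]; se <- sqrt(fit$var[1, 1])
    data.frame(variable = v, n_missing = sum(miss), n_measured = sum(miss == 0),
               hr = exp(b), lower = exp(b - 1.96 * se), upper = exp(b + 1.96 * se),
               se_log = se, stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

normalize_pred <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(all(c("person_id", "risk") %in% names(p) | c("person_id", "risk") %in% names(p)))
    nm <- if ("risk" %in% names(p)) "risk" else setdiff(names(p), "person_id")[1]
    return(data.frame(person_id = as.character(p$person_id), risk = p[[nm]],
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(p))) names(p) <- as.character(seq_along(p))
  data.frame(person_id = names(p), risk = as.numeric(p), stringsAsFactors = FALSE)
}
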