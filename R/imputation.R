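# Chained-equation multiple imputation of smoking status, systolic blood
# pressure, cholesterol/HDL ratio and BMI, and Rubin's-rules pooling.
#
# The imputation models condition on the full risk-factor roster plus the
# outcome information: CVD occurrence, non-CVD death, follow-up time and the
# event-by-time interactions. Continuous targets use Bayesian linear
# regression draws (posterior draw of sigma^2 and beta, then a noise draw);
# smoking uses a multinomial regression draw. Observed values are never
# altered.

IMPUTE_TARGETS <- c("smoking", "sbp", "chol_hdl_ratio", "bmi")

# Numeric predictor frame for the imputation models (everything except the
# four targets themselves; targets are appended per-equation during cycling).
imputation_predictors <- function(cohort, followup) {
  stopifnot(identical(cohort$person_id, followup$person_id))
  ev_cvd <- as.numeric(followup$event == "cvd")
  ev_death <- as.numeric(followup$event == "death_other")
  fut <- followup$time
  data.frame(
    age = cohort$age_at_index,
    sex_male = as.numeric(cohort$sex == "male"),
    eth_black = as.numeric(cohort$ethnicity == "black"),
    eth_indian = as.numeric(cohort$ethnicity == "indian"),
    eth_other = as.numeric(cohort$ethnicity == "other"),
    eth_unknown = as.numeric(cohort$ethnicity == "unknown"),
    deprivation = as.numeric(cohort$deprivation_quintile),
    tht = as.numeric(cohort$treated_hypertension),
    diabetes = as.numeric(cohort$diabetes),
    af = as.numeric(cohort$atrial_fibrillation),
    crd = as.numeric(cohort$chronic_renal_disease),
    ra = as.numeric(cohort$rheumatoid_arthritis),
    lvh = as.numeric(cohort$lvh),
    fh = as.numeric(cohort$family_history_chd),
    records_log = log1p(cohort$records_prior_year),
    calendar = calendar_year_of(cohort$index_date) - 2004,
    ev_cvd = ev_cvd, ev_death = ev_death, fut = fut,
    ev_cvd_fut = ev_cvd * fut, ev_death_fut = ev_death * fut
  )
}

# Encode current values of the non-active targets as numeric columns.
target_columns <- function(cohort, exclude) {
  cols <- list()
  if (!"smoking" %in% exclude && "smoking" %in% names(cohort)) {
    cols$smk_past <- as.numeric(cohort$smoking == "past")
    cols$smk_current <- as.numeric(cohort$smoking == "current")
  }
  for (v in setdiff(c("sbp", "chol_hdl_ratio", "bmi"), exclude))
    cols[[v]] <- as.numeric(cohort[[v]])
  if (length(cols) == 0) return(NULL)
  as.data.frame(cols)
}

# Drop rank-deficient columns of X (collinear predictors) with a warning.
drop_aliased <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    keep <- q$pivot[seq_len(q$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("dropping collinear imputation predictor(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

# One Bayesian linear-regression imputation draw (optionally PMM).
impute_continuous <- function(y, X, miss, pmm = FALSE, pmm_k = 5L) {
  Xo <- drop_aliased(X[!miss, , drop = FALSE])
  Xm <- X[miss, colnames(Xo), drop = FALSE]
  yo <- y[!miss]
  n <- nrow(Xo); p <- ncol(Xo)
  fit <- stats::lm.fit(Xo, yo)
  rss <- sum(fit$residuals^2)
  df <- max(n - p, 1)
  sigma2_star <- rss / stats::rchisq(1, df)
  XtX <- crossprod(Xo)
  ch <- chol(XtX + diag(1e-10, p))
  beta_star <- fit$coefficients + backsolve(ch, stats::rnorm(p)) * sqrt(sigma2_star)
  mu_mis <- drop(Xm %*% beta_star)
  if (!pmm) return(mu_mis + stats::rnorm(sum(miss)) * sqrt(sigma2_star))
  # predictive mean matching: sample one of the pmm_k observed donors whose
  # fitted mean is nearest to the missing person's drawn mean
  mu_obs <- drop(Xo %*% beta_star)
  ord <- order(mu_obs)
  mu_sorted <- mu_obs[ord]
  y_sorted <- yo[ord]
  pos <- findInterval(mu_mis, mu_sorted)
  vapply(seq_along(mu_mis), function(i) {
    lo <- max(1, pos[i] - pmm_k)
    hi <- min(length(y_sorted), pos[i] + pmm_k)
    cand <- lo:hi
    d <- abs(mu_sorted[cand] - mu_mis[i])
    donors <- cand[order(d)][seq_len(min(pmm_k, length(cand)))]
    y_sorted[sample(donors, 1)]
  }, numeric(1))
}

impute_smoking <- function(cohort, X, miss) {
  dat <- as.data.frame(X[, -1, drop = FALSE])  # multinom adds its own intercept
  dat$.y <- cohort$smoking
  fit <- nnet::multinom(.y ~ ., data = dat[!miss, , drop = FALSE],
                        trace = FALSE, maxit = 200)
  pr <- stats::predict(fit, newdata = dat[miss, , drop = FALSE], type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = sum(miss), byrow = FALSE,
                                     dimnames = list(NULL, fit$lev))
  lev <- colnames(pr)
  u <- stats::runif(sum(miss))
  cum <- t(apply(pr, 1, cumsum))
  pick <- 1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
  factor(lev[pick], levels = SMOKING_LEVELS)
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of the cohort. Targets are smoking status
#' (3-level multinomial), systolic blood pressure, cholesterol/HDL ratio and
#' BMI (Bayesian linear draws, or predictive-mean matching with
#' `method = "pmm"` to avoid implausible values). The predictor set is the full
#' risk-factor roster plus CVD occurrence, non-CVD death, follow-up time and
#' the event-by-time interactions. Each of the `m` chains runs `cycles`
#' burn-in sweeps; a trace of imputed-value means per cycle is kept for
#' convergence checking. The cigarettes-per-day band is completed conditionally
#' for persons imputed as current smokers.
#'
#' @param cohort cohort with missing values in the target columns.
#' @param m number of imputed datasets (default 5).
#' @param seed integer seed; chains are independent and reproducible.
#' @param followup follow-up table from [derive_followup()]; derived from the
#'   cohort when omitted.
#' @param targets subset of the four target variables to impute.
#' @param cycles chained-equation burn-in sweeps per chain (default 10).
#' @param method `"norm"` for normal-model draws, `"pmm"` for predictive-mean
#'   matching on the continuous targets.
#' @return an `imputation_set`: list with elements `m`, `datasets` (list of
#'   completed cohorts), `targets`, `method`, `seed`, `models` and a `trace`
#'   array of imputed means.
#' @export
impute <- function(cohort, m = 5, seed = 1, followup = NULL,
                   targets = IMPUTE_TARGETS, cycles = 10,
                   method = c("norm", "pmm")) {
  method <- match.arg(method)
  stopifnot(m >= 1)
  targets <- match.arg(targets, IMPUTE_TARGETS, several.ok = TRUE)
  if (is.null(followup)) followup <- derive_followup(cohort)
  miss <- lapply(targets, function(v) is.na(cohort[[v]]))
  names(miss) <- targets
  for (v in targets) {
    if (all(miss[[v]])) stop("target '", v, "' has no observed values")
  }
  active <- targets[vapply(miss, any, logical(1))]
  base_pred <- imputation_predictors(cohort, followup)

  cig_p <- NULL
  if ("smoking" %in% active) {
    obs_cur <- !is.na(cohort$smoking) & cohort$smoking == "current" &
      !is.na(cohort$cigs_per_day) & cohort$cigs_per_day != "none"
    cig_p <- if (any(obs_cur)) table(droplevels(factor(cohort$cigs_per_day[obs_cur],
                                                       levels = CIGS_LEVELS[-1])))
             else stats::setNames(rep(1, 3), CIGS_LEVELS[-1])
  }

  datasets <- vector("list", m)
  trace <- list()
  for (j in seq_len(m)) {
    set.seed(child_seed(seed, 100 + j))
    dat <- cohort
    # initialise each missing value by a random draw from the observed values
    for (v in active) {
      obs <- which(!miss[[v]]); mis <- which(miss[[v]])
      dat[[v]][mis] <- dat[[v]][sample(obs, length(mis), replace = TRUE)]
    }
    tr <- matrix(NA_real_, nrow = cycles, ncol = length(active),
                 dimnames = list(NULL, active))
    for (cy in seq_len(cycles)) {
      for (v in active) {
        others <- target_columns(dat, exclude = v)
        X <- cbind(`(Intercept)` = 1,
                   as.matrix(if (is.null(others)) base_pred else cbind(base_pred, others)))
        if (v == "smoking") {
          dat$smoking[miss$smoking] <- impute_smoking(dat, X, miss$smoking)
          tr[cy, v] <- mean(dat$smoking[miss$smoking] == "current")
        } else {
          dat[[v]][miss[[v]]] <- impute_continuous(as.numeric(dat[[v]]), X, miss[[v]],
                                                   pmm = method == "pmm")
          tr[cy, v] <- mean(dat[[v]][miss[[v]]])
        }
      }
    }
    if ("smoking" %in% active) {
      # conditional completion of the cigarettes band for imputed smokers
      imp_smk <- which(miss$smoking)
      now_cur <- imp_smk[dat$smoking[imp_smk] == "current"]
      dat$cigs_per_day[imp_smk] <- "none"
      if (length(now_cur) > 0)
        dat$cigs_per_day[now_cur] <- factor(
          sample(names(cig_p), length(now_cur), replace = TRUE, prob = cig_p),
          levels = CIGS_LEVELS)
    }
    datasets[[j]] <- dat
    trace[[j]] <- tr
  }

  structure(list(
    m = m, datasets = datasets, targets = targets, method = method,
    seed = seed, cycles = cycles,
    models = paste("target ~ risk factors + CVD occurrence + non-CVD death +",
                   "follow-up time + event-by-time interactions + other targets"),
    trace = trace
  ), class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d completed datasets (%s draws, %d cycles)\n",
              x$m, x$method, x$cycles))
  cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}

#' Persist an imputation set as m cohort CSVs plus a JSON manifest
#' @param iset an `imputation_set`.
#' @param dir output directory (created if needed).
#' @export
write_imputation_set <- function(iset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(iset$m)
  for (j in seq_len(iset$m)) {
    files[j] <- file.path(dir, sprintf("imputed_%02d.csv", j))
    write_cohort(iset$datasets[[j]], files[j])
  }
  jsonlite::write_json(
    list(m = iset$m, seed = iset$seed, targets = iset$targets,
         method = iset$method, cycles = iset$cycles, models = iset$models,
         files = basename(files)),
    file.path(dir, "imputation_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Point estimate `Qbar = mean(estimates)`; within-imputation variance
#' `Wbar = mean(variances)`; between-imputation variance `B = var(estimates)`;
#' total `T = Wbar + (1 + 1/m) B`; small-sample degrees of freedom
#' `(m - 1)(1 + Wbar / ((1 + 1/m) B))^2`; 95% CI from the t distribution.
#'
#' @param estimates m point estimates of one scalar quantity.
#' @param variances m squared standard errors.
#' @return a `pooled_estimate` with elements `point`, `within_var`,
#'   `between_var`, `total_var`, `dof`, `ci95`, `m`.
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling needs m >= 2 estimates")
  if (length(variances) != m) stop("estimates and variances must have equal length")
  if (any(variances < 0)) stop("variances must be non-negative")
  qbar <- mean(estimates)
  wbar <- mean(variances)
  b <- stats::var(estimates)
  total <- wbar + (1 + 1 / m) * b
  dof <- if (b > 0) (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2 else Inf
  half <- stats::qt(0.975, dof) * sqrt(total)
  structure(list(point = qbar, within_var = wbar, between_var = b,
                 total_var = total, dof = dof,
                 ci95 = c(qbar - half, qbar + half), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> %.6g (95%% CI %.6g to %.6g), T = %.6g, dof = %.1f\n",
              x$point, x$ci95[1], x$ci95[2], x$total_var, x$dof))
  invisible(x)
}

#' Average per-person risk tables across imputed datasets
#'
#' Per-person pooled risk is the arithmetic mean over the m datasets. Count and
#' percentage tables downstream are instead computed per dataset and then
#' averaged (see [build_report()]); which mode produced a table is recorded in
#' its metadata.
#'
#' @param tables list of wide prediction tables (identical person sets).
#' @return one wide table of pooled risks, attribute `"pooling"` = "mean_risk".
#' @export
pool_predictions <- function(tables) {
  stopifnot(length(tables) >= 1)
  ids <- tables[[1]]$person_id
  cols <- setdiff(names(tables[[1]]), "person_id")
  for (tb in tables[-1]) {
    if (!identical(sort(tb$person_id), sort(ids)))
      stop("person sets differ across imputed prediction tables")
  }
  aligned <- lapply(tables, function(tb) {
    tb <- tb[match(ids, tb$person_id), , drop = FALSE]
    as.matrix(tb[cols])
  })
  avg <- Reduce(`+`, aligned) / length(aligned)
  out <- data.frame(person_id = ids, avg, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "pooling") <- "mean_risk"
  out
}
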