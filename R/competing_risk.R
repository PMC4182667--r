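# Individual 10-year CVD risk from cause-specific proportional-hazards models
# with the competing risk of non-CVD death. Each cause is fitted as a Cox model
# (Efron ties, Breslow baseline at the stratum covariate means) treating the
# other cause as censoring; the absolute risk is the product-integral
# cumulative incidence F_cvd(t|x) = sum_{u <= t} S(u-|x) dH_cvd(u|x) with
# S(u-|x) = prod_{v < u} (1 - dH_cvd(v|x) - dH_death(v|x)), so that
# F_cvd + F_death + S = 1 holds exactly at every event time.

FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional-polynomial basis
#'
#' Powers come from the standard set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}; power 0
#' means the natural log, and a repeated power (p, p) means (x^p, x^p log x).
#' The input is shifted/scaled to be strictly positive before transforming.
#'
#' @param x numeric vector.
#' @param powers one or two powers.
#' @param shift,scale applied as `(x + shift) / scale` before the transform.
#' @return matrix with one column per power.
#' @export
fp_basis <- function(x, powers, shift = 0, scale = 1) {
  xx <- (x + shift) / scale
  if (any(!is.na(xx) & xx <= 0))
    stop("fractional polynomial input not strictly positive after shift")
  one <- function(p) if (p == 0) log(xx) else xx^p
  b1 <- one(powers[1])
  if (length(powers) == 1) return(cbind(fp1 = b1))
  b2 <- if (powers[2] == powers[1]) b1 * log(xx) else one(powers[2])
  cbind(fp1 = b1, fp2 = b2)
}

# Cohort columns plus derived model covariates usable in fits.
cr_covariate_frame <- function(cohort) {
  fr <- as.data.frame(cohort)
  fr$calendar <- calendar_year_of(cohort$index_date) - 2004
  fr$records_log <- log1p(cohort$records_prior_year)
  fr$records_band <- records_band(cohort$records_prior_year)
  fr$ethnicity <- factor(as.character(cohort$ethnicity), levels = ETHNICITY_LEVELS)
  fr$ethnicity_unknown <- as.numeric(cohort$ethnicity == "unknown")
  fr
}

#' Default covariate set for the cause-specific models
#'
#' The risk-factor roster plus calendar year at index, log consultation count
#' and an unrecorded-ethnicity indicator — the data-driven predictors that
#' published scores do not carry. The `"desk"` set omits the rarest comorbidity
#' flags and minor ethnicity levels, which at desk-scale cohort sizes carry too
#' few events for a stable partial-likelihood maximum; `"full"` is the complete
#' roster for large cohorts.
#'
#' @param set `"desk"` (default) or `"full"`.
#' @return character vector of covariate names.
#' @export
default_cr_covariates <- function(set = c("desk", "full")) {
  set <- match.arg(set)
  desk <- c("age_at_index", "sex", "smoking", "sbp", "chol_hdl_ratio", "bmi",
            "treated_hypertension", "diabetes", "family_history_chd",
            "deprivation_quintile", "ethnicity_unknown", "records_log",
            "calendar")
  if (set == "desk") return(desk)
  c(setdiff(desk, "ethnicity_unknown"),
    "atrial_fibrillation", "chronic_renal_disease", "rheumatoid_arthritis",
    "lvh", "ethnicity")
}

# Build the numeric design matrix: fp bases for covariates with a transform,
# treatment-coded dummies for factors (levels fixed by xlevels for reuse at
# prediction time), plain numeric otherwise.
build_design <- function(frame, covariates, fp = list(), xlevels = list()) {
  cols <- list()
  for (cov in covariates) {
    x <- frame[[cov]]
    if (is.null(x)) stop("unknown model covariate: ", cov)
    if (anyNA(x)) stop("model covariate '", cov, "' has missing values; impute first")
    if (!is.null(fp[[cov]])) {
      tr <- fp[[cov]]
      b <- fp_basis(as.numeric(x), tr$powers, tr$shift %||% 0, tr$scale %||% 1)
      for (k in seq_len(ncol(b))) cols[[paste0(cov, ".fp", k)]] <- b[, k]
    } else if (is.factor(x) || is.character(x)) {
      lev <- xlevels[[cov]] %||% levels(factor(x))
      xlevels[[cov]] <- lev
      for (l in lev[-1]) cols[[paste0(cov, "=", l)]] <- as.numeric(as.character(x) == l)
    } else {
      cols[[cov]] <- as.numeric(x)
    }
  }
  X <- if (length(cols) > 0) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(frame), ncol = 0)
  list(X = X, xlevels = xlevels)
}

#' Fit a cause-specific proportional-hazards model
#'
#' Cox partial likelihood with Efron tie handling, treating events of the other
#' cause as censored at their time (the cause-specific hazard convention). The
#' baseline cumulative hazard is the Breslow estimator at the covariate means
#' of the fitted design. Covariates that are constant in the data are dropped
#' with a warning and reported with coefficient zero.
#'
#' @param followup follow-up table (`person_id`, `time`, `event`).
#' @param cohort covariate source, aligned by `person_id`.
#' @param cause `"cvd"` or `"death_other"`.
#' @param covariates character vector of covariate names from the cohort or
#'   the derived set (`calendar`, `records_log`, `records_band`).
#' @param fp named list of fractional-polynomial transforms (from
#'   [select_fractional_polynomial()]) keyed by covariate.
#' @param stratum label recorded on the fit (e.g. `"female 50-59"`).
#' @return a `cause_specific_fit`: coefficients, design means, baseline
#'   cumulative-hazard step function, factor levels, log partial likelihood,
#'   convergence flag.
#' @export
fit_cause_specific <- function(followup, cohort, cause = c("cvd", "death_other"),
                               covariates = default_cr_covariates(),
                               fp = list(), stratum = "all") {
  cause <- match.arg(cause)
  ord <- match(followup$person_id, cohort$person_id)
  if (anyNA(ord)) stop("followup contains persons absent from the cohort")
  frame <- cr_covariate_frame(cohort[ord, , drop = FALSE])
  status <- as.integer(followup$event == cause)
  if (sum(status) == 0) stop("no events of cause '", cause, "' in stratum ", stratum)

  des <- build_design(frame, covariates, fp)
  X <- des$X
  dropped <- character(0)
  if (ncol(X) > 0) {
    const <- apply(X, 2, function(v) max(v) - min(v) == 0)
    if (any(const)) {
      dropped <- colnames(X)[const]
      warning("degenerate covariate(s) constant in stratum ", stratum, ": ",
              paste(dropped, collapse = ", "), " (coefficient set to 0)")
      X <- X[, !const, drop = FALSE]
    }
    # a binary indicator whose exposed (or unexposed) group has no events has a
    # monotone partial likelihood; drop it rather than report an infinite HR
    if (ncol(X) > 0) {
      sep <- vapply(seq_len(ncol(X)), function(j) {
        v <- X[, j]
        u <- unique(v)
        if (length(u) > 2) return(FALSE)
        d <- sum(status == 1 & v == max(u))
        d == 0 || d == sum(status)
      }, logical(1))
      if (any(sep)) {
        dropped <- c(dropped, colnames(X)[sep])
        warning("covariate(s) separated from events in stratum ", stratum, ": ",
                paste(colnames(X)[sep], collapse = ", "), " (coefficient set to 0)")
        X <- X[, !sep, drop = FALSE]
      }
    }
  }

  y <- survival::Surv(followup$time, status)
  converged <- TRUE
  fit <- withCallingHandlers(
    if (ncol(X) > 0)
      survival::coxph(y ~ X, ties = "efron",
                      control = survival::coxph.control(eps = 1e-10, iter.max = 50))
    else survival::coxph(y ~ 1, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) converged <<- FALSE
      invokeRestart("muffleWarning")
    })

  coef_used <- if (ncol(X) > 0) stats::setNames(unname(stats::coef(fit)), colnames(X))
               else stats::setNames(numeric(0), character(0))
  # an essentially infinite coefficient (monotone likelihood) is not a usable fit
  if (anyNA(coef_used) || any(abs(coef_used) > 15)) converged <- FALSE
  means <- if (ncol(X) > 0) stats::setNames(unname(fit$means), colnames(X))
           else stats::setNames(numeric(0), character(0))
  bh <- survival::basehaz(fit, centered = TRUE)

  se_used <- if (ncol(X) > 0) stats::setNames(sqrt(diag(fit$var)), colnames(X))
             else stats::setNames(numeric(0), character(0))
  structure(list(
    cause = cause, stratum = stratum, covariates = covariates, fp = fp,
    xlevels = des$xlevels, coef = coef_used, se = se_used, means = means,
    dropped = dropped,
    baseline = data.frame(time = bh$time, hazard = bh$hazard),
    n = nrow(frame), nevent = sum(status),
    loglik = unname(fit$loglik), converged = converged
  ), class = "cause_specific_fit")
}

#' @export
print.cause_specific_fit <- function(x, ...) {
  cat(sprintf("<cause_specific_fit> cause %s, stratum %s: n = %d, events = %d, %s\n",
              x$cause, x$stratum, x$n, x$nevent,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$coef) > 0) print(round(x$coef, 4))
  invisible(x)
}

# Centred linear predictor of a fit for new persons.
cr_linear_predictor <- function(fit, cohort) {
  frame <- cr_covariate_frame(cohort)
  X <- build_design(frame, fit$covariates, fit$fp, fit$xlevels)$X
  keep <- names(fit$coef)
  if (length(keep) == 0) return(numeric(nrow(frame)))
  drop(sweep(X[, keep, drop = FALSE], 2, fit$means[keep]) %*% fit$coef[keep])
}

#' Predict the 10-year cumulative incidence of CVD for individuals
#'
#' Combines the two cause-specific fits into the product-integral cumulative
#' incidence. Baseline-hazard increments of both causes are merged on a common
#' event-time grid (coarsened to at most `max_steps` bins when very fine, by
#' summing increments within bins); for each person the discrete cause-specific
#' hazards `dH_k(u|x) = dH0k(u) exp(lp_k)` drive the recursion
#' `F_k += S(u-) dH_k`, `S *= 1 - dH_cvd - dH_death`, which conserves
#' `F_cvd + F_death + S = 1` exactly. A horizon beyond the last observed event
#' time is flagged `extrapolated` (the cumulative hazard is held at its last
#' step). With `fit_death = NULL` the competing hazard is zero and the result
#' is the single-cause (Kaplan-Meier complement) risk.
#'
#' @param fit_cvd,fit_death `cause_specific_fit` objects for the two causes.
#' @param cohort persons to predict for.
#' @param horizon years (default 10).
#' @param max_steps grid-coarsening bound (default 1024).
#' @param chunk persons per block in the vectorised recursion.
#' @return data.frame `person_id`, `horizon`, `cif_cvd`, `cif_death`, `surv`,
#'   `extrapolated`.
#' @export
predict_cif <- function(fit_cvd, fit_death = NULL, cohort, horizon = 10,
                        max_steps = 1024L, chunk = 5000L) {
  if (!fit_cvd$converged) stop("CVD cause-specific fit did not converge")
  if (!is.null(fit_death) && !fit_death$converged)
    stop("competing-cause fit did not converge")

  inc <- function(fit) {
    if (is.null(fit)) return(data.frame(time = numeric(0), dh = numeric(0)))
    data.frame(time = fit$baseline$time, dh = diff(c(0, fit$baseline$hazard)))
  }
  ic <- inc(fit_cvd); id_ <- inc(fit_death)
  last_time <- suppressWarnings(max(c(ic$time, id_$time)))
  extrapolated <- is.finite(last_time) && horizon > last_time

  grid <- sort(unique(c(ic$time[ic$time <= horizon], id_$time[id_$time <= horizon])))
  map_inc <- function(tab) {
    out <- numeric(length(grid))
    keep <- tab$time <= horizon
    out[match(tab$time[keep], grid)] <- tab$dh[keep]
    out
  }
  dHc <- map_inc(ic); dHd <- map_inc(id_)
  if (length(grid) > max_steps) {
    bin <- ceiling(seq_along(grid) * max_steps / length(grid))
    dHc <- as.numeric(rowsum(dHc, bin))
    dHd <- as.numeric(rowsum(dHd, bin))
  }

  lp1 <- cr_linear_predictor(fit_cvd, cohort)
  lp2 <- if (is.null(fit_death)) NULL else cr_linear_predictor(fit_death, cohort)
  n <- nrow(cohort)
  cif_c <- cif_d <- surv <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    e1 <- exp(lp1[idx])
    e2 <- if (is.null(lp2)) numeric(length(idx)) else exp(lp2[idx])
    sprev <- rep(1, length(idx))
    Fc <- Fd <- numeric(length(idx))
    for (g in seq_along(dHc)) {
      dc <- dHc[g] * e1
      dd <- dHd[g] * e2
      dt <- dc + dd
      over <- dt > 1  # discrete hazard mass cannot exceed 1
      if (any(over)) {
        sc <- 1 / dt[over]
        dc[over] <- dc[over] * sc; dd[over] <- dd[over] * sc; dt[over] <- 1
      }
      Fc <- Fc + sprev * dc
      Fd <- Fd + sprev * dd
      sprev <- sprev * (1 - dt)
    }
    cif_c[idx] <- Fc; cif_d[idx] <- Fd; surv[idx] <- sprev
  }
  data.frame(person_id = cohort$person_id, horizon = horizon,
             cif_cvd = cif_c, cif_death = cif_d, surv = surv,
             extrapolated = extrapolated, stringsAsFactors = FALSE)
}

#' Closed-test fractional-polynomial selection for one covariate
#'
#' Finds the best-fitting FP2 and FP1 transforms by partial likelihood over the
#' standard power set, then applies the closed test: best FP2 against the
#' covariate-free model (4 df), against the linear term (3 df), and against the
#' best FP1 (2 df), each at level `alpha`, returning the simplest adequate
#' transform.
#'
#' @inheritParams fit_cause_specific
#' @param covariate continuous covariate to transform.
#' @param adjusters other covariates kept in every candidate model.
#' @param alpha test level (default 0.05).
#' @return an `fp_transform`: `covariate`, `powers`, `shift`, `scale`,
#'   `selected` (linear / FP1 / FP2), and the closed-test p-values.
#' @export
select_fractional_polynomial <- function(followup, cohort, covariate,
                                         cause = c("cvd", "death_other"),
                                         adjusters = character(0), alpha = 0.05) {
  cause <- match.arg(cause)
  ord <- match(followup$person_id, cohort$person_id)
  frame <- cr_covariate_frame(cohort[ord, , drop = FALSE])
  status <- as.integer(followup$event == cause)
  y <- survival::Surv(followup$time, status)
  x <- as.numeric(frame[[covariate]])
  shift <- if (min(x) <= 0) -min(x) + max(1, stats::sd(x) / 10) else 0
  scale <- 1
  if (length(unique(x)) <= 2) {
    warning("too few distinct values for an FP transform; using linear")
    return(structure(list(covariate = covariate, powers = 1, shift = 0, scale = 1,
                          selected = "linear", pvalues = NULL), class = "fp_transform"))
  }
  adj <- build_design(frame, adjusters)$X

  ll <- function(basis) {
    X <- cbind(basis, adj)
    f <- survival::coxph(y ~ X, ties = "efron")
    unname(f$loglik[2])
  }
  ll_null <- {
    f <- if (ncol(adj) > 0) survival::coxph(y ~ adj, ties = "efron")
         else survival::coxph(y ~ 1, ties = "efron")
    unname(f$loglik[length(f$loglik)])
  }
  ll_lin <- ll(fp_basis(x, 1, shift, scale))

  fp1 <- lapply(FP_POWERS, function(p) list(powers = p, ll = ll(fp_basis(x, p, shift, scale))))
  best1 <- fp1[[which.max(vapply(fp1, `[[`, numeric(1), "ll"))]]
  pairs <- expand.grid(i = seq_along(FP_POWERS), j = seq_along(FP_POWERS))
  pairs <- pairs[pairs$i <= pairs$j, ]
  fp2 <- lapply(seq_len(nrow(pairs)), function(r) {
    pw <- FP_POWERS[c(pairs$i[r], pairs$j[r])]
    list(powers = pw, ll = ll(fp_basis(x, pw, shift, scale)))
  })
  best2 <- fp2[[which.max(vapply(fp2, `[[`, numeric(1), "ll"))]]

  p_any <- stats::pchisq(2 * (best2$ll - ll_null), df = 4, lower.tail = FALSE)
  p_nonlin <- stats::pchisq(2 * (best2$ll - ll_lin), df = 3, lower.tail = FALSE)
  p_fp2 <- stats::pchisq(2 * (best2$ll - best1$ll), df = 2, lower.tail = FALSE)
  pv <- c(any_effect = p_any, nonlinear = p_nonlin, fp2_vs_fp1 = p_fp2)

  sel <- if (p_any >= alpha || p_nonlin >= alpha)
    list(powers = 1, selected = "linear")
  else if (p_fp2 >= alpha) list(powers = best1$powers, selected = "FP1")
  else list(powers = best2$powers, selected = "FP2")

  structure(list(covariate = covariate, powers = sel$powers,
                 shift = if (identical(sel$selected, "linear")) 0 else shift,
                 scale = scale, selected = sel$selected, pvalues = pv),
            class = "fp_transform")
}

#' Nonparametric observed cumulative incidence (Aalen-Johansen)
#'
#' The competing-risk life-table estimate of the probability of a first CVD
#' event by `horizon`, treating non-CVD death as a competing event, with its
#' standard error.
#'
#' @param followup follow-up table (`time`, `event`).
#' @param horizon years.
#' @return list `estimate`, `se`, `horizon`, `n`, `n_event`.
#' @export
observed_risk_aalen_johansen <- function(followup, horizon = 10) {
  stopifnot(nrow(followup) > 0)
  ev <- factor(as.character(followup$event), levels = EVENT_LEVELS)
  if (sum(ev == "cvd") == 0)
    return(list(estimate = 0, se = 0, horizon = horizon, n = nrow(followup), n_event = 0))
  sf <- survival::survfit(survival::Surv(followup$time, ev) ~ 1)
  sm <- summary(sf, times = horizon, extend = TRUE)
  k <- match("cvd", sf$states)
  list(estimate = unname(sm$pstate[1, k]), se = unname(sm$std.err[1, k]),
       horizon = horizon, n = nrow(followup), n_event = sum(ev == "cvd"))
}

#' Persist / restore a cause-specific fit as JSON
#' @param fit a `cause_specific_fit`.
#' @param path JSON path.
#' @export
write_cr_fit <- function(fit, path) {
  out <- unclass(fit)
  out$coef <- as.list(out$coef)    # keep names (JSON objects, not arrays)
  out$means <- as.list(out$means)
  out$se <- as.list(out$se)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_cr_fit
#' @export
read_cr_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coef <- unlist(x$coef) %||% stats::setNames(numeric(0), character(0))
  x$means <- unlist(x$means) %||% stats::setNames(numeric(0), character(0))
  x$se <- unlist(x$se) %||% stats::setNames(numeric(0), character(0))
  x$fp <- lapply(x$fp, function(tr) { tr$powers <- as.numeric(tr$powers); tr })
  x$baseline <- as.data.frame(x$baseline)
  x$covariates <- as.character(x$covariates)
  x$dropped <- as.character(x$dropped %||% character(0))
  structure(x, class = "cause_specific_fit")
}
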