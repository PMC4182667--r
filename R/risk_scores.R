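# Coefficient-file-driven engine for Cox-form 10-year risk equations:
# risk = 1 - S0(t)^exp(L), L = sum_j beta_j (g_j(x_j) - g_j(xbar_j)).
# The Framingham / ASSIGN / QRISK2 family all have this functional form; a spec
# file supplies the terms, centring constants and sex-specific baseline
# survival, so the engine never hard-codes published coefficients.

SCORE_TRANSFORMS <- c("identity", "centered", "log", "categorical", "interaction")

#' Load and validate a risk-score specification
#'
#' A spec is JSON with fields `name`, `horizon` (years), `baseline_survival`
#' (either a single number or `{"male": s, "female": s}`), `terms` (array of
#' term objects), optional `applicability` (`age_min`, `age_max`, `sex`) and
#' optional `missing_policy` (per covariate: a default value / category, or
#' `"reject"`).
#'
#' Term object fields: `covariate` (a cohort column), `transform` (one of
#' identity, centered, log, categorical, interaction), `coefficient`,
#' `reference` (centring constant, for continuous transforms), `level` (for
#' categorical terms), `sex` (optional: term applies to one sex only), and for
#' interactions `with` + `with_level` (the modifying indicator).
#'
#' @param path JSON file path.
#' @return a validated `risk_score_spec`.
#' @export
load_score_spec <- function(path) {
  if (!file.exists(path)) stop("score spec file not found: ", path)
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_score_spec(spec)
}

#' @rdname load_score_spec
#' @param spec a spec list (e.g. parsed from JSON).
#' @export
validate_score_spec <- function(spec) {
  fail <- function(field, why) stop("invalid score spec field '", field, "': ", why)
  if (is.null(spec$name) || !nzchar(spec$name)) fail("name", "missing")
  if (is.null(spec$horizon) || spec$horizon <= 0) fail("horizon", "must be > 0")
  s0 <- spec$baseline_survival
  if (is.null(s0)) fail("baseline_survival", "missing")
  s0v <- unlist(s0)
  if (!all(is.finite(s0v)) || any(s0v <= 0) || any(s0v >= 1))
    fail("baseline_survival", "must lie strictly in (0, 1)")
  if (is.list(s0) && !all(names(s0) %in% SEX_LEVELS))
    fail("baseline_survival", "names must be male/female")
  if (is.null(spec$terms) || length(spec$terms) == 0) fail("terms", "empty")
  for (i in seq_along(spec$terms)) {
    tm <- spec$terms[[i]]
    where <- paste0("terms[", i, "]")
    if (is.null(tm$covariate)) fail(where, "no covariate")
    if (!tm$covariate %in% names(COHORT_COLUMNS))
      fail(where, paste0("unknown covariate '", tm$covariate, "'"))
    if (is.null(tm$transform) || !tm$transform %in% SCORE_TRANSFORMS)
      fail(where, paste0("unknown transform '", tm$transform %||% "NULL", "'"))
    if (is.null(tm$coefficient) || !is.finite(tm$coefficient)) fail(where, "no coefficient")
    if (tm$transform == "categorical" && is.null(tm$level)) fail(where, "categorical needs level")
    if (tm$transform == "interaction" && is.null(tm$with)) fail(where, "interaction needs 'with'")
  }
  structure(spec, class = "risk_score_spec")
}

#' @export
print.risk_score_spec <- function(x, ...) {
  cat(sprintf("<risk_score_spec> %s: %d terms, horizon %g y\n",
              x$name, length(x$terms), x$horizon))
  invisible(x)
}

#' Serialise a risk-score spec to JSON
#' @param spec a `risk_score_spec`.
#' @param path output path.
#' @export
write_score_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# g_j(x) for one term on a resolved covariate vector. Continuous transforms are
# centred at the term's reference; categorical terms contribute the level
# indicator (reference contribution 0).
term_value <- function(tm, x) {
  tr <- tm$transform
  if (tr %in% c("identity", "centered", "interaction")) {
    # an interaction term centres its continuous base; the indicator of the
    # modifying covariate is applied by the caller
    if (tr == "interaction" && !is.null(tm$level))
      return(as.numeric(tolower(as.character(x)) == tolower(as.character(tm$level))))
    ref <- tm$reference %||% 0
    return(as.numeric(x) - ref)
  }
  if (tr == "log") {
    xv <- as.numeric(x)
    if (any(!is.na(xv) & xv <= 0))
      stop("covariate '", tm$covariate, "' outside log-transform domain (<= 0)")
    ref <- tm$reference %||% 1
    if (ref <= 0) stop("log-transform reference must be > 0")
    return(log(xv) - log(ref))
  }
  if (tr == "categorical")
    return(as.numeric(tolower(as.character(x)) == tolower(as.character(tm$level))))
  stop("unhandled transform: ", tr)
}

# Resolve one covariate column under the spec's missing policy; returns the
# column with substitutions applied and a logical vector of unresolved rows.
resolve_covariate <- function(cohort, cov, policy) {
  x <- cohort[[cov]]
  miss <- is.na(x)
  if (!any(miss)) return(list(x = x, reject = rep(FALSE, nrow(cohort))))
  rule <- policy[[cov]]
  if (is.null(rule) || identical(rule, "reject"))
    return(list(x = x, reject = miss))
  if (is.factor(x)) x[miss] <- rule else x[miss] <- as.numeric(rule)
  list(x = x, reject = rep(FALSE, nrow(cohort)))
}

#' Evaluate a Cox-form risk score on a cohort
#'
#' Computes the linear predictor `L = sum beta_j (g_j(x_j) - g_j(xbar_j))` and
#' `risk = 1 - S0(horizon)^exp(L)` per person, with sex-specific baseline
#' survival and per-sex terms where the spec defines them. Persons outside the
#' spec's applicability or with a missing covariate whose policy is `reject`
#' are returned with `NA` risk and listed in the `"rejects"` attribute rather
#' than dropped silently.
#'
#' @param spec a `risk_score_spec`.
#' @param cohort a cohort table (complete or imputed; the missing policy covers
#'   stray NAs).
#' @return data.frame `person_id`, `score`, `risk` with attribute `"rejects"`.
#' @export
evaluate_score <- function(spec, cohort) {
  spec <- if (inherits(spec, "risk_score_spec")) spec else validate_score_spec(spec)
  n <- nrow(cohort)
  policy <- spec$missing_policy %||% list()
  # smoking "unknown" maps to never by default unless the policy says otherwise
  if (is.null(policy$smoking)) policy$smoking <- "never"

  reject <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  app <- spec$applicability %||% list()
  if (!is.null(app$age_min)) {
    out <- cohort$age_at_index < app$age_min | cohort$age_at_index > (app$age_max %||% Inf)
    reason[out & !reject] <- "outside age applicability"
    reject <- reject | out
  }
  if (!is.null(app$sex) && app$sex != "both") {
    out <- cohort$sex != app$sex
    reason[out & !reject] <- "sex not covered"
    reject <- reject | out
  }

  L <- numeric(n)
  for (tm in spec$terms) {
    rc <- resolve_covariate(cohort, tm$covariate, policy)
    reason[rc$reject & !reject] <- paste0("missing covariate '", tm$covariate, "'")
    reject <- reject | rc$reject
    g <- term_value(tm, rc$x)
    if (tm$transform == "interaction") {
      w <- resolve_covariate(cohort, tm$with, policy)
      reason[w$reject & !reject] <- paste0("missing covariate '", tm$with, "'")
      reject <- reject | w$reject
      ind <- as.numeric(tolower(as.character(w$x)) ==
                          tolower(as.character(tm$with_level %||% TRUE)))
      g <- g * ind
    }
    if (!is.null(tm$sex)) g <- g * as.numeric(cohort$sex == tm$sex)
    g[is.na(g)] <- 0  # rejected rows; masked below
    L <- L + tm$coefficient * g
  }

  s0 <- spec$baseline_survival
  s0_vec <- if (is.list(s0)) {
    unlist(s0)[as.character(cohort$sex)]
  } else rep(as.numeric(s0), n)
  risk <- 1 - s0_vec^exp(L)
  risk[reject] <- NA_real_

  out <- data.frame(person_id = cohort$person_id, score = spec$name, risk = unname(risk),
                    stringsAsFactors = FALSE)
  attr(out, "rejects") <- data.frame(person_id = cohort$person_id[reject],
                                     score = rep(spec$name, sum(reject)),
                                     reason = reason[reject],
                                     stringsAsFactors = FALSE)
  out
}

#' Evaluate several risk scores on one cohort
#'
#' Applies [evaluate_score()] for each spec to the same cohort (hence the same
#' imputed covariate values across scores) and returns a wide per-person table
#' with one risk column per score. Per-person evaluation failures are collected
#' into the `"rejects"` attribute, not dropped silently.
#'
#' @param specs list of `risk_score_spec` (or paths, loaded on the fly).
#' @param cohort a cohort table.
#' @return data.frame `person_id` plus one column per score name; attribute
#'   `"rejects"` collects per-person rejections across scores.
#' @export
evaluate_all <- function(specs, cohort) {
  if (length(specs) == 0) stop("at least one score spec is required")
  if (nrow(cohort) == 0) stop("cohort is empty")
  specs <- lapply(specs, function(s) if (is.character(s)) load_score_spec(s) else s)
  out <- data.frame(person_id = cohort$person_id, stringsAsFactors = FALSE)
  rejects <- list()
  for (s in specs) {
    res <- evaluate_score(s, cohort)
    out[[s$name]] <- res$risk
    rejects[[s$name]] <- attr(res, "rejects")
  }
  attr(out, "rejects") <- do.call(rbind, unname(rejects))
  out
}

#' Write a long per-person prediction table as CSV
#' @param predictions wide table from [evaluate_all()].
#' @param path output CSV path.
#' @export
write_predictions <- function(predictions, path) {
  long <- stats::reshape(predictions, direction = "long",
                         varying = setdiff(names(predictions), "person_id"),
                         v.names = "risk", timevar = "score",
                         times = setdiff(names(predictions), "person_id"),
                         idvar = "person_id")
  rownames(long) <- NULL
  utils::write.csv(long[order(long$score, long$person_id), ], path,
                   row.names = FALSE, na = "")
  invisible(path)
}
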