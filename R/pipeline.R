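# End-to-end orchestration at desk scale: cohort (synthetic or CSV) ->
# eligibility -> missingness -> multiple imputation -> risk-score evaluation +
# competing-risk fit/predict per imputed dataset -> pooling -> agreement
# report, with artifacts and a manifest on disk.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"csv"` (read one).
#' @param generator a [generator_config()] (synthetic mode).
#' @param cohort_csv path to a cohort CSV (csv mode).
#' @param score_specs paths to risk-score spec JSON files; defaults to the
#'   three packaged synthetic fixtures.
#' @param m number of imputed datasets (>= 2; default 5).
#' @param seed master seed for imputation and any stochastic stage.
#' @param horizon prediction horizon in years (default 10).
#' @param thresholds list with `high` (default 0.20) and `low` (0.15).
#' @param stratify `"none"` (single competing-risk model) or `"sex_age"`
#'   (separate fits by sex and age group).
#' @param age_group_cuts age-group lower bounds for `"sex_age"` (default 50, 60
#'   giving 35-49 / 50-59 / 60-74).
#' @param cr_covariates covariates of the cause-specific models.
#' @param fp named list of `fp_transform`s for the competing-risk model.
#' @param apply_missingness inject the configured missingness into a synthetic
#'   cohort before imputation (default TRUE).
#' @param groups number of calibration vigintiles.
#' @param strat_factors factors of the stratified difference table.
#' @return a validated `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv"),
                       generator = generator_config(n_persons = 2000, seed = 101),
                       cohort_csv = NULL,
                       score_specs = default_score_specs(),
                       m = 5, seed = 42, horizon = 10,
                       thresholds = list(high = 0.20, low = 0.15),
                       stratify = c("none", "sex_age"),
                       age_group_cuts = c(50, 60),
                       cr_covariates = default_cr_covariates(),
                       fp = list(),
                       apply_missingness = TRUE,
                       groups = 20,
                       strat_factors = c("sex", "age_band", "calendar_period",
                                         "ethnicity", "diabetes", "lvh",
                                         "records_band")) {
  cfg <- list(mode = match.arg(mode), generator = generator,
              cohort_csv = cohort_csv, score_specs = score_specs, m = m,
              seed = seed, horizon = horizon, thresholds = thresholds,
              stratify = match.arg(stratify), age_group_cuts = age_group_cuts,
              cr_covariates = cr_covariates, fp = fp,
              apply_missingness = apply_missingness, groups = groups,
              strat_factors = strat_factors)
  if (cfg$m < 2) stop("invalid run config: m must be >= 2 for pooling")
  if (cfg$horizon <= 0) stop("invalid run config: horizon must be > 0")
  th <- cfg$thresholds
  if (th$high <= 0 || th$high >= 1 || th$low <= 0 || th$low >= 1)
    stop("invalid run config: thresholds must lie in (0, 1)")
  if (cfg$mode == "csv" && is.null(cfg$cohort_csv))
    stop("invalid run config: csv mode needs cohort_csv")
  structure(cfg, class = "run_config")
}

#' Packaged synthetic score-spec fixtures
#' @return paths of the three shipped spec files.
#' @export
default_score_specs <- function() {
  files <- c("framingham_synthetic.json", "assign_synthetic.json",
             "qrisk2_synthetic.json")
  vapply(files, function(f) system.file("extdata", f, package = "riskconcord",
                                        mustWork = TRUE), character(1),
         USE.NAMES = FALSE)
}

# Fit both cause-specific models, optionally by sex x age-group stratum, and
# predict each person's CIF at the horizon from their own stratum's fits.
fit_and_predict_cr <- function(followup, cohort, config) {
  covs <- config$cr_covariates
  if (config$stratify == "none") {
    f_cvd <- fit_cause_specific(followup, cohort, "cvd", covs, fp = config$fp)
    f_dth <- fit_cause_specific(followup, cohort, "death_other", covs, fp = config$fp)
    pred <- predict_cif(f_cvd, f_dth, cohort, horizon = config$horizon)
    return(list(pred = pred, fits = list(all = list(cvd = f_cvd, death_other = f_dth))))
  }
  cuts <- config$age_group_cuts
  agegrp <- cut(cohort$age_at_index, breaks = c(-Inf, cuts, Inf), right = FALSE)
  stratum <- interaction(cohort$sex, agegrp, drop = TRUE, sep = " ")
  covs_s <- setdiff(covs, "sex")
  fits <- list()
  preds <- list()
  for (s in levels(stratum)) {
    sel <- stratum == s
    co_s <- cohort[sel, , drop = FALSE]
    fu_s <- followup[match(co_s$person_id, followup$person_id), , drop = FALSE]
    f_cvd <- fit_cause_specific(fu_s, co_s, "cvd", covs_s, fp = config$fp, stratum = s)
    f_dth <- fit_cause_specific(fu_s, co_s, "death_other", covs_s, fp = config$fp, stratum = s)
    fits[[s]] <- list(cvd = f_cvd, death_other = f_dth)
    preds[[s]] <- predict_cif(f_cvd, f_dth, co_s, horizon = config$horizon)
  }
  pred <- do.call(rbind, preds)
  pred <- pred[match(cohort$person_id, pred$person_id), , drop = FALSE]
  rownames(pred) <- NULL
  list(pred = pred, fits = fits)
}

# Element-wise mean of the numeric cells of structurally identical tables
# (per-imputed-dataset analysis, then averaging — the default pooling mode for
# count/percentage tables).
average_tables <- function(tables) {
  t1 <- tables[[1]]
  num <- vapply(t1, is.numeric, logical(1))
  for (tb in tables[-1]) {
    stopifnot(identical(dim(tb), dim(t1)),
              identical(tb[!num], t1[!num]))
  }
  out <- t1
  for (cn in names(t1)[num])
    out[[cn]] <- Reduce(`+`, lapply(tables, `[[`, cn)) / length(tables)
  out
}

average_matrices <- function(mats) Reduce(`+`, mats) / length(mats)

#' Assemble the full agreement report
#'
#' Computes every evaluation table from per-imputed-dataset prediction tables:
#' the pairwise ICC matrix, difference-band concordance per ordered method
#' pair, vigintile calibration of the competing-risk predictions, per-vigintile
#' band profiles of each score against the competing-risk risks, stratified
#' differences, threshold-consistency tables at the high and low thresholds,
#' case capture, and the risk-distribution summary. Each table is computed per
#' dataset and its numeric cells averaged across the m datasets
#' (`pooling = "per_dataset_average"`); pass a single-element list to analyse
#' pooled risks instead.
#'
#' @param pred_tables list (length m) of wide prediction tables: `person_id`,
#'   one column per score and a `competing_risk` column (probability scale).
#' @param followup follow-up table.
#' @param cohort cohort used for stratification (typically the pre-imputation
#'   cohort so "unknown" levels are visible).
#' @param config a [run_config()].
#' @return a `comparison_report` (list of tables).
#' @export
build_report <- function(pred_tables, followup, cohort, config = run_config()) {
  methods <- setdiff(names(pred_tables[[1]]), "person_id")
  per <- lapply(pred_tables, function(tb) {
    stopifnot(identical(tb$person_id, cohort$person_id))
    mat <- as.matrix(tb[methods])
    rownames(mat) <- tb$person_id
    icc <- icc_agreement(mat)
    conc <- do.call(rbind, lapply(methods, function(a)
      do.call(rbind, lapply(setdiff(methods, a), function(b)
        difference_band_table(mat[, a], mat[, b], a, b)))))
    cr <- data.frame(person_id = tb$person_id, risk = tb$competing_risk)
    calib <- vigintile_calibration(cr, followup, config$horizon, config$groups)
    prof <- do.call(rbind, lapply(setdiff(methods, "competing_risk"), function(a) {
      p <- vigintile_band_profile(
        data.frame(person_id = tb$person_id, risk = mat[, a]), cr, config$groups)
      p$comparator <- a
      p
    }))
    strat <- do.call(rbind, lapply(setdiff(methods, "competing_risk"), function(a) {
      s <- stratified_differences(mat[, a], mat[, "competing_risk"], cohort,
                                  config$strat_factors)
      s$comparator <- a
      s
    }))
    cons_hi <- threshold_consistency(mat, config$thresholds$high, "ge")
    cons_lo <- threshold_consistency(mat, config$thresholds$low, "lt")
    cases <- case_capture(mat, followup)
    dist <- summarize_risk_distribution(cr, cohort)
    list(icc = icc, concordance = conc, calibration = calib, profile = prof,
         stratified = strat, consistency_high = cons_hi,
         consistency_low = cons_lo, case_capture = cases,
         risk_distribution = dist)
  })
  structure(list(
    icc = average_matrices(lapply(per, `[[`, "icc")),
    concordance = average_tables(lapply(per, `[[`, "concordance")),
    calibration = average_tables(lapply(per, `[[`, "calibration")),
    profile = average_tables(lapply(per, `[[`, "profile")),
    stratified = average_tables(lapply(per, `[[`, "stratified")),
    consistency_high = average_tables(lapply(per, `[[`, "consistency_high")),
    consistency_low = average_tables(lapply(per, `[[`, "consistency_low")),
    case_capture = average_tables(lapply(per, `[[`, "case_capture")),
    risk_distribution = average_tables(lapply(per, `[[`, "risk_distribution")),
    pooling = if (length(pred_tables) > 1) "per_dataset_average" else "pooled_risks",
    m = length(pred_tables), methods = methods
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d methods, pooling = %s (m = %d)\n",
              length(x$methods), x$pooling, x$m))
  cat("  ICC matrix:\n")
  print(round(x$icc, 3))
  invisible(x)
}

#' Write a comparison report as CSV tables plus a JSON bundle
#' @param report a `comparison_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tb, name)
    utils::write.csv(tb, file.path(dir, paste0(name, ".csv")), row.names = FALSE, na = "")
  w(as.data.frame(report$icc), "icc")
  for (nm in c("concordance", "calibration", "profile", "stratified",
               "consistency_high", "consistency_low", "case_capture",
               "risk_distribution"))
    w(report[[nm]], nm)
  jsonlite::write_json(
    lapply(unclass(report), function(x) if (is.matrix(x)) as.data.frame(x) else x),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns", pretty = TRUE)
  invisible(dir)
}

#' Distribution of predicted 10-year risk by age group and sex
#'
#' Counts and percentages of persons in the risk bins <10 / 10-15 / 15-20 /
#' >=20 percentage points, with mean, median and 5th/95th percentiles (linear
#' interpolation between order statistics), overall and within age-group and
#' sex strata.
#'
#' @param predicted per-person risks (data.frame `person_id`,`risk` or named
#'   vector, probability scale).
#' @param cohort aligned cohort.
#' @return data.frame, one row per stratum.
#' @export
summarize_risk_distribution <- function(predicted, cohort) {
  pr <- normalize_pred(predicted)
  ord <- match(pr$person_id, cohort$person_id)
  if (anyNA(ord)) stop("predictions contain persons absent from the cohort")
  co <- cohort[ord, , drop = FALSE]
  strata <- list(
    All = rep(TRUE, nrow(co)),
    `age 35-49` = co$age_at_index < 50,
    `age 50+` = co$age_at_index >= 50,
    men = co$sex == "male",
    women = co$sex == "female")
  rows <- lapply(names(strata), function(s) {
    sel <- strata[[s]]
    if (!any(sel)) return(NULL)
    r <- 100 * pr$risk[sel]
    bins <- table(risk_bin(r))
    out <- data.frame(stratum = s, n = sum(sel))
    for (b in RISK_BIN_LABELS) {
      out[[paste0("n_", b)]] <- as.numeric(bins[b])
      out[[paste0("pct_", b)]] <- 100 * as.numeric(bins[b]) / sum(sel)
    }
    qs <- stats::quantile(r, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
    out$mean <- mean(r); out$median <- qs[2]; out$p5 <- qs[1]; out$p95 <- qs[3]
    out
  })
  do.call(rbind, rows)
}

#' Run the full evaluation pipeline
#'
#' Executes: cohort acquisition (synthetic generation or CSV), eligibility
#' filtering, follow-up derivation, missingness injection (synthetic mode),
#' chained-equation imputation (m datasets), risk-score evaluation and
#' competing-risk fit/prediction per imputed dataset, prediction pooling, the
#' bias analyses, and the agreement report. All artifacts (cohort, truth,
#' imputations, fits, predictions, report tables) are written under `out_dir`
#' together with a manifest recording seeds, the configuration and file
#' checksums; a rerun with the same configuration reproduces the artifacts
#' exactly. A failing stage aborts with a stage-named error and leaves partial
#' artifacts under `<out_dir>/failed`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the `comparison_report`, invisibly with attributes `pooled`
#'   (pooled prediction table), `fits`, `secular_trend`, `imputed_vs_measured`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_name <- "setup"
  run <- function(name, expr) {
    stage_name <<- name
    tryCatch(expr, error = function(e) {
      failed <- file.path(out_dir, "failed")
      dir.create(failed, showWarnings = FALSE)
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(failed, "FAILED.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- run("cohort", {
    if (config$mode == "synthetic") {
      ch <- generate_cohort(config$generator)
      if (config$apply_missingness)
        ch <- inject_missingness(ch, config$generator$missingness,
                                 seed = config$generator$seed)
      ch
    } else read_cohort(config$cohort_csv)
  })
  cohort <- run("eligibility", apply_eligibility(cohort))
  message(sprintf("[cohort] %d persons after eligibility", nrow(cohort)))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  if (!is.null(attr(cohort, "truth")))
    write_truth(cohort, file.path(out_dir, "truth.csv"))

  followup <- run("followup", derive_followup(cohort))
  message(sprintf("[followup] events: %s",
                  paste(names(table(followup$event)), table(followup$event),
                        sep = "=", collapse = ", ")))

  bias_tables <- run("bias_analyses", list(
    secular_trend = tryCatch(secular_trend(followup, cohort),
                             error = function(e) NULL),
    imputed_vs_measured = tryCatch(imputed_vs_measured(followup, cohort),
                                   error = function(e) NULL)))

  iset <- run("imputation",
              impute(cohort, m = config$m, seed = config$seed, followup = followup))
  write_imputation_set(iset, file.path(out_dir, "imputations"))

  specs <- run("score_specs", lapply(config$score_specs, load_score_spec))
  pred_tables <- vector("list", config$m)
  fits <- NULL
  for (j in seq_len(config$m)) {
    dat <- iset$datasets[[j]]
    scores <- run(sprintf("scores[m=%d]", j), evaluate_all(specs, dat))
    cr <- run(sprintf("competing_risk[m=%d]", j), fit_and_predict_cr(followup, dat, config))
    if (j == 1) {
      fits <- cr$fits
      for (s in names(fits)) for (cause in names(fits[[s]]))
        write_cr_fit(fits[[s]][[cause]],
                     file.path(out_dir, sprintf("fit_%s_%s.json",
                                                gsub("[^a-z0-9]+", "_", tolower(s)), cause)))
    }
    scores$competing_risk <- cr$pred$cif_cvd[match(scores$person_id, cr$pred$person_id)]
    pred_tables[[j]] <- scores
  }

  pooled <- run("pooling", pool_predictions(pred_tables))
  utils::write.csv(pooled, file.path(out_dir, "predictions_pooled.csv"),
                   row.names = FALSE, na = "")

  report <- run("report", build_report(pred_tables, followup, cohort, config))
  write_report(report, file.path(out_dir, "report"))
  if (!is.null(bias_tables$secular_trend))
    utils::write.csv(bias_tables$secular_trend,
                     file.path(out_dir, "report", "secular_trend.csv"),
                     row.names = FALSE, na = "")
  if (!is.null(bias_tables$imputed_vs_measured))
    utils::write.csv(bias_tables$imputed_vs_measured,
                     file.path(out_dir, "report", "imputed_vs_measured.csv"),
                     row.names = FALSE, na = "")

  run("manifest", {
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    sums <- tools::md5sum(files)
    jsonlite::write_json(list(
      package_version = as.character(utils::packageVersion("riskconcord")),
      seed = config$seed,
      generator_seed = if (config$mode == "synthetic") config$generator$seed else NULL,
      m = config$m, horizon = config$horizon, mode = config$mode,
      stratify = config$stratify, thresholds = config$thresholds,
      score_specs = basename(unlist(config$score_specs)),
      n_persons = nrow(cohort),
      files = as.list(stats::setNames(unname(sums),
                                      sub(paste0(out_dir, "/?"), "", names(sums), fixed = FALSE)))
    ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  })

  attr(report, "pooled") <- pooled
  attr(report, "fits") <- fits
  attr(report, "secular_trend") <- bias_tables$secular_trend
  attr(report, "imputed_vs_measured") <- bias_tables$imputed_vs_measured
  invisible(report)
}
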