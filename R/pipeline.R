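#' First-month gain flags
#'
#' Programme early-response indicators: whether a child showed *no* MUAC
#' gain and *no* weight gain between admission and the visit closest to
#' day 28 (accepted window: days 21-42). "No gain" is a gain of zero or
#' less. Children without a visit in the window, or with a missing
#' endpoint, get a missing flag.
#'
#' @param visits cleaned visit tibble.
#' @return tibble per child: `child_id`, `muac_gain_1m`, `weight_gain_1m`,
#'   `no_muac_gain_1m`, `no_weight_gain_1m`.
#' @export
first_month_gain_flags <- function(visits) {
  visits |>
    dplyr::group_by(.data$child_id) |>
    dplyr::arrange(.data$visit_date, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      day <- as.numeric(difftime(df$visit_date, df$visit_date[1],
                                 units = "days"))
      gain_at_1m <- function(x) {
        cand <- which(day >= 21 & day <= 42 & !is.na(x))
        if (!length(cand) || is.na(x[1])) return(NA_real_)
        x[cand[which.min(abs(day[cand] - 28))]] - x[1]
      }
      tibble::tibble(muac_gain_1m = gain_at_1m(df$muac_mm),
                     weight_gain_1m = gain_at_1m(df$weight_kg))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(no_muac_gain_1m = .data$muac_gain_1m <= 0,
                  no_weight_gain_1m = .data$weight_gain_1m <= 0)
}

#' Admission covariates for the prediction model
#'
#' Builds, per child, the categorical admission covariates used to model
#' response category: sex, age band (6-11 / 12-23 / 24-59 months),
#' admission MUAC band (<110 / 110-114 / 115-119 / >=120 mm), admission
#' WHZ and WAZ bands (>= -3 vs < -3), any reported morbidity over
#' follow-up, and the first-month no-gain flags.
#'
#' @param visits cleaned visit tibble with z-scores.
#' @return tibble, one row per child.
#' @export
admission_covariates <- function(visits) {
  adm <- visits |>
    dplyr::group_by(.data$child_id) |>
    dplyr::arrange(.data$visit_date, .by_group = TRUE) |>
    dplyr::summarise(
      sex = dplyr::first(.data$sex),
      age_adm_months = dplyr::first(.data$age_months),
      muac_adm = dplyr::first(.data$muac_mm),
      whz_adm = dplyr::first(.data$whz),
      waz_adm = dplyr::first(.data$waz),
      haz_adm = dplyr::first(.data$haz),
      morbidity_any = any(.data$morbidity, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      age_cat = cut(.data$age_adm_months, c(6, 12, 24, 60),
                    labels = c("6-11", "12-23", "24-59"), right = FALSE),
      muac_cat = cut(.data$muac_adm, c(-Inf, 110, 115, 120, Inf),
                     labels = c("<110", "110-114", "115-119", ">=120"),
                     right = FALSE),
      whz_cat = factor(ifelse(is.na(.data$whz_adm), NA,
                              ifelse(.data$whz_adm < -3, "<-3", ">=-3")),
                       levels = c(">=-3", "<-3")),
      waz_cat = factor(ifelse(is.na(.data$waz_adm), NA,
                              ifelse(.data$waz_adm < -3, "<-3", ">=-3")),
                       levels = c(">=-3", "<-3")),
      severity_adm = classify_severity(.data$muac_adm, .data$whz_adm)
    )
  dplyr::left_join(adm, first_month_gain_flags(visits), by = "child_id")
}

#' Compare a variable across response groups
#'
#' The descriptive-table tests: Pearson chi-square for binary/categorical
#' variables and Kruskal-Wallis for continuous ones, with group medians and
#' IQRs (continuous) or counts and percentages (categorical) reported
#' alongside.
#'
#' @param data tibble with the variable and the group column.
#' @param variable variable name (string).
#' @param group grouping column name (string).
#' @param correct continuity correction for 2x2 chi-square (default off).
#' @return list: `test` (one-row tibble: variable, test, statistic,
#'   parameter, p.value) and `summary` (per-group descriptives).
#' @export
compare_groups <- function(data, variable, group, correct = FALSE) {
  x <- data[[variable]]
  g <- as.factor(data[[group]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("compare_groups(): need >= 2 groups", call. = FALSE)
  if (is.numeric(x)) {
    ht <- stats::kruskal.test(x, g)
    summary <- tibble::tibble(group = levels(g)) |>
      dplyr::mutate(
        n = as.integer(table(g)),
        median = tapply(x, g, stats::median),
        q1 = tapply(x, g, stats::quantile, 0.25),
        q3 = tapply(x, g, stats::quantile, 0.75)
      )
    test_name <- "kruskal_wallis"
  } else {
    tab <- table(x, g)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    if (any(ht$expected < 1)) {
      warning("compare_groups(): expected cell count < 1", call. = FALSE)
    }
    summary <- tibble::as_tibble(as.data.frame(tab)) |>
      rlang::set_names(c("level", "group", "n")) |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    test_name <- "chi_squared"
  }
  list(
    test = tibble::tibble(variable = variable, test = test_name,
                          statistic = unname(ht$statistic),
                          parameter = unname(ht$parameter),
                          p.value = ht$p.value),
    summary = summary
  )
}

#' Univariate multinomial OR table
#'
#' Table-1-style output: one univariate three-category multinomial fit per
#' predictor (reference outcome: recovered), reporting per-level odds
#' ratios with 95\% CIs for both non-responder contrasts and the joint
#' Wald p-value per variable.
#'
#' @param data per-child tibble with `response_category` and the
#'   predictors.
#' @param predictors character vector of predictor column names.
#' @param outcome outcome column; default `"response_category"`.
#' @return tibble: `variable`, `y.level`, `term`, `or`, `conf.low`,
#'   `conf.high`, `wald_p`, `converged`. A fit without a finite MLE (e.g.
#'   an empty predictor-by-outcome cell separating the data) keeps its rows
#'   but reports a missing Wald p-value and `converged = FALSE`.
#' @export
univariate_or_table <- function(data, predictors,
                                outcome = "response_category") {
  purrr::map_dfr(predictors, function(v) {
    f <- stats::as.formula(paste(outcome, "~", v))
    fit <- fit_multinomial(data, f, ref = "recovered")
    wp <- if (fit$converged) wald_test(fit, v)$p.value else NA_real_
    tidy(fit, exponentiate = TRUE) |>
      dplyr::filter(.data$term != "(Intercept)") |>
      dplyr::transmute(variable = v, y.level = .data$y.level,
                       term = .data$term, or = .data$estimate,
                       conf.low = .data$conf.low,
                       conf.high = .data$conf.high, wald_p = wp,
                       converged = fit$converged)
  })
}

#' Run the full non-response re-classification pipeline
#'
#' End-to-end orchestration over a visit-level dataset (or a synthetic
#' cohort generated on the fly): z-scoring, cleaning, exit
#' re-classification, the first-quartile non-responder split, the
#' univariate OR table, the multivariate multinomial prediction model with
#' VIF screen and classification metrics, and (optionally) the per-group
#' growth-curve fits. All stage outputs are returned in one report and can
#' be written to delimited files.
#'
#' @param visits visit-level tibble; if `NULL`, a cohort is simulated from
#'   `config`.
#' @param labels study-assigned exit labels per child (required with
#'   `visits`).
#' @param config a [sim_config()] used when simulating.
#' @param lms LMS reference for z-scoring.
#' @param indicator split indicator, see [split_non_responders()].
#' @param fit_trajectories also fit MUAC/weight growth curves (slower).
#' @param out_dir optional directory; stage outputs are written there as
#'   tab-separated files.
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(visits = NULL, labels = NULL, config = sim_config(),
                         lms = synthetic_lms_reference(),
                         indicator = "muac", fit_trajectories = FALSE,
                         out_dir = NULL) {
  if (is.null(visits)) {
    cohort <- simulate_cohort(config, lms = lms)
    visits <- cohort$visits
    labels <- cohort$labels
  } else {
    cohort <- NULL
    if (is.null(labels)) stop("labels are required with supplied visits",
                              call. = FALSE)
  }
  scored <- add_zscores(visits, lms)
  cleaned <- clean_visits(scored)
  outcomes <- classify_exit(cleaned$visits, labels)
  aset <- build_analysis_set(outcomes)
  gains <- compute_gains(
    dplyr::semi_join(cleaned$visits, aset$analysis, by = "child_id"))
  split <- split_non_responders(gains, aset$analysis, indicator = indicator)
  covs <- admission_covariates(
    dplyr::semi_join(cleaned$visits, aset$analysis, by = "child_id"))
  model_data <- dplyr::left_join(split$data, covs, by = "child_id")

  or_vars <- c("sex", "age_cat", "muac_cat", "whz_cat", "waz_cat",
               "morbidity_any", "no_muac_gain_1m", "no_weight_gain_1m")
  or_table <- univariate_or_table(model_data, or_vars)

  mv_formula <- response_category ~ sex + age_cat + muac_cat + whz_cat +
    waz_cat + morbidity_any + no_muac_gain_1m + no_weight_gain_1m
  mv_fit <- fit_multinomial(model_data, mv_formula, ref = "recovered")
  mm_vars <- all.vars(mv_formula)[-1]
  cc <- model_data[stats::complete.cases(model_data[, mm_vars]), mm_vars]
  X <- stats::model.matrix(~ ., cc)[, -1, drop = FALSE]
  vif <- vif_screen(X)
  metrics <- model_metrics(mv_fit)

  curves <- NULL
  if (fit_trajectories) {
    traj_data <- cleaned$visits |>
      dplyr::inner_join(dplyr::select(model_data, "child_id",
                                      "response_category", "age_adm_months"),
                        by = "child_id") |>
      add_weeks_since_admission()
    curves <- purrr::map(
      c(muac = "muac_mm", weight = "weight_kg"),
      function(oc) {
        fit <- fit_group_curves(traj_data, oc, adjust_age = TRUE)
        predict_weekly_means(fit)
      })
  }

  report <- structure(list(
    flow = aset$flow, cleaning = cleaned$report,
    threshold = split$threshold,
    categories = dplyr::select(model_data, "child_id", "final_label",
                               "response_category"),
    or_table = or_table, model = mv_fit, vif = vif, metrics = metrics,
    curves = curves, model_data = model_data,
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(config),
                      package_version = as.character(
                        utils::packageVersion("cmamnr")),
                      r_version = R.version.string)
  ), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Write a pipeline report to delimited files
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wt(report$flow, "flow_counts")
  wt(report$cleaning$counts, "cleaning_counts")
  wt(report$threshold, "q1_threshold")
  wt(report$categories, "response_categories")
  wt(report$or_table, "univariate_or")
  wt(tidy(report$model, exponentiate = TRUE), "multivariate_model")
  wt(report$vif, "vif")
  if (!is.null(report$curves)) {
    purrr::iwalk(report$curves, function(cv, nm) {
      wt(cv, paste0("curves_", nm))
    })
  }
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("CMAM non-response pipeline report\n")
  print(x$flow)
  cat("Split threshold (", x$threshold$indicator, "): q1 =",
      x$threshold$q1, "over", x$threshold$n_used, "non-responders\n")
  print(table(x$categories$response_category))
  print(x$metrics)
  invisible(x)
}
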