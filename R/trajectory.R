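#' Weeks since admission
#'
#' Adds a `week` column: completed weeks (`floor(days / 7)`) since each
#' child's first visit.
#'
#' @param visits visit tibble with `child_id` and `visit_date`.
#' @return the tibble with a `week` integer column.
#' @export
add_weeks_since_admission <- function(visits) {
  visits |>
    dplyr::group_by(.data$child_id) |>
    dplyr::mutate(week = as.integer(floor(as.numeric(difftime(
      .data$visit_date, min(.data$visit_date), units = "days")) / 7))) |>
    dplyr::ungroup()
}

#' Fit per-group growth curves with a penalized-spline mixed GAM
#'
#' One smooth mean curve of time per response group, with group
#' intercepts, group-specific cubic P-spline smooths of week since
#' admission (second-difference penalty, so straight-line trends are
#' unpenalized), child-level random intercepts absorbed as a ridge-penalized
#' effect, and optionally a linear adjustment for age at admission (used
#' for MUAC and weight, whose level varies strongly with age). Smoothing
#' parameters are selected by GCV by default; REML is available.
#'
#' @param data visit-level tibble with columns `child_id`, `week` (see
#'   [add_weeks_since_admission()]), the outcome column, a group factor
#'   (e.g. `response_category`), and `age_adm_months` when
#'   `adjust_age = TRUE`.
#' @param outcome name of the outcome column (e.g. `"muac_mm"`).
#' @param group name of the grouping column; coerced to factor.
#' @param adjust_age include a linear admission-age term.
#' @param k basis dimension per group smooth (default 12: cubic B-splines
#'   on roughly 10 interior knots); reduced with a warning when a group has
#'   fewer distinct weeks.
#' @param method smoothing selection criterion: `"GCV.Cp"` (default) or
#'   `"REML"`; the big-data engine uses its fast-REML equivalent.
#' @param random_intercept include the child-level random intercept
#'   (default `TRUE`).
#' @param engine `"gam"` (exact, fine up to a few hundred children),
#'   `"bam"` ([mgcv::bam()] with discretised covariates, needed when the
#'   random-intercept factor has thousands of levels), or `"auto"`
#'   (default: `bam` beyond 400 children).
#' @return object of class `growth_curves_fit` wrapping the fitted
#'   [mgcv::gam()] or [mgcv::bam()] model.
#' @export
fit_group_curves <- function(data, outcome, group = "response_category",
                             adjust_age = FALSE, k = 12,
                             method = c("GCV.Cp", "REML"),
                             random_intercept = TRUE,
                             engine = c("auto", "gam", "bam")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  df <- tibble::as_tibble(data)
  stopifnot(all(c("child_id", "week", outcome, group) %in% names(df)))
  df <- df[!is.na(df[[outcome]]) & !is.na(df[[group]]), ]
  df$.group <- droplevels(as.factor(df[[group]]))
  df$.y <- df[[outcome]]
  df$child_id <- as.factor(df$child_id)

  min_weeks <- df |>
    dplyr::group_by(.data$.group) |>
    dplyr::summarise(n_wk = dplyr::n_distinct(.data$week), .groups = "drop")
  k_use <- min(k, min(min_weeks$n_wk))
  if (k_use < k) {
    warning("basis dimension reduced to ", k_use,
            " (a group has only that many distinct weeks)", call. = FALSE)
  }
  if (k_use < 4) k_use <- 4

  rhs <- if (nlevels(df$.group) > 1) {
    ".group + s(week, by = .group, bs = \"ps\", k = k_use, m = c(2, 2))"
  } else {
    "s(week, bs = \"ps\", k = k_use, m = c(2, 2))"
  }
  if (adjust_age) {
    stopifnot("age_adm_months" %in% names(df))
    rhs <- paste(rhs, "+ age_adm_months")
  }
  if (random_intercept) rhs <- paste(rhs, "+ s(child_id, bs = \"re\")")
  form <- stats::as.formula(paste(".y ~", rhs))
  if (engine == "auto") {
    engine <- if (dplyr::n_distinct(df$child_id) > 400) "bam" else "gam"
  }
  fit <- if (engine == "bam") {
    mgcv::bam(form, data = df, method = "fREML", discrete = TRUE)
  } else {
    mgcv::gam(form, data = df, method = method)
  }

  structure(list(
    gam = fit, outcome = outcome, group = group,
    group_levels = levels(df$.group),
    week_range = range(df$week),
    adjust_age = adjust_age,
    reference_age = if (adjust_age) mean(df$age_adm_months) else NA_real_,
    random_intercept = random_intercept,
    child_level = levels(df$child_id)[1],
    n_children = dplyr::n_distinct(df$child_id), n_visits = nrow(df)
  ), class = "growth_curves_fit")
}

#' Modelled weekly group means with pointwise 95\% intervals
#'
#' Evaluates the fitted group curves on a weekly grid at the population
#' level (child random intercept excluded; admission age fixed at
#' `reference_age` when the fit is age-adjusted). Intervals are pointwise
#' Wald bands from the penalized coefficient covariance. Requested weeks
#' outside the fitted range are an error: the curves are not extrapolated.
#'
#' @param fit a `growth_curves_fit`.
#' @param weeks integer weeks; default the full fitted range.
#' @param reference_age admission age (months) at which to evaluate an
#'   age-adjusted fit; default the mean admission age of the fitting data.
#' @param conf.level confidence level for the bands.
#' @return tibble: `group`, `week`, `mean`, `ci_low`, `ci_high`.
#' @export
predict_weekly_means <- function(fit, weeks = NULL, reference_age = NULL,
                                 conf.level = 0.95) {
  if (is.null(weeks)) weeks <- seq(fit$week_range[1], fit$week_range[2])
  if (any(weeks < fit$week_range[1] | weeks > fit$week_range[2])) {
    stop("predict_weekly_means(): weeks outside the fitted range ",
         fit$week_range[1], "-", fit$week_range[2],
         "; curves are not extrapolated", call. = FALSE)
  }
  grid <- tidyr::expand_grid(.group = factor(fit$group_levels,
                                             levels = fit$group_levels),
                             week = weeks)
  grid$child_id <- factor(fit$child_level,
                          levels = levels(fit$gam$model$child_id))
  if (fit$adjust_age) {
    grid$age_adm_months <- if (is.null(reference_age)) fit$reference_age
                           else reference_age
  }
  excl <- if (fit$random_intercept) "s(child_id)" else NULL
  pr <- mgcv::predict.gam(fit$gam, newdata = grid, se.fit = TRUE,
                          exclude = excl, newdata.guaranteed = TRUE)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    group = grid$.group, week = grid$week,
    mean = as.numeric(pr$fit),
    ci_low = as.numeric(pr$fit - z * pr$se.fit),
    ci_high = as.numeric(pr$fit + z * pr$se.fit)
  )
}

#' @export
print.growth_curves_fit <- function(x, ...) {
  cat("Penalized-spline growth curves for", x$outcome, "by", x$group, "\n")
  cat(x$n_children, "children,", x$n_visits, "visits; weeks",
      x$week_range[1], "to", x$week_range[2],
      if (x$adjust_age) "; age-adjusted" else "", "\n")
  invisible(x)
}

#' Tidy the smooth terms of a growth-curve fit
#' @param x a `growth_curves_fit`.
#' @param ... unused.
#' @return tibble of smooth terms: `term`, `edf`, `ref.df`, `statistic`,
#'   `p.value`.
#' @export
tidy.growth_curves_fit <- function(x, ...) {
  s <- summary(x$gam)$s.table
  tibble::tibble(term = rownames(s), edf = s[, "edf"],
                 ref.df = s[, "Ref.df"], statistic = s[, "F"],
                 p.value = s[, "p-value"])
}

#' Glance at a growth-curve fit
#' @param x a `growth_curves_fit`.
#' @param ... unused.
#' @return one-row tibble with fit-level summaries.
#' @export
glance.growth_curves_fit <- function(x, ...) {
  sm <- summary(x$gam)
  tibble::tibble(
    r.squared = sm$r.sq, deviance_explained = sm$dev.expl,
    scale = sm$scale, n_visits = x$n_visits, n_children = x$n_children
  )
}

#' Plot modelled weekly group means
#'
#' Ribbon-and-line panel of the modelled weekly means with 95\% bands,
#' one colour per response group — the standard presentation for group
#' growth trajectories.
#'
#' @param object a `growth_curves_fit`.
#' @param ... passed to [predict_weekly_means()].
#' @return a ggplot object.
#' @export
autoplot.growth_curves_fit <- function(object, ...) {
  curves <- predict_weekly_means(object, ...)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$week, y = .data$mean,
                                       colour = .data$group,
                                       fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Weeks since admission", y = object$outcome,
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
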