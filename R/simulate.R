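#' Configuration for the synthetic CMAM cohort generator
#'
#' Defaults emulate the pooled-study conditions: three latent growth
#' classes (recovering, delayed responders who grow on a near-parallel
#' track but fall short of the discharge thresholds, and non-growers with
#' essentially zero MUAC/weight drift but positive height drift), weekly
#' visits up to 16 weeks, admission MUAC centred near 119 / 111.5 / 118 mm
#' for the three classes, class-specific morbidity, geometric weekly
#' dropout, and a fifth of admissions presenting with oedema. Trajectories
#' are monotone saturating exponentials (the shape of observed group
#' curves); measurement noise is technical-error-of-measurement scale.
#'
#' @param n_children number of children.
#' @param class_proportions named proportions for recovering /
#'   delayed_responder / non_grower; must sum to 1.
#' @param max_weeks programme maximum stay (weeks).
#' @param min_stay_weeks earliest week at which discharge criteria are
#'   checked (programmes treat for a minimum period before discharging).
#' @param p_male probability of male sex.
#' @param oedema_prob probability of oedema at admission (excluded by the
#'   pipeline; generated so the exclusion branch is exercised).
#' @param dropout_hazard weekly geometric dropout hazard.
#' @param unknown_prob probability that a completer's study label is
#'   recorded as `unknown` rather than its true exit classification.
#' @param noise_sd named measurement noise SDs: `muac` (mm), `weight`
#'   (kg), `height` (cm).
#' @param morbidity_prob named per-class probability of any reported
#'   morbidity over follow-up.
#' @param seed integer seed; mandatory for reproducibility.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_children = 1000,
                       class_proportions = c(recovering = 0.86,
                                             delayed_responder = 0.10,
                                             non_grower = 0.04),
                       max_weeks = 16,
                       min_stay_weeks = 4,
                       p_male = 0.43,
                       oedema_prob = 0.20,
                       dropout_hazard = 0.01,
                       unknown_prob = 0.05,
                       noise_sd = c(muac = 2, weight = 0.15, height = 0.4),
                       morbidity_prob = c(recovering = 0.59,
                                          delayed_responder = 0.61,
                                          non_grower = 0.77),
                       seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  if (any(noise_sd < 0) || dropout_hazard < 0 || dropout_hazard >= 1) {
    stop("noise SDs must be >= 0 and dropout hazard in [0, 1)", call. = FALSE)
  }
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory", call. = FALSE)
  if (min_stay_weeks < 2 || min_stay_weeks >= max_weeks) {
    stop("min_stay_weeks must be in [2, max_weeks)", call. = FALSE)
  }
  structure(list(
    n_children = n_children, class_proportions = class_proportions,
    max_weeks = max_weeks, min_stay_weeks = min_stay_weeks,
    p_male = p_male, oedema_prob = oedema_prob,
    dropout_hazard = dropout_hazard, unknown_prob = unknown_prob,
    noise_sd = noise_sd, morbidity_prob = morbidity_prob,
    seed = as.integer(seed)
  ), class = "sim_config")
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a longitudinal CMAM cohort with planted latent classes
#'
#' Generates weekly visit series for `n_children` children, each assigned
#' a latent class. True MUAC and WHZ follow class-specific saturating
#' exponential curves (recovering children plateau above the recovery
#' thresholds, delayed responders on the same shape shifted down so they
#' plateau just short, non-growers flat); true height follows a slowly
#' rising height-for-age track, and true weight is derived from the true
#' WHZ at the true height through the LMS reference, so the pipeline's
#' z-scoring recovers the planted z-scores up to measurement noise.
#' Study-style exit labels are assigned from the observed (noisy)
#' measurements: discharge as recovered on two consecutive qualifying
#' visits (MUAC >= 125 mm or WHZ >= -2), defaulting follows a geometric
#' weekly hazard, and completers reaching the maximum stay without
#' qualifying are non-responders; a configurable fraction of completer
#' labels is recorded as `unknown`. The same config and seed give
#' bit-identical cohorts.
#'
#' @param config a [sim_config()].
#' @param lms LMS reference used to plant heights/weights; default
#'   [synthetic_lms_reference()] (use the same reference in the pipeline).
#' @return list of class `synthetic_cohort`: `visits` (ChildVisit tibble),
#'   `labels` (child_id, original_label), `truth` (latent class and
#'   noise-free admission/exit values), `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            lms = synthetic_lms_reference()) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  n <- config$n_children
  classes <- names(config$class_proportions)
  cls <- sample(classes, n, replace = TRUE, prob = config$class_proportions)

  # admission state, anchored at the three groups' observed medians, with
  # spreads wide enough to populate all four admission MUAC bands in the
  # proportions the pooled groups show
  muac0 <- dplyr::case_when(
    cls == "recovering" ~ rnorm_trunc(n, 121, 6, 95, 124.5),
    cls == "delayed_responder" ~ rnorm_trunc(n, 111.5, 6, 95, 122),
    TRUE ~ rnorm_trunc(n, 120, 6.5, 95, 124.5)
  )
  whz0 <- dplyr::case_when(
    cls == "recovering" ~ rnorm_trunc(n, -2.4, 0.5, -4.5, -0.5),
    cls == "delayed_responder" ~ rnorm_trunc(n, -3.0, 0.5, -5, -1.5),
    TRUE ~ rnorm_trunc(n, -2.9, 0.5, -5, -1.5)
  )
  haz0 <- rnorm_trunc(n, -2.7, 1.1, -6, 1)
  age0 <- pmin(pmax(stats::rlnorm(n, log(17), 0.5), 6), 59)
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  oedema <- stats::runif(n) < config$oedema_prob

  # saturating-exponential curve parameters per class
  muac_A <- dplyr::case_when(
    cls == "recovering" ~ pmax(muac0 + 10, 127),
    cls == "delayed_responder" ~ pmin(muac0 + 14, 124),
    TRUE ~ muac0
  )
  muac_tau <- dplyr::case_when(cls == "recovering" ~ 5,
                               cls == "delayed_responder" ~ 6, TRUE ~ 6)
  whz_A <- dplyr::case_when(
    cls == "recovering" ~ pmax(whz0 + 0.8, -1.7),
    cls == "delayed_responder" ~ pmin(whz0 + 1.0, -2.1),
    TRUE ~ whz0
  )
  whz_tau <- dplyr::case_when(cls == "recovering" ~ 5,
                              cls == "delayed_responder" ~ 6, TRUE ~ 6)
  haz_slope <- stats::rnorm(n, 0.02, 0.008)  # z per week; height keeps rising

  admission_date <- as.Date("2019-06-03") +
    sample.int(400, n, replace = TRUE) - 1

  child <- tibble::tibble(
    child_id = sprintf("c%05d", seq_len(n)), class = cls,
    sex = sex, age0 = age0, muac0 = muac0, whz0 = whz0, haz0 = haz0,
    muac_A = muac_A, muac_tau = muac_tau, whz_A = whz_A, whz_tau = whz_tau,
    haz_slope = haz_slope, oedema = oedema, admission_date = admission_date,
    morbid = stats::runif(n) < config$morbidity_prob[cls],
    dropout_week = if (config$dropout_hazard > 0) {
      dw <- stats::rgeom(n, config$dropout_hazard) + 1
      ifelse(dw > config$max_weeks, Inf, dw)
    } else rep(Inf, n)
  )

  grid <- tidyr::expand_grid(child, week = 0:config$max_weeks)
  grid <- grid |> dplyr::mutate(
    age_months = .data$age0 + .data$week * 7 / DAYS_PER_MONTH,
    true_muac = .data$muac_A -
      (.data$muac_A - .data$muac0) * exp(-.data$week / .data$muac_tau),
    true_whz = .data$whz_A -
      (.data$whz_A - .data$whz0) * exp(-.data$week / .data$whz_tau),
    true_haz = .data$haz0 + .data$haz_slope * .data$week
  )
  haz_ref <- lms_at(lms, "HAZ", grid$sex, grid$age_months * DAYS_PER_MONTH)
  grid$true_height <- lms_invert(grid$true_haz, haz_ref$L, haz_ref$M,
                                 haz_ref$S)
  whz_ref <- lms_at(lms, "WHZ", grid$sex, grid$true_height * 10)
  grid$true_weight <- lms_invert(grid$true_whz, whz_ref$L, whz_ref$M,
                                 whz_ref$S)

  ns <- config$noise_sd
  m <- nrow(grid)
  grid <- grid |> dplyr::mutate(
    muac_mm = round(.data$true_muac + stats::rnorm(m, 0, ns[["muac"]])),
    weight_kg = round(.data$true_weight + stats::rnorm(m, 0, ns[["weight"]]),
                      2),
    height_cm = round(.data$true_height + stats::rnorm(m, 0, ns[["height"]]),
                      1)
  )

  # observed WHZ as the study would see it, for the discharge rule
  whz_obs_ref <- lms_at(lms, "WHZ", grid$sex, grid$height_cm * 10)
  grid$whz_obs <- ifelse(
    is.na(whz_obs_ref$M), NA_real_,
    lms_zscore(pmax(grid$weight_kg, 0.1), whz_obs_ref$L, whz_obs_ref$M,
               whz_obs_ref$S)
  )

  grid <- grid |>
    dplyr::group_by(.data$child_id) |>
    dplyr::arrange(.data$week, .by_group = TRUE) |>
    dplyr::mutate(
      qualify = .data$muac_mm >= 125 |
        (!is.na(.data$whz_obs) & .data$whz_obs >= -2),
      discharge = .data$week >= config$min_stay_weeks & .data$qualify &
        dplyr::lag(.data$qualify, default = FALSE)
    ) |>
    dplyr::mutate(discharge_week = if (any(.data$discharge))
      min(.data$week[.data$discharge]) else Inf) |>
    dplyr::ungroup()

  per_child <- grid |>
    dplyr::distinct(.data$child_id, .data$class, .data$dropout_week,
                    .data$discharge_week, .data$morbid, .data$oedema)
  per_child <- per_child |> dplyr::mutate(
    exit_week = pmin(.data$discharge_week, .data$dropout_week,
                     config$max_weeks),
    original_label = dplyr::case_when(
      .data$discharge_week <= pmin(.data$dropout_week, config$max_weeks) ~
        "recovered",
      .data$dropout_week < config$max_weeks ~ "defaulter",
      TRUE ~ "non_responder"
    )
  )
  completer <- per_child$original_label %in% c("recovered", "non_responder")
  mask_unknown <- completer & stats::runif(nrow(per_child)) < config$unknown_prob
  per_child$original_label[mask_unknown] <- "unknown"

  visits <- grid |>
    dplyr::inner_join(dplyr::select(per_child, "child_id", "exit_week"),
                      by = "child_id") |>
    dplyr::filter(.data$week <= .data$exit_week) |>
    dplyr::mutate(
      visit_date = .data$admission_date + 7L * .data$week,
      study_id = "synthetic",
      morbidity = .data$morbid & stats::runif(dplyr::n()) < 0.35
    ) |>
    dplyr::select("child_id", "study_id", "visit_date", "age_months", "sex",
                  "weight_kg", "height_cm", "muac_mm", "oedema", "morbidity")

  truth <- grid |>
    dplyr::inner_join(dplyr::select(per_child, "child_id", "exit_week",
                                    "original_label"), by = "child_id") |>
    dplyr::filter(.data$week == 0 | .data$week == .data$exit_week) |>
    dplyr::group_by(.data$child_id, .data$class, .data$original_label) |>
    dplyr::summarise(
      true_muac_admission = .data$true_muac[.data$week == 0][1],
      true_muac_exit = .data$true_muac[which.max(.data$week)],
      true_whz_admission = .data$true_whz[.data$week == 0][1],
      true_whz_exit = .data$true_whz[which.max(.data$week)],
      exit_week = max(.data$week), .groups = "drop"
    ) |>
    dplyr::mutate(true_muac_gain = .data$true_muac_exit -
                    .data$true_muac_admission)

  structure(list(
    visits = visits,
    labels = dplyr::select(per_child, "child_id", "original_label"),
    truth = truth, config = config
  ), class = "synthetic_cohort")
}

#' Planted truth of a synthetic cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @return tibble with one row per child: latent `class`, noise-free
#'   admission/exit MUAC and WHZ, true MUAC gain, exit week.
#' @export
truth_labels <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$truth
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic CMAM cohort:", nrow(x$labels), "children,",
      nrow(x$visits), "visits (seed", x$config$seed, ")\n")
  print(table(x$truth$class))
  invisible(x)
}
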