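#' Classify exit outcomes, re-classifying defaulters and unknowns
#'
#' Reproduces the cohort-flow rules of the pooled analysis. Study-assigned
#' `recovered` / `non_responder` labels pass through unchanged. Children
#' with oedema at admission, and children who died or were transferred out
#' for medical reasons, are excluded. Children originally labelled
#' `defaulter` or `unknown` are re-classified from their exit anthropometry
#' when their length of stay is at least `min_los_weeks`:
#' \itemize{
#'   \item re-classified **recovered** when at least one recovery criterion
#'     is met (exit MUAC >= 125 mm or exit WHZ >= -2), with no oedema at
#'     exit and no observed criterion of severe wasting (MUAC >= 115 mm and
#'     WHZ >= -3 on the observed indicators);
#'   \item re-classified **non_responder** when every observed indicator is
#'     below both thresholds (MUAC < 125 mm and WHZ < -2);
#'   \item otherwise excluded as unclassifiable (e.g. one indicator above
#'     its recovery cut-off while the other shows severe wasting).
#' }
#' Defaulters/unknowns with a shorter stay are excluded. A missing
#' indicator cannot satisfy a recovery criterion and does not veto one.
#'
#' Exit anthropometry is taken, per indicator, from the last visit with a
#' non-missing value (MUAC and WHZ may come from different final visits).
#' Length of stay is `floor((last visit date - admission date) / 7)` weeks.
#'
#' @param visits cleaned visit tibble with z-scores; one row per visit,
#'   columns `child_id`, `visit_date`, `muac_mm`, `whz`, `oedema`.
#' @param labels tibble with one row per child: `child_id`,
#'   `original_label` in recovered / non_responder / defaulter / unknown /
#'   died / medical_transfer.
#' @param min_los_weeks minimum stay for re-classification (default 12).
#' @return tibble, one row per child: `child_id`, `original_label`,
#'   `final_label` (recovered / non_responder / excluded),
#'   `exclusion_reason`, `los_weeks`, `exit_muac`, `exit_whz`,
#'   `reclassified`.
#' @export
classify_exit <- function(visits, labels, min_los_weeks = 12) {
  stopifnot(all(c("child_id", "original_label") %in% names(labels)))
  ok_labels <- c("recovered", "non_responder", "defaulter", "unknown",
                 "died", "medical_transfer")
  if (!all(labels$original_label %in% ok_labels)) {
    stop("unknown original_label value(s): ",
         paste(setdiff(unique(labels$original_label), ok_labels),
               collapse = ", "), call. = FALSE)
  }
  last_non_missing <- function(x, d) {
    i <- which(!is.na(x))
    if (length(i)) x[max(i)] else NA_real_
  }
  per_child <- visits |>
    dplyr::group_by(.data$child_id) |>
    dplyr::arrange(.data$visit_date, .by_group = TRUE) |>
    dplyr::summarise(
      admission_date = dplyr::first(.data$visit_date),
      exit_date = dplyr::last(.data$visit_date),
      oedema_admission = dplyr::first(.data$oedema),
      oedema_exit = dplyr::last(.data$oedema),
      exit_muac = last_non_missing(.data$muac_mm, .data$visit_date),
      exit_whz = last_non_missing(.data$whz, .data$visit_date),
      n_visits = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(los_weeks = floor(as.numeric(
      difftime(.data$exit_date, .data$admission_date, units = "days")) / 7))

  out <- dplyr::left_join(labels, per_child, by = "child_id")
  muac <- out$exit_muac; whz <- out$exit_whz
  muac_rec <- !is.na(muac) & muac >= 125
  whz_rec <- !is.na(whz) & whz >= -2
  severe_veto <- (!is.na(muac) & muac < 115) | (!is.na(whz) & whz < -3)
  any_obs <- !is.na(muac) | !is.na(whz)
  below_both <- any_obs &
    (is.na(muac) | muac < 125) & (is.na(whz) | whz < -2)
  reclassifiable <- out$original_label %in% c("defaulter", "unknown")
  long_enough <- !is.na(out$los_weeks) & out$los_weeks >= min_los_weeks
  rec_ok <- (muac_rec | whz_rec) & !severe_veto &
    !(!is.na(out$oedema_exit) & out$oedema_exit)

  out <- out |> dplyr::mutate(
    final_label = dplyr::case_when(
      is.na(.data$n_visits) ~ "excluded",
      .data$oedema_admission ~ "excluded",
      .data$original_label %in% c("died", "medical_transfer") ~ "excluded",
      .data$original_label %in% c("recovered", "non_responder") ~
        .data$original_label,
      reclassifiable & !long_enough ~ "excluded",
      reclassifiable & long_enough & rec_ok ~ "recovered",
      reclassifiable & long_enough & !rec_ok & below_both ~ "non_responder",
      TRUE ~ "excluded"
    ),
    exclusion_reason = dplyr::case_when(
      .data$final_label != "excluded" ~ NA_character_,
      is.na(.data$n_visits) ~ "unclassifiable",
      .data$oedema_admission ~ "oedema_at_admission",
      .data$original_label == "died" ~ "died",
      .data$original_label == "medical_transfer" ~ "medical_transfer",
      reclassifiable & !long_enough ~ "short_stay_lt_12wk",
      TRUE ~ "unclassifiable"
    ),
    reclassified = reclassifiable &
      .data$final_label %in% c("recovered", "non_responder")
  )
  dplyr::select(out, "child_id", "original_label", "final_label",
                "exclusion_reason", "los_weeks", "exit_muac", "exit_whz",
                "reclassified")
}

#' Build the analysis set and the cohort flow counts
#'
#' Filters classified records to the analysis set (final label recovered or
#' non_responder) and tallies the flow-chart boxes. The counts are
#' conservative: `n_input = n_oedema_excluded + n_other_excluded +
#' n_analysis` and `n_analysis = n_recovered + n_non_responder`.
#'
#' @param outcomes output of [classify_exit()].
#' @return list with `analysis` (the retained rows) and `flow` (a one-row
#'   tibble of FlowCounts).
#' @export
build_analysis_set <- function(outcomes) {
  analysis <- dplyr::filter(outcomes,
                            .data$final_label %in% c("recovered",
                                                     "non_responder"))
  flow <- tibble::tibble(
    n_input = nrow(outcomes),
    n_oedema_excluded = sum(outcomes$exclusion_reason == "oedema_at_admission",
                            na.rm = TRUE),
    n_other_excluded = sum(outcomes$final_label == "excluded") -
      sum(outcomes$exclusion_reason == "oedema_at_admission", na.rm = TRUE),
    n_analysis = nrow(analysis),
    n_recovered = sum(analysis$final_label == "recovered"),
    n_non_responder = sum(analysis$final_label == "non_responder")
  )
  stopifnot(flow$n_input ==
              flow$n_oedema_excluded + flow$n_other_excluded + flow$n_analysis,
            flow$n_analysis == flow$n_recovered + flow$n_non_responder)
  list(analysis = analysis, flow = flow)
}
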