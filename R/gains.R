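#' Admission-to-exit anthropometric gains per child
#'
#' For each child, computes exit minus admission for MUAC, weight, height
#' and the four z-scores, plus the weight gain velocity (g/kg/day, on the
#' admission weight and the calendar days between the two weight
#' measurements) and length of stay in completed weeks. The admission value
#' is the one recorded at the admission (first) visit; the exit value is
#' the last non-missing one per indicator. A delta is missing whenever
#' either endpoint is missing.
#'
#' @param visits cleaned visit tibble with z-score columns.
#' @return tibble, one row per child: `child_id`, `delta_muac`,
#'   `delta_weight`, `delta_height`, `delta_whz`, `delta_waz`, `delta_haz`,
#'   `delta_muacz`, `rate`, `los_weeks`.
#' @export
compute_gains <- function(visits) {
  vars <- c(muac = "muac_mm", weight = "weight_kg", height = "height_cm",
            whz = "whz", waz = "waz", haz = "haz", muacz = "muacz")
  visits |>
    dplyr::group_by(.data$child_id) |>
    dplyr::arrange(.data$visit_date, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      res <- list()
      for (nm in names(vars)) {
        x <- df[[vars[[nm]]]]
        if (is.null(x)) { res[[paste0("delta_", nm)]] <- NA_real_; next }
        adm <- x[1]
        i_exit <- if (any(!is.na(x))) max(which(!is.na(x))) else NA_integer_
        res[[paste0("delta_", nm)]] <-
          if (is.na(adm) || is.na(i_exit)) NA_real_ else x[i_exit] - adm
      }
      w <- df$weight_kg
      w_adm <- w[1]
      i_w <- if (any(!is.na(w))) max(which(!is.na(w))) else NA_integer_
      dur <- if (is.na(i_w) || i_w == 1) NA_real_ else
        as.numeric(difftime(df$visit_date[i_w], df$visit_date[1],
                            units = "days"))
      res$rate <- if (is.na(w_adm) || is.na(i_w) || is.na(dur) || dur <= 0)
        NA_real_ else weight_gain_rate(w_adm, w[i_w], dur)
      res$los_weeks <- floor(as.numeric(difftime(
        max(df$visit_date), min(df$visit_date), units = "days")) / 7)
      tibble::as_tibble(res)
    }) |>
    dplyr::ungroup()
}

#' First-quartile gain threshold over non-responders
#'
#' The subgrouping threshold: the 25th percentile of the pooled
#' admission-to-exit gain among non-responders, under the
#' linear-interpolation quantile rule (`stats::quantile` type 7 by
#' default; the convention is configurable because small-sample thresholds
#' depend on it).
#'
#' @param gains numeric vector of gains from non-responders only.
#' @param indicator label recorded with the threshold.
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return one-row tibble: `indicator`, `q1`, `n_used`.
#' @examples
#' q1_threshold(0:7, "muac")  # q1 = 1.75
#' @export
q1_threshold <- function(gains, indicator = "muac", type = 7) {
  gains <- gains[!is.na(gains)]
  if (length(gains) < 4) {
    stop("q1_threshold(): need at least 4 non-missing non-responder gains",
         call. = FALSE)
  }
  tibble::tibble(
    indicator = indicator,
    q1 = stats::quantile(gains, 0.25, type = type, names = FALSE),
    n_used = length(gains)
  )
}

#' Assign the three-level response category
#'
#' Recovered children keep their label. Non-responders with gain below the
#' first-quartile threshold become low growth non-responders; those at or
#' above it (ties included) become high growth non-responders. A missing
#' gain leaves the category missing (unassigned).
#'
#' @param final_label `"recovered"` or `"non_responder"` per child.
#' @param gain admission-to-exit gain in the split indicator's units.
#' @param q1 threshold (scalar, from [q1_threshold()]).
#' @return factor with levels recovered, high_growth_nr, low_growth_nr.
#' @export
assign_response_category <- function(final_label, gain, q1) {
  stopifnot(length(q1) == 1, !is.na(q1))
  out <- dplyr::case_when(
    final_label == "recovered" ~ "recovered",
    final_label == "non_responder" & is.na(gain) ~ NA_character_,
    final_label == "non_responder" & gain < q1 ~ "low_growth_nr",
    final_label == "non_responder" & gain >= q1 ~ "high_growth_nr",
    TRUE ~ NA_character_
  )
  factor(out, levels = c("recovered", "high_growth_nr", "low_growth_nr"))
}

#' Split non-responders at the first quartile of gain
#'
#' Convenience wrapper joining [compute_gains()] output with classified
#' outcomes, computing the Q1 threshold over non-responders for the chosen
#' indicator, and assigning response categories.
#'
#' @param gains output of [compute_gains()].
#' @param outcomes output of [classify_exit()] (analysis rows only).
#' @param indicator one of `"muac"`, `"weight"`, `"rate"`, `"waz"`,
#'   `"whz"` (gain column `delta_muac` etc.; `"rate"` uses the g/kg/day
#'   velocity). MUAC is the default split indicator.
#' @param type quantile convention, see [q1_threshold()].
#' @return list with `data` (outcomes joined with gains and
#'   `response_category`) and `threshold` (the [q1_threshold()] row).
#' @export
split_non_responders <- function(gains, outcomes, indicator = "muac",
                                 type = 7) {
  col <- if (indicator == "rate") "rate" else paste0("delta_", indicator)
  if (!col %in% names(gains)) stop("unknown split indicator: ", indicator,
                                   call. = FALSE)
  df <- dplyr::inner_join(outcomes, gains, by = "child_id",
                          suffix = c("", ".gain"))
  nr_gains <- df[[col]][df$final_label == "non_responder"]
  thr <- q1_threshold(nr_gains, indicator, type = type)
  df$response_category <- assign_response_category(df$final_label, df[[col]],
                                                   thr$q1)
  list(data = tibble::as_tibble(df), threshold = thr)
}
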