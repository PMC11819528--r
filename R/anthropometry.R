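#' Classify wasting severity from MUAC and WHZ
#'
#' WHO-style case definitions for children without oedema:
#' severe wasting is MUAC < 115 mm or WHZ < -3; moderate wasting is
#' 115 <= MUAC < 125 mm or -3 <= WHZ < -2 (and not severe); otherwise not
#' wasted. A child meeting the severe cut-off on either indicator is severe
#' regardless of the other. Both indicators missing gives `NA`.
#'
#' @param muac_mm MUAC in mm (may be `NA`).
#' @param whz weight-for-height z-score (may be `NA`).
#' @return character vector: `"severe_wasting"`, `"moderate_wasting"`,
#'   `"not_wasted"`, or `NA` when unclassifiable.
#' @examples
#' classify_severity(114, -2.5)  # severe (MUAC criterion)
#' classify_severity(120, -2.5)  # moderate
#' classify_severity(130, -1.0)  # not wasted
#' @export
classify_severity <- function(muac_mm, whz) {
  n <- max(length(muac_mm), length(whz))
  muac_mm <- rep_len(muac_mm, n); whz <- rep_len(whz, n)
  sev <- (!is.na(muac_mm) & muac_mm < 115) | (!is.na(whz) & whz < -3)
  mod <- (!is.na(muac_mm) & muac_mm >= 115 & muac_mm < 125) |
    (!is.na(whz) & whz >= -3 & whz < -2)
  out <- dplyr::case_when(
    is.na(muac_mm) & is.na(whz) ~ NA_character_,
    sev ~ "severe_wasting",
    mod ~ "moderate_wasting",
    TRUE ~ "not_wasted"
  )
  out
}

#' Concurrent wasting-and-stunting and severe-underweight flags
#'
#' WaSt is concurrent wasting and stunting, defined as WHZ < -2 together
#' with HAZ < -2. Severe underweight is WAZ < -3. Missing inputs propagate
#' to missing flags.
#'
#' @param whz,haz,waz z-scores (may be `NA`).
#' @return tibble with logical columns `wast` and `severe_underweight`.
#' @export
derive_flags <- function(whz, haz, waz) {
  tibble::tibble(
    wast = (whz < -2) & (haz < -2),
    severe_underweight = waz < -3
  )
}

#' Weight gain velocity in g/kg/day
#'
#' Programme-standard velocity: gained grams per kilogram of admission body
#' weight per day of stay, `1000 * (w_exit - w_adm) / (w_adm * duration)`.
#'
#' @param w_adm admission weight, kg (> 0).
#' @param w_exit exit weight, kg.
#' @param duration_days days between the two measurements (> 0).
#' @return velocity in g/kg/day; `NA` inputs give `NA`.
#' @examples
#' weight_gain_rate(6, 6.84, 70)  # 2 g/kg/day
#' @export
weight_gain_rate <- function(w_adm, w_exit, duration_days) {
  if (any(!is.na(duration_days) & duration_days <= 0)) {
    stop("weight_gain_rate(): duration must be positive", call. = FALSE)
  }
  if (any(!is.na(w_adm) & w_adm <= 0)) {
    stop("weight_gain_rate(): admission weight must be positive", call. = FALSE)
  }
  1000 * (w_exit - w_adm) / (w_adm * duration_days)
}
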