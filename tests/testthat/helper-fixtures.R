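# shared in-code fixtures: visit builders and a miniature LMS table

make_visit <- function(child_id, day, weight = NA, height = NA, muac = NA,
                       age = 12, sex = "female", oedema = FALSE,
                       morbidity = FALSE) {
  tibble::tibble(
    child_id = child_id, study_id = "test",
    visit_date = as.Date("2020-01-01") + day,
    age_months = age + day / 30.4375, sex = sex,
    weight_kg = weight, height_cm = height, muac_mm = muac,
    oedema = oedema, morbidity = morbidity
  )
}

make_series <- function(child_id, days, weights = NA, heights = NA,
                        muacs = NA, ...) {
  n <- length(days)
  purrr::pmap_dfr(
    list(day = days, weight = rep_len(weights, n),
         height = rep_len(heights, n), muac = rep_len(muacs, n)),
    function(day, weight, height, muac)
      make_visit(child_id, day, weight, height, muac, ...)
  )
}

# flat miniature LMS table: every indicator has constant (L, M, S) so
# expected z-scores are hand-computable: z = ((x/M)^L - 1) / (L * S)
tiny_lms <- function() {
  dplyr::bind_rows(purrr::map_dfr(c("male", "female"), function(sx) {
    dplyr::bind_rows(
      tibble::tibble(indicator = "WHZ", sex = sx, key = c(450, 1200),
                     L = 1, M = 8, S = 0.1),
      tibble::tibble(indicator = "WAZ", sex = sx, key = c(0, 1856),
                     L = 1, M = 9, S = 0.12),
      tibble::tibble(indicator = "HAZ", sex = sx, key = c(0, 1856),
                     L = 1, M = 75, S = 0.04),
      tibble::tibble(indicator = "MUACZ", sex = sx, key = c(0, 1856),
                     L = 1, M = 150, S = 0.07)
    )
  }))
}

# deterministic per-child label table
make_labels <- function(child_ids, labels) {
  tibble::tibble(child_id = child_ids, original_label = labels)
}
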