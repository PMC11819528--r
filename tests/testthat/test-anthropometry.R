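test_that("lms_zscore matches the Box-Cox closed form", {
  # median maps to zero for any (L, S)
  for (L in c(-1, -0.5, 0, 1, 2)) {
    expect_equal(lms_zscore(10, L, 10, 0.1), 0)
  }
  # L = 1 reduces to (x - M) / (M * S)
  expect_equal(lms_zscore(11, 1, 10, 0.1), 1)
  # direct evaluation of ((1.1 ^ -0.5) - 1) / (-0.05)
  expect_equal(lms_zscore(11, -0.5, 10, 0.1),
               ((1.1^-0.5) - 1) / (-0.5 * 0.1), tolerance = 1e-12)
  expect_equal(round(lms_zscore(11, -0.5, 10, 0.1), 4), 0.9307)
  expect_error(lms_zscore(-1, 1, 10, 0.1), "positive")
  expect_error(lms_zscore(5, 1, -10, 0.1), "positive")
  expect_true(is.na(lms_zscore(NA, 1, 10, 0.1)))
})

test_that("lms_zscore is strictly increasing and invertible", {
  grid <- seq(4, 20, by = 0.25)
  for (L in c(-0.5, 0, 0.3, 1)) {
    z <- lms_zscore(grid, L, 10, 0.12)
    expect_true(all(diff(z) > 0))
    expect_equal(lms_invert(z, L, 10, 0.12), grid, tolerance = 1e-9)
  }
})

test_that("restricted adjustment rescales beyond-3SD values onto the SD gap", {
  L <- -0.35; M <- 8; S <- 0.082
  sd2 <- lms_invert(2, L, M, S); sd3 <- lms_invert(3, L, M, S)
  x <- sd3 + 0.4 * (sd3 - sd2)  # 0.4 of an SD gap above the +3 bound
  expect_equal(lms_zscore(x, L, M, S, restricted = TRUE), 3.4,
               tolerance = 1e-10)
  sd2n <- lms_invert(-2, L, M, S); sd3n <- lms_invert(-3, L, M, S)
  xn <- sd3n - 0.25 * (sd2n - sd3n)
  expect_equal(lms_zscore(xn, L, M, S, restricted = TRUE), -3.25,
               tolerance = 1e-10)
  # inside +/-3 the adjustment is inert
  expect_equal(lms_zscore(M * 1.05, L, M, S, restricted = TRUE),
               lms_zscore(M * 1.05, L, M, S))
})

test_that("severity classification follows the MUAC/WHZ cut-offs", {
  expect_equal(classify_severity(114, -2.5), "severe_wasting")
  expect_equal(classify_severity(120, -2.5), "moderate_wasting")
  expect_equal(classify_severity(130, -1.0), "not_wasted")
  # either severe criterion alone is decisive (OR logic)
  expect_equal(classify_severity(130, -3.5), "severe_wasting")
  expect_equal(classify_severity(NA, -3.5), "severe_wasting")
  expect_equal(classify_severity(114, NA), "severe_wasting")
  expect_true(is.na(classify_severity(NA, NA)))
  # boundary: cut-offs are strict "<"
  expect_equal(classify_severity(115, -3), "moderate_wasting")
  expect_equal(classify_severity(125, -2), "not_wasted")
})

test_that("severity is monotone in the single criteria", {
  # never not_wasted when a single-criterion severe call would fire
  grid <- tidyr::expand_grid(muac = c(110, 114, 115, 120, 124, 125, 140),
                             whz = c(-3.5, -3, -2.5, -2, -1))
  out <- classify_severity(grid$muac, grid$whz)
  single_severe <- grid$muac < 115 | grid$whz < -3
  expect_false(any(out[single_severe] == "not_wasted"))
})

test_that("WaSt and severe-underweight flags propagate missingness", {
  f <- derive_flags(whz = c(-2.1, -1.9, NA), haz = c(-2.1, -3.0, -2.5),
                    waz = c(-3.01, -2.99, -4))
  expect_equal(f$wast, c(TRUE, FALSE, NA))
  expect_equal(f$severe_underweight, c(TRUE, FALSE, TRUE))
})

test_that("weight gain velocity is in g/kg/day", {
  expect_equal(weight_gain_rate(6, 6.84, 70), 2)
  expect_equal(weight_gain_rate(6, 6, 70), 0)
  expect_equal(weight_gain_rate(6, 5.58, 70), -1)
  expect_error(weight_gain_rate(6, 6.84, 0), "duration")
  expect_error(weight_gain_rate(0, 6.84, 70), "positive")
})

test_that("z-score missingness equals input missingness", {
  visits <- dplyr::bind_rows(
    make_visit("a", 0, weight = 7, height = 75, muac = 120),
    make_visit("a", 7, weight = NA, height = 75, muac = 120),
    make_visit("a", 14, weight = 7, height = NA, muac = NA)
  )
  scored <- add_zscores(visits, tiny_lms())
  expect_equal(is.na(scored$whz), is.na(visits$weight_kg) |
                 is.na(visits$height_cm))
  expect_equal(is.na(scored$waz), is.na(visits$weight_kg))
  expect_equal(is.na(scored$haz), is.na(visits$height_cm))
  expect_equal(is.na(scored$muacz), is.na(visits$muac_mm))
  # constant tiny reference: hand-check one value, z = (x - M) / (M * S)
  expect_equal(scored$haz[1], (75 - 75) / (75 * 0.04))
  expect_equal(scored$muacz[1], (120 - 150) / (150 * 0.07))
})

test_that("out-of-range lookup keys give missing z-scores, not errors", {
  lms <- tiny_lms()
  v <- make_visit("a", 0, weight = 7, height = 75, muac = 120, age = 70)
  scored <- add_zscores(v, lms)  # age 70 months: outside the age tables
  expect_true(is.na(scored$waz) && is.na(scored$haz) && is.na(scored$muacz))
  expect_false(is.na(scored$whz))  # WHZ keyed on height, still in range
  expect_error(add_zscores(dplyr::mutate(v, sex = "M"), lms), "male")
})

test_that("the synthetic LMS reference is structurally valid", {
  ref <- synthetic_lms_reference()
  expect_true(all(ref$M > 0) && all(ref$S > 0))
  mono <- ref |>
    dplyr::group_by(indicator, sex) |>
    dplyr::summarise(ok = all(diff(key) > 0), m_up = all(diff(M) > 0),
                     .groups = "drop")
  expect_true(all(mono$ok))
  expect_true(all(mono$m_up))  # medians rise with age/length
  expect_setequal(unique(ref$indicator), c("WHZ", "WAZ", "HAZ", "MUACZ"))
})
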