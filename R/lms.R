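#' LMS z-score for a single measurement
#'
#' Converts a measurement into a z-score against an LMS (Box-Cox power,
#' median, coefficient-of-variation) growth reference:
#' \deqn{z = \frac{(x/M)^L - 1}{L \cdot S}} for \eqn{L \neq 0} and
#' \eqn{z = \log(x/M)/S} when \eqn{L = 0}.
#'
#' For weight-based indicators the WHO reference computation replaces
#' extreme z-scores (|z| > 3) with a restricted value measured on the scale
#' of the distance between the +/-2 SD and +/-3 SD bounds, so that values far
#' in the tail remain finite and comparable. Set `restricted = TRUE` to apply
#' that adjustment.
#'
#' @param x measurement (same units as `M`); must be positive.
#' @param L Box-Cox power (dimensionless).
#' @param M reference median; must be positive.
#' @param S reference coefficient of variation; must be positive.
#' @param restricted apply the WHO restricted adjustment for |z| > 3
#'   (used for weight-based indicators: WHZ, WAZ, MUACZ).
#' @return z-score (dimensionless), vectorised over the inputs. `NA` inputs
#'   give `NA` outputs.
#' @examples
#' lms_zscore(11, L = 1, M = 10, S = 0.1)      # exactly 1
#' lms_zscore(11, L = -0.5, M = 10, S = 0.1)   # ~0.9307
#' @export
lms_zscore <- function(x, L, M, S, restricted = FALSE) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  bad <- (!is.na(x) & x <= 0) | (!is.na(M) & M <= 0) | (!is.na(S) & S <= 0)
  if (any(bad)) {
    stop("lms_zscore(): x, M and S must all be positive", call. = FALSE)
  }
  z <- ifelse(abs(L) < 1e-12,
    log(x / M) / S,
    ((x / M)^L - 1) / (L * S)
  )
  if (restricted) {
    sd_at <- function(k) ifelse(abs(L) < 1e-12,
      M * exp(k * S),
      M * (1 + L * S * k)^(1 / L)
    )
    sd2p <- sd_at(2); sd3p <- sd_at(3); sd2n <- sd_at(-2); sd3n <- sd_at(-3)
    hi <- !is.na(z) & z > 3
    lo <- !is.na(z) & z < -3
    z[hi] <- 3 + (x[hi] - sd3p[hi]) / (sd3p[hi] - sd2p[hi])
    z[lo] <- -3 + (x[lo] - sd3n[lo]) / (sd2n[lo] - sd3n[lo])
  }
  z
}

#' Invert the LMS transform
#'
#' Recovers the measurement that yields z-score `z` under reference values
#' (L, M, S). Inverse of [lms_zscore()] without the restricted adjustment.
#'
#' @inheritParams lms_zscore
#' @param z z-score.
#' @return measurement in the units of `M`.
#' @export
lms_invert <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n); M <- rep_len(M, n)
  S <- rep_len(S, n)
  ifelse(abs(L) < 1e-12, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

lms_indicators <- c("WHZ", "WAZ", "HAZ", "MUACZ")

validate_lms <- function(ref) {
  need <- c("indicator", "sex", "key", "L", "M", "S")
  miss <- setdiff(need, names(ref))
  if (length(miss)) {
    stop("LMS reference is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(ref$indicator %in% lms_indicators)) {
    stop("LMS indicator must be one of ", paste(lms_indicators, collapse = ", "),
         call. = FALSE)
  }
  if (!all(ref$sex %in% c("male", "female"))) {
    stop("LMS sex must be 'male' or 'female'", call. = FALSE)
  }
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    stop("LMS reference requires M > 0 and S > 0", call. = FALSE)
  }
  ok <- ref |>
    dplyr::group_by(.data$indicator, .data$sex) |>
    dplyr::summarise(mono = all(diff(.data$key) > 0), .groups = "drop")
  if (!all(ok$mono)) {
    stop("LMS keys must be strictly increasing within (indicator, sex)",
         call. = FALSE)
  }
  tibble::as_tibble(ref)
}

#' Read an LMS growth reference from a delimited file
#'
#' Expected columns: `indicator` (WHZ, WAZ, HAZ, MUACZ), `sex`
#' (male/female), `key` (age in days for the age-based indicators, or
#' length/height in mm for WHZ), `L`, `M`, `S`. Lookup between tabulated
#' keys is linear in the key.
#'
#' @param path path to a tab- or comma-separated file with a header row.
#' @param sep field separator; default tab.
#' @return validated LMS reference tibble.
#' @export
read_lms_reference <- function(path, sep = "\t") {
  ref <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_lms(ref)
}

#' Synthetic LMS growth reference
#'
#' Constructs a *synthetic* LMS reference table with smooth, monotone,
#' sex-specific median curves anchored at field-plausible values for
#' children aged 6-59 months. It is NOT the WHO 2006 reference: it is a
#' stand-in with the same structure, units and rough magnitudes, bundled so
#' that the full pipeline (z-scoring, cleaning, classification, modelling)
#' is exercisable and testable without external reference files. For real
#' analyses supply the WHO tables via [read_lms_reference()].
#'
#' Keys: age in days (WAZ/HAZ/MUACZ; monthly grid, 30.4375 d/month, 0-61
#' months) or length/height in mm (WHZ; 5 mm grid, 450-1200 mm).
#'
#' @return LMS reference tibble (columns indicator, sex, key, L, M, S).
#' @export
synthetic_lms_reference <- function() {
  months <- 0:61
  days <- months * 30.4375
  # height-for-age median, cm: rapid infant growth then steady gain
  h_med <- function(a, male) {
    base <- 49.2 + 31 * (1 - exp(-a / 12)) + 0.44 * a
    if (male) base + 0.8 else base - 0.8
  }
  # weight-for-age median, kg: composed as the weight-for-length median at
  # the height-for-age median, so the three references are mutually
  # consistent (a child at median height and median weight-for-length has
  # WAZ ~ 0)
  w_med <- function(a, male) {
    wfl_med(h_med(a, male) * 10, male)
  }
  # MUAC-for-age median, mm: shallow rise over 6-59 months
  m_med <- function(a, male) {
    base <- 120 + 30 * (1 - exp(-a / 16)) + 0.25 * a
    if (male) base + 1.5 else base - 1.5
  }
  # weight-for-length median, kg, monotone in length
  wfl_med <- function(h_mm, male) {
    h <- h_mm / 10
    base <- 2.4 + 0.118 * (h - 45) + 0.00165 * (h - 45)^2
    if (male) base * 1.02 else base * 0.98
  }
  age_part <- purrr::map_dfr(c(TRUE, FALSE), function(male) {
    sex <- if (male) "male" else "female"
    dplyr::bind_rows(
      tibble::tibble(indicator = "HAZ", sex = sex, key = days,
                     L = 1, M = h_med(months, male), S = 0.036),
      tibble::tibble(indicator = "WAZ", sex = sex, key = days,
                     L = 0.25, M = w_med(months, male), S = 0.115),
      tibble::tibble(indicator = "MUACZ", sex = sex, key = days,
                     L = 0.4, M = m_med(months, male), S = 0.066)
    )
  })
  h_keys <- seq(450, 1200, by = 5)
  wh_part <- purrr::map_dfr(c(TRUE, FALSE), function(male) {
    tibble::tibble(indicator = "WHZ", sex = if (male) "male" else "female",
                   key = h_keys, L = -0.35, M = wfl_med(h_keys, male),
                   S = 0.082)
  })
  validate_lms(dplyr::bind_rows(age_part, wh_part))
}

# Interpolated (L, M, S) at lookup keys; out-of-range keys give NA rows.
lms_at <- function(ref, indicator, sex, key) {
  out <- tibble::tibble(L = NA_real_, M = NA_real_, S = NA_real_,
                        .rows = length(key))
  for (sx in unique(stats::na.omit(sex))) {
    tab <- ref[ref$indicator == indicator & ref$sex == sx, ]
    if (nrow(tab) == 0) next
    sel <- which(!is.na(key) & sex == sx)
    if (!length(sel)) next
    k <- key[sel]
    inside <- k >= min(tab$key) & k <= max(tab$key)
    idx <- sel[inside]
    if (length(idx)) {
      out$L[idx] <- stats::approx(tab$key, tab$L, xout = key[idx])$y
      out$M[idx] <- stats::approx(tab$key, tab$M, xout = key[idx])$y
      out$S[idx] <- stats::approx(tab$key, tab$S, xout = key[idx])$y
    }
  }
  out
}

DAYS_PER_MONTH <- 30.4375

#' Add WHO-style z-score columns to a visit table
#'
#' Computes `whz`, `waz`, `haz` and `muacz` for every visit from the raw
#' measurements and an LMS reference. A z-score is missing exactly when its
#' input measurement is missing or its lookup key falls outside the
#' reference range (out-of-range lookups are counted in the
#' `lms_out_of_range` attribute rather than raising).
#'
#' @param visits tibble with columns `sex`, `age_months`, `weight_kg`,
#'   `height_cm`, `muac_mm`.
#' @param lms LMS reference tibble (see [read_lms_reference()]).
#' @param restricted apply the WHO restricted adjustment on the
#'   weight-based indicators (WHZ, WAZ, MUACZ); default `TRUE`.
#' @return the input tibble with columns `whz`, `waz`, `haz`, `muacz`
#'   added or replaced.
#' @export
add_zscores <- function(visits, lms, restricted = TRUE) {
  lms <- validate_lms(lms)
  if (!all(stats::na.omit(unique(visits$sex)) %in% c("male", "female"))) {
    stop("sex must be coded 'male' or 'female'", call. = FALSE)
  }
  age_days <- visits$age_months * DAYS_PER_MONTH
  h_mm <- visits$height_cm * 10

  zcol <- function(indicator, x, key, restricted) {
    p <- lms_at(lms, indicator, visits$sex, key)
    ok <- !is.na(x) & !is.na(p$M)
    z <- rep(NA_real_, length(x))
    z[ok] <- lms_zscore(x[ok], p$L[ok], p$M[ok], p$S[ok],
                        restricted = restricted)
    attr(z, "n_out_of_range") <- sum(!is.na(x) & !is.na(key) & is.na(p$M))
    z
  }
  whz <- zcol("WHZ", visits$weight_kg, h_mm, restricted)
  waz <- zcol("WAZ", visits$weight_kg, age_days, restricted)
  haz <- zcol("HAZ", visits$height_cm, age_days, FALSE)
  muacz <- zcol("MUACZ", visits$muac_mm, age_days, restricted)
  out <- dplyr::mutate(tibble::as_tibble(visits),
                       whz = as.numeric(whz), waz = as.numeric(waz),
                       haz = as.numeric(haz), muacz = as.numeric(muacz))
  attr(out, "lms_out_of_range") <- c(
    whz = attr(whz, "n_out_of_range"), waz = attr(waz, "n_out_of_range"),
    haz = attr(haz, "n_out_of_range"), muacz = attr(muacz, "n_out_of_range")
  )
  out
}
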