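#' @importFrom rlang .data
NULL

# raw measurement -> z-scores computed from it; blanking a measurement must
# blank these too so z-missingness tracks input missingness
z_dependents <- list(
  weight_kg = c("whz", "waz"),
  height_cm = c("whz", "haz"),
  muac_mm = "muacz"
)

default_bounds <- list(
  weight_kg = c(3.5, 40),
  height_cm = c(60, 120),
  muac_mm = c(70, 200)
)

default_deltas <- c(weight_kg = 1.5, muac_mm = 15, height_cm = 1.5)

blank_dependents <- function(visits, rows, var) {
  for (zc in intersect(z_dependents[[var]], names(visits))) {
    visits[[zc]][rows] <- NA_real_
  }
  visits
}

#' Blank out-of-bound anthropometric values
#'
#' Per-visit plausibility bounds: height/length outside 60-120 cm, MUAC
#' outside 70-200 mm and weight outside 3.5-40 kg are set missing (and the
#' z-scores computed from them, if present). In-bound values pass through
#' unchanged.
#'
#' @param visits visit tibble.
#' @param bounds named list of `c(lower, upper)` per measurement column.
#' @return list with `visits` (cleaned tibble) and `audit` (one row per
#'   blanked value: child_id, visit_date, variable, rule, value).
#' @export
flag_implausible_values <- function(visits, bounds = default_bounds) {
  visits <- tibble::as_tibble(visits)
  audit <- list()
  for (var in names(bounds)) {
    if (!var %in% names(visits)) next
    b <- bounds[[var]]
    bad <- which(!is.na(visits[[var]]) &
                   (visits[[var]] < b[1] | visits[[var]] > b[2]))
    if (length(bad)) {
      audit[[var]] <- tibble::tibble(
        child_id = visits$child_id[bad], visit_date = visits$visit_date[bad],
        variable = var, rule = "bounds", value = visits[[var]][bad]
      )
      visits[[var]][bad] <- NA_real_
      visits <- blank_dependents(visits, bad, var)
    }
  }
  list(visits = visits, audit = dplyr::bind_rows(audit))
}

#' Tukey-fence outlier mask for a pooled z-score vector
#'
#' Boxplot rule: values below `Q1 - k * IQR` or above `Q3 + k * IQR` are
#' flagged. Quartiles use the default linear-interpolation quantile rule.
#'
#' @param values numeric vector (pooled over the dataset for one indicator).
#' @param k fence multiplier; default 1.5 (the standard boxplot fence).
#' @return logical mask, `FALSE` for missing values.
#' @export
flag_zscore_outliers <- function(values, k = 1.5) {
  ok <- !is.na(values)
  if (sum(ok) < 4) {
    stop("flag_zscore_outliers(): need at least 4 non-missing values",
         call. = FALSE)
  }
  q <- stats::quantile(values[ok], c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  mask <- ok & (values < q[1] - k * iqr | values > q[2] + k * iqr)
  mask[is.na(mask)] <- FALSE
  mask
}

#' Enforce visit-to-visit longitudinal consistency within children
#'
#' For each child (visits sorted by date) and each measurement, every
#' non-missing value is compared against the last retained value, skipping
#' over missing ones. A height/length decrease blanks the later height. A
#' change exceeding the weekly threshold (weight +/-1.5 kg, MUAC +/-15 mm,
#' height +1.5 cm) blanks the later value; thresholds scale linearly with
#' the gap in weeks between the compared visits, capped at `gap_cap` weeks
#' (gaps under one week use the one-week threshold). The later visit is
#' always the one blanked, keeping admission measurements as the anchor.
#'
#' @param visits visit tibble sorted by `visit_date` within `child_id`.
#' @param deltas named weekly thresholds.
#' @param gap_cap maximum scaling of the weekly thresholds, in weeks.
#' @return list with `visits` and `audit` as in [flag_implausible_values()].
#' @export
enforce_longitudinal_consistency <- function(visits, deltas = default_deltas,
                                             gap_cap = 4) {
  visits <- tibble::as_tibble(visits)
  unsorted <- visits |>
    dplyr::group_by(.data$child_id) |>
    dplyr::summarise(bad = is.unsorted(.data$visit_date), .groups = "drop")
  if (any(unsorted$bad)) {
    stop("visits must be sorted by visit_date within child", call. = FALSE)
  }
  audit <- list()
  for (var in intersect(names(deltas), names(visits))) {
    flagged <- logical(nrow(visits))
    for (rows in split(seq_len(nrow(visits)), visits$child_id)) {
      last_val <- NA_real_; last_date <- NA
      for (i in rows) {
        v <- visits[[var]][i]
        if (is.na(v)) next
        if (!is.na(last_val)) {
          gap_wk <- as.numeric(difftime(visits$visit_date[i], last_date,
                                        units = "days")) / 7
          g <- min(max(gap_wk, 1), gap_cap)
          d <- v - last_val
          viol <- if (var == "height_cm") d < 0 || d > deltas[[var]] * g
                  else abs(d) > deltas[[var]] * g
          if (viol) { flagged[i] <- TRUE; next }
        }
        last_val <- v; last_date <- visits$visit_date[i]
      }
    }
    bad <- which(flagged)
    if (length(bad)) {
      rule <- if (var == "height_cm") "height_delta" else "weekly_delta"
      audit[[var]] <- tibble::tibble(
        child_id = visits$child_id[bad], visit_date = visits$visit_date[bad],
        variable = var, rule = rule, value = visits[[var]][bad]
      )
      visits[[var]][bad] <- NA_real_
      visits <- blank_dependents(visits, bad, var)
    }
  }
  list(visits = visits, audit = dplyr::bind_rows(audit))
}

#' Full three-layer cleaning pass
#'
#' Applies, in order: (0) exclusion of visits recording no anthropometry at
#' all; (1) per-visit plausibility bounds; (2) pooled Tukey-fence outlier
#' blanking of the z-score columns, re-estimating the fences until no
#' further value is flagged so the whole pass is a fixed point (idempotent);
#' (3) longitudinal consistency within children; (4) exclusion of visits
#' left with no anthropometry by the rules. Stage order matters: a value
#' removed by an earlier rule can no longer trigger a later one.
#'
#' @param visits visit tibble (ideally after [add_zscores()]).
#' @param k Tukey fence multiplier.
#' @param bounds,deltas,gap_cap rule parameters, see the stage functions.
#' @return list with `visits` (cleaned) and `report` (a `cleaning_report`:
#'   `$counts` per rule x variable, `$audit` trail, `$n_visits_dropped`).
#' @export
clean_visits <- function(visits, k = 1.5, bounds = default_bounds,
                         deltas = default_deltas, gap_cap = 4) {
  visits <- tibble::as_tibble(visits)
  raw_vars <- intersect(names(default_bounds), names(visits))
  zcols <- intersect(c("whz", "waz", "haz", "muacz"), names(visits))

  no_anthro <- function(v) {
    rowSums(!is.na(as.data.frame(v[, raw_vars]))) == 0
  }
  empty0 <- no_anthro(visits)
  n_dropped_empty <- sum(empty0)
  visits <- visits[!empty0, ]

  s1 <- flag_implausible_values(visits, bounds)
  visits <- s1$visits

  # stages 2-3 iterate jointly to a fixed point: longitudinal blanking
  # removes z-scores from the pool the fences are estimated on, so the
  # fences are re-estimated until no rule fires; this makes the whole
  # cleaning pass idempotent
  z_audit <- list()
  long_audit <- list()
  repeat {
    n_new <- 0L
    for (zc in zcols) {
      repeat {
        if (sum(!is.na(visits[[zc]])) < 4) break
        mask <- flag_zscore_outliers(visits[[zc]], k = k)
        if (!any(mask)) break
        n_new <- n_new + sum(mask)
        z_audit[[length(z_audit) + 1L]] <- tibble::tibble(
          child_id = visits$child_id[mask],
          visit_date = visits$visit_date[mask],
          variable = zc, rule = "z_outlier", value = visits[[zc]][mask]
        )
        visits[[zc]][mask] <- NA_real_
      }
    }
    s3 <- enforce_longitudinal_consistency(visits, deltas, gap_cap)
    visits <- s3$visits
    n_new <- n_new + nrow(s3$audit)
    if (nrow(s3$audit)) long_audit[[length(long_audit) + 1L]] <- s3$audit
    if (n_new == 0L) break
  }

  emptied <- no_anthro(visits)
  n_dropped_emptied <- sum(emptied)
  visits <- visits[!emptied, ]

  audit <- dplyr::bind_rows(s1$audit, dplyr::bind_rows(z_audit),
                            dplyr::bind_rows(long_audit))
  counts <- if (nrow(audit)) {
    dplyr::count(audit, .data$rule, .data$variable, name = "n_flagged")
  } else {
    tibble::tibble(rule = character(), variable = character(),
                   n_flagged = integer())
  }
  report <- structure(
    list(counts = counts, audit = audit,
         n_visits_dropped = c(no_anthropometry = n_dropped_empty,
                              emptied_by_cleaning = n_dropped_emptied),
         total_flagged = nrow(audit)),
    class = "cleaning_report"
  )
  list(visits = visits, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:", x$total_flagged, "values blanked;",
      sum(x$n_visits_dropped), "visits dropped",
      sprintf("(%d with no anthropometry, %d emptied by cleaning)\n",
              x$n_visits_dropped[["no_anthropometry"]],
              x$n_visits_dropped[["emptied_by_cleaning"]]))
  print(x$counts)
  invisible(x)
}
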