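#' Signed percent difference against a reference
#'
#' The convention used throughout the calibrator QA: `100 * (measured -
#' reference) / reference`. Invariant under a common rescaling of both
#' arguments (a unit change cannot alter a constancy verdict).
#'
#' @param measured,reference Numeric vectors; `reference` must be nonzero.
#' @return Signed percent difference.
#' @export
#' @examples
#' percent_difference(206, 199.97)
percent_difference <- function(measured, reference) {
  if (any(reference == 0)) {
    abort("Percent difference is undefined against a zero reference.",
          class = "luquant_domain_error")
  }
  100 * (measured - reference) / reference
}

#' Daily constancy report for a re-entrant chamber
#'
#' Compares each chamber reading with the activity expected from radioactive
#' decay of a NIST-traceable calibration point. By default the expected
#' ("calculated") activity is recomputed from the calibration point with
#' [decay_correct()]; a `calculated_mCi` column in `readings` (the value
#' transcribed on the QA sheet, typically rounded to 2 decimals) overrides the
#' recomputation so that sheet arithmetic can be verified exactly.
#'
#' @param readings Tibble with columns `timestamp`, `activity_mCi`,
#'   `device_id`, and optionally `calculated_mCi`.
#' @param calibration_mCi Calibration activity in mCi.
#' @param calibration_time Calibration timestamp (ledger dialect or POSIXct).
#' @param spec A [radionuclide_spec()].
#' @param warn_pct Absolute percent difference above which a row is flagged
#'   (`within_warn = FALSE`). The QA programme this mirrors states no numeric
#'   action level; 5% is a common institutional choice and is configurable.
#' @return A tibble with one row per reading: `timestamp`, `device_id`,
#'   `calculated_mCi`, `measured_mCi`, `pct_diff`, `within_warn`.
#' @export
#' @examples
#' readings <- tibble::tibble(
#'   timestamp = "10/24/18 11:00", activity_mCi = 206, device_id = "Atom Lab 1"
#' )
#' constancy_report(readings, 245.270, "10/22/18 12:00")
constancy_report <- function(readings, calibration_mCi, calibration_time,
                             spec = lu177(), warn_pct = 5) {
  if (nrow(readings) == 0) {
    return(tibble::tibble(
      timestamp = character(), device_id = character(),
      calculated_mCi = double(), measured_mCi = double(),
      pct_diff = double(), within_warn = logical()
    ))
  }
  calc <- decay_correct(calibration_mCi, calibration_time, readings$timestamp,
                        spec = spec)
  if ("calculated_mCi" %in% names(readings)) calc <- readings$calculated_mCi
  if (any(calc == 0)) {
    abort("Calculated activity is zero; percent difference undefined.",
          class = "luquant_domain_error")
  }
  tibble::tibble(
    timestamp = as.character(readings$timestamp),
    device_id = readings$device_id,
    calculated_mCi = calc,
    measured_mCi = readings$activity_mCi,
    pct_diff = percent_difference(readings$activity_mCi, calc),
    within_warn = abs(percent_difference(readings$activity_mCi, calc)) <= warn_pct
  )
}

#' Dose-calibrator linearity check
#'
#' Least-squares line of measured response versus expected (decay-derived)
#' activity over a series of sources, with the Pearson correlation reported at
#' full precision (the QA report rounds it to one decimal).
#'
#' @param series Data frame with columns `expected_mCi` and `measured_mCi`
#'   (at least 3 rows; expected activities strictly positive with nonzero
#'   spread).
#' @return A `linearity_fit` object with elements `slope`, `intercept`,
#'   `correlation`, `n`, the input `series`, and the underlying `lm` fit.
#'   [tidy()] returns per-point fitted values and residuals, [glance()] the
#'   one-row summary, [autoplot()] the response plot.
#' @export
#' @examples
#' s <- tibble::tibble(expected_mCi = c(1, 2, 4), measured_mCi = c(1.02, 2.05, 4.1))
#' glance(linearity_check(s))
linearity_check <- function(series) {
  series <- tibble::as_tibble(series)
  if (nrow(series) < 3) {
    abort("Linearity needs at least 3 (expected, measured) points.",
          class = "luquant_input_error")
  }
  if (any(series$expected_mCi <= 0)) {
    abort("Expected activities must be strictly positive.",
          class = "luquant_domain_error")
  }
  if (stats::var(series$expected_mCi) == 0) {
    abort("Expected activities have zero variance; no line can be fit.",
          class = "luquant_domain_error")
  }
  fit <- lm(measured_mCi ~ expected_mCi, data = series)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      correlation = cor(series$expected_mCi, series$measured_mCi),
      n = nrow(series),
      series = series,
      fit = fit
    ),
    class = "linearity_fit"
  )
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf(
    "<linearity_fit> n = %d, slope = %.4f, intercept = %.4f, R = %.6f (reported %.1f)\n",
    x$n, x$slope, x$intercept, x$correlation, round(x$correlation, 1)
  ))
  invisible(x)
}

#' @method tidy linearity_fit
#' @export
tidy.linearity_fit <- function(x, ...) {
  dplyr::mutate(
    x$series,
    fitted_mCi = x$intercept + x$slope * .data$expected_mCi,
    residual_mCi = .data$measured_mCi - .data$fitted_mCi
  )
}

#' @method glance linearity_fit
#' @export
glance.linearity_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, slope = x$slope, intercept = x$intercept,
    correlation = x$correlation,
    correlation_reported = round(x$correlation, 1)
  )
}

#' @method autoplot linearity_fit
#' @export
autoplot.linearity_fit <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(.data$expected_mCi, .data$measured_mCi)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Expected activity (mCi)", y = "Measured activity (mCi)",
      title = "Dose-calibrator linearity",
      subtitle = sprintf("R = %.6f (reported %.1f)",
                         object$correlation, round(object$correlation, 1))
    )
}

#' Bundled re-entrant chamber QA ledger
#'
#' The commissioning constancy ledger shipped with the package: a single
#' NIST-traceable Lu-177 calibration point (245.270 mCi at 10/22/18 12:00,
#' half-life recorded as 6.6500 d) followed by five days of readings on two
#' AtomLab chambers, with the decay values and signed percent differences as
#' transcribed on the sheet.
#'
#' @return `atomlab_calibration()` returns a list with `activity_mCi`,
#'   `timestamp`, `half_life_days`, `vial_volume_mL`. `atomlab_constancy_ledger()`
#'   returns a long tibble with columns `timestamp`, `device_id`,
#'   `activity_mCi` (measured), `calculated_mCi` (sheet value), and
#'   `pct_diff_sheet`.
#' @export
#' @examples
#' atomlab_constancy_ledger()
atomlab_calibration <- function() {
  list(
    activity_mCi = 245.270,
    timestamp = "10/22/18 12:00",
    half_life_days = 6.6500,
    vial_volume_mL = 24.500
  )
}

#' @rdname atomlab_calibration
#' @export
atomlab_constancy_ledger <- function() {
  ts <- c("10/24/18 11:00", "10/25/18 10:00", "10/26/18 10:00",
          "10/30/18 10:00", "10/31/18 11:20")
  calc <- c(199.97, 180.95, 163.03, 107.43, 96.37)
  dplyr::bind_rows(
    tibble::tibble(
      timestamp = ts, device_id = "Atom Lab 1",
      activity_mCi = c(206, 186.5, 168.5, 110.9, 99.3),
      calculated_mCi = calc,
      pct_diff_sheet = c(3.02, 3.07, 3.36, 3.23, 3.04)
    ),
    tibble::tibble(
      timestamp = ts, device_id = "Atom Lab 2",
      activity_mCi = c(208, 187.9, 170.3, 112.2, 100.6),
      calculated_mCi = calc,
      pct_diff_sheet = c(4.02, 3.84, 4.46, 4.44, 4.39)
    )
  )
}

#' Bundled NEMA sphere commissioning measurements
#'
#' The three filled spheres of the NEMA-style phantom used for the
#' quantification end-to-end test: physical diameters, injected activities,
#' and the VOI count rates reported by the clinical quantification software,
#' together with the volume-sensitivity calibration factors measured before
#' and after the scanner service intervention.
#'
#' @return `commissioning_sphere_counts()`: tibble with `diameter_mm`,
#'   `injected_mCi`, `measured_cps`. `commissioning_cf()`: named vector of the
#'   two calibration factors in cps/MBq.
#' @export
#' @examples
#' commissioning_sphere_counts()
commissioning_sphere_counts <- function() {
  tibble::tibble(
    diameter_mm = c(37, 28, 22),
    injected_mCi = c(0.63, 0.27, 0.13),
    measured_cps = c(251.6, 109.5, 51.5)
  )
}

#' @rdname commissioning_sphere_counts
#' @export
commissioning_cf <- function() {
  c(pre_service = 5.04159, post_service = 5.124969)
}

#' Bundled hybrid-registration QA history
#'
#' Per-axis mean (SD) CT-to-NM point-source offsets, in mm, measured with the
#' medium-energy collimator before (5/2/2022) and after (6/6/2022) the scanner
#' service intervention, with the 2.2 mm per-axis tolerance.
#'
#' @return A tibble with columns `date`, `stage`, `axis`, `mean_mm`, `sd_mm`,
#'   `tolerance_mm`.
#' @export
#' @examples
#' registration_history()
registration_history <- function() {
  tibble::tibble(
    date = rep(c("5/2/2022", "6/6/2022"), each = 3),
    stage = rep(c("pre_service", "post_service"), each = 3),
    axis = rep(c("x", "y", "z"), 2),
    mean_mm = c(3.04, 0.87, 1.24, 0.82, 0.63, 0.91),
    sd_mm = c(0.95, 0.48, 0.68, 0.39, 0.45, 0.06),
    tolerance_mm = 2.2
  )
}
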