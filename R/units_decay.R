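#' Radionuclide physical constants
#'
#' Bundles the constants every other computation needs: physical half-life,
#' imaging photopeak, and the mean energy deposited locally per decay (beta
#' plus conversion/Auger electrons), used by the local-deposition dose model.
#'
#' @param name Radionuclide label, e.g. `"Lu-177"`.
#' @param half_life_days Physical half-life in days. Must be positive.
#' @param photopeak_keV Imaging photopeak energy in keV.
#' @param energy_per_decay_J Mean locally absorbed energy per decay in joules.
#'   Must be positive.
#'
#' @return An object of class `radionuclide_spec`.
#' @seealso [lu177()] for the Lu-177 defaults.
#' @export
#' @examples
#' radionuclide_spec("Lu-177", 6.65, 208, 2.3696e-14)
radionuclide_spec <- function(name, half_life_days, photopeak_keV,
                              energy_per_decay_J) {
  if (!is.numeric(half_life_days) || half_life_days <= 0) {
    abort("`half_life_days` must be a positive number.", class = "luquant_domain_error")
  }
  if (!is.numeric(energy_per_decay_J) || energy_per_decay_J <= 0) {
    abort("`energy_per_decay_J` must be a positive number.", class = "luquant_domain_error")
  }
  structure(
    list(
      name = as.character(name),
      half_life_days = as.numeric(half_life_days),
      photopeak_keV = as.numeric(photopeak_keV),
      energy_per_decay_J = as.numeric(energy_per_decay_J)
    ),
    class = "radionuclide_spec"
  )
}

#' @export
print.radionuclide_spec <- function(x, ...) {
  cat(sprintf(
    "<radionuclide_spec> %s: T1/2 = %.4f d, photopeak %.1f keV, %.4g J/decay\n",
    x$name, x$half_life_days, x$photopeak_keV, x$energy_per_decay_J
  ))
  invisible(x)
}

#' Lu-177 constants used throughout the package
#'
#' Half-life is taken as exactly 6.6500 days, the value recorded on the
#' dose-calibrator QA ledger this package reproduces (the evaluated literature
#' value is 6.647 d; the ledger value is kept so that ledger arithmetic
#' round-trips). The locally absorbed energy per decay, 147.9 keV
#' (2.3696e-14 J), is the mean beta plus conversion/Auger electron energy from
#' standard evaluated decay data; it is a configurable constant, not a value
#' from the QA ledger.
#'
#' @param energy_per_decay_J Override for the locally absorbed energy per
#'   decay (J).
#' @return A [radionuclide_spec()].
#' @export
#' @examples
#' lu177()
lu177 <- function(energy_per_decay_J = 147.9e3 * 1.602176634e-19) {
  radionuclide_spec("Lu-177",
    half_life_days = 6.6500,
    photopeak_keV = 208,
    energy_per_decay_J = energy_per_decay_J
  )
}

#' Parse QA-ledger timestamps
#'
#' Timestamps on the assay ledger are naive local times written as
#' `"MM/DD/YY HH:MM"` (minute resolution, no timezone or DST bookkeeping).
#' `POSIXct` input passes through unchanged.
#'
#' @param x Character vector of timestamps, or a `POSIXct`.
#' @return A `POSIXct` vector (UTC used as the neutral carrier).
#' @export
#' @examples
#' parse_assay_time("10/22/18 12:00")
parse_assay_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(as.character(x), format = "%m/%d/%y %H:%M", tz = "UTC")
  if (anyNA(out)) {
    bad <- as.character(x)[is.na(out)]
    abort(
      paste0("Unparseable timestamp(s): ", paste(bad, collapse = ", "),
             ' (expected "MM/DD/YY HH:MM").'),
      class = "luquant_input_error"
    )
  }
  out
}

#' Signed elapsed time in fractional days
#'
#' @param t0,t Timestamps (character in ledger dialect, or `POSIXct`).
#' @return Signed fractional days, `t - t0`, at minute resolution.
#' @export
#' @examples
#' elapsed_days("10/22/18 12:00", "10/24/18 11:00")
elapsed_days <- function(t0, t) {
  as.numeric(difftime(parse_assay_time(t), parse_assay_time(t0), units = "days"))
}

#' Decay-correct an activity between two times
#'
#' Returns `a0 * 2^(-(t - t0) / T1/2)`. Back-correction (`t` before `t0`) is
#' allowed and yields a larger activity.
#'
#' @param a0 Activity at `t0` (any activity unit; the unit is preserved).
#' @param t0 Reference timestamp.
#' @param t Target timestamp(s); vectorised.
#' @param spec A [radionuclide_spec()]; defaults to [lu177()].
#' @return Activity at `t`, same unit as `a0`.
#' @export
#' @examples
#' decay_correct(245.270, "10/22/18 12:00", "10/24/18 11:00")
decay_correct <- function(a0, t0, t, spec = lu177()) {
  stopifnot(inherits(spec, "radionuclide_spec"))
  if (any(a0 < 0)) abort("Activity must be nonnegative.", class = "luquant_domain_error")
  dt <- elapsed_days(t0, t)
  a0 * 2^(-dt / spec$half_life_days)
}

#' Convert between millicurie and megabecquerel
#'
#' Uses the exact definitional factor 1 mCi = 37 MBq.
#'
#' @param x Nonnegative activity value(s).
#' @return Converted activity.
#' @export
#' @examples
#' mci_to_mbq(0.63)
#' mbq_to_mci(49.093)
mci_to_mbq <- function(x) {
  if (any(x < 0)) abort("Activity must be nonnegative.", class = "luquant_domain_error")
  x * 37
}

#' @rdname mci_to_mbq
#' @export
mbq_to_mci <- function(x) {
  if (any(x < 0)) abort("Activity must be nonnegative.", class = "luquant_domain_error")
  x / 37
}

#' Decay constant in 1/s
#'
#' @param spec A [radionuclide_spec()].
#' @return `ln(2) / T1/2` with the half-life converted to seconds.
#' @export
decay_constant_per_s <- function(spec = lu177()) {
  log(2) / (spec$half_life_days * 86400)
}

#' Acquisition energy windows
#'
#' An energy window is a labelled `[lower, upper)` interval in keV. The
#' Lu-177 protocol uses a 208 keV +/-10% main window flanked by two narrow
#' scatter windows; [lu177_windows()] returns those three with their exact
#' protocol bounds.
#'
#' @param label One of `"main"`, `"lower_scatter"`, `"upper_scatter"`.
#' @param lower_keV,upper_keV Window bounds in keV, `upper_keV > lower_keV`.
#' @return A tibble row with `label`, `lower_keV`, `upper_keV`, `width_keV`.
#' @export
#' @examples
#' energy_window("main", 187.6, 229.2)
#' lu177_windows()
energy_window <- function(label = c("main", "lower_scatter", "upper_scatter"),
                          lower_keV, upper_keV) {
  label <- match.arg(label)
  if (!(upper_keV > lower_keV)) {
    abort("`upper_keV` must exceed `lower_keV`.", class = "luquant_domain_error")
  }
  tibble::tibble(
    label = label, lower_keV = lower_keV, upper_keV = upper_keV,
    width_keV = upper_keV - lower_keV
  )
}

#' @rdname energy_window
#' @export
lu177_windows <- function() {
  dplyr::bind_rows(
    energy_window("main", 187.6, 229.2),
    energy_window("lower_scatter", 168.9, 186.7),
    energy_window("upper_scatter", 228.0, 252.0)
  )
}

#' Read or write an activity-assay ledger
#'
#' Ledgers are plain CSV with columns `timestamp` (ledger dialect),
#' `activity_mCi`, `device_id`, and optionally `calculated_mCi` (the decay
#' value transcribed on the sheet).
#'
#' @param path CSV file path.
#' @param ledger Tibble to write.
#' @return `read_assay_ledger()` returns a tibble with parsed timestamps.
#' @export
read_assay_ledger <- function(path) {
  df <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  req <- c("timestamp", "activity_mCi", "device_id")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    abort(paste0("Ledger is missing column(s): ", paste(missing, collapse = ", ")),
          class = "luquant_input_error")
  }
  if (any(df$activity_mCi < 0)) {
    abort("Ledger activities must be nonnegative.", class = "luquant_domain_error")
  }
  df$time <- parse_assay_time(df$timestamp)
  df
}

#' @rdname read_assay_ledger
#' @export
write_assay_ledger <- function(ledger, path) {
  keep <- intersect(c("timestamp", "activity_mCi", "device_id", "calculated_mCi"),
                    names(ledger))
  write.csv(as.data.frame(ledger[keep]), path, row.names = FALSE)
  invisible(path)
}
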