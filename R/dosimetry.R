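#' Single-time-point cumulated activity
#'
#' Under the physical-decay-only assumption (appropriate for a phantom, where
#' there is no biological clearance), the time-integrated activity in each
#' voxel is `A / lambda` with `lambda = ln(2) / T1/2` in 1/s. An effective
#' half-life can be supplied to fold in clearance kinetics.
#'
#' @param activity_map [volume_image()] in MBq per voxel.
#' @param spec A [radionuclide_spec()].
#' @param effective_half_life_days Optional override of the physical
#'   half-life (e.g. an effective half-life including washout).
#' @return A [volume_image()] with quantity `"MBq_s_per_voxel"` and an
#'   `integration` attribute naming the assumption.
#' @export
#' @examples
#' v <- nm_grid(c(8, 8, 4), quantity = "activity_MBq_per_voxel")
#' v$data[4, 4, 2] <- 1
#' sum(cumulate_stp(v)$data) # ~8.29e5 MBq s for Lu-177
cumulate_stp <- function(activity_map, spec = lu177(),
                         effective_half_life_days = NULL) {
  stopifnot(inherits(activity_map, "volume_image"))
  t_half <- effective_half_life_days %||% spec$half_life_days
  if (t_half <= 0) abort("Half-life must be positive.", class = "luquant_domain_error")
  lambda <- log(2) / (t_half * 86400)
  out <- volume_image(activity_map$data / lambda, activity_map$spacing,
                      activity_map$origin, frame = activity_map$frame,
                      quantity = "MBq_s_per_voxel")
  attr(out, "integration") <- if (is.null(effective_half_life_days)) {
    "physical-decay-only"
  } else {
    sprintf("effective-half-life %.3f d", effective_half_life_days)
  }
  out
}

#' Local-deposition voxel dose map
#'
#' The local deposition method (LDM) assumes every decay deposits its charged-
#' particle energy in the voxel where it occurs — a good approximation for the
#' short-range Lu-177 betas at SPECT voxel sizes. Per voxel,
#' `D = A_cum * 1e6 * E_decay / m_voxel` in Gy, with `A_cum` in MBq s,
#' `E_decay` the locally absorbed energy per decay in J, and the voxel mass
#' defaulting to water density times the voxel volume. Kernel-convolution
#' (voxel S-value) dosimetry is a plug-in alternative: supply
#' `kernel_fun(dose_array, spacing)` to post-process the local map; none is
#' bundled.
#'
#' @param cum [volume_image()] of cumulated activity (MBq s per voxel).
#' @param spec A [radionuclide_spec()] providing `energy_per_decay_J`.
#' @param voxel_mass_kg Voxel mass; default water density x voxel volume.
#' @param kernel_fun Optional voxel-S-value kernel hook (see above).
#' @return A [volume_image()] with quantity `"dose_Gy"`.
#' @export
ldm_dose <- function(cum, spec = lu177(), voxel_mass_kg = NULL,
                     kernel_fun = NULL) {
  stopifnot(inherits(cum, "volume_image"))
  if (is.null(voxel_mass_kg)) {
    voxel_mass_kg <- prod(cum$spacing) * 1e-3 * 1e-3 # mm^3 -> mL -> kg of water
  }
  if (voxel_mass_kg <= 0) abort("Voxel mass must be positive.", class = "luquant_domain_error")
  dose <- cum$data * 1e6 * spec$energy_per_decay_J / voxel_mass_kg
  if (!is.null(kernel_fun)) dose <- kernel_fun(dose, cum$spacing)
  out <- volume_image(dose, cum$spacing, cum$origin, frame = cum$frame,
                      quantity = "dose_Gy")
  attr(out, "provenance") <- list(
    radionuclide = spec$name,
    energy_per_decay_J = spec$energy_per_decay_J,
    voxel_mass_kg = voxel_mass_kg,
    method = if (is.null(kernel_fun)) "LDM" else "LDM+kernel"
  )
  out
}

#' Per-VOI dose summary
#'
#' @param dose A dose [volume_image()].
#' @param masks Named list of mask [volume_image()]s on the dose grid.
#' @return Tibble with `voi`, `mean_Gy`, `max_Gy`, `voxels`.
#' @export
dose_summary <- function(dose, masks) {
  stopifnot(inherits(dose, "volume_image"))
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]$data != 0
    tibble::tibble(
      voi = nm,
      mean_Gy = mean(dose$data[m]),
      max_Gy = max(dose$data[m]),
      voxels = sum(m)
    )
  })
  dplyr::bind_rows(rows)
}
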