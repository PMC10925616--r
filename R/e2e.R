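#' Configuration for the end-to-end commissioning run
#'
#' One seed drives every stochastic stage (sub-seeds are derived from it), so
#' a config maps to exactly one report. The defaults are the desk-scale study
#' conditions: a 64 x 64 x 48 emission grid at 4.42 mm, 60 views, Poisson
#' noise on, the three-sphere phantom, an 18-mCi uniform cylinder for the
#' volume-sensitivity calibration, 10-mm partial-volume margins, and a
#' five-point-source registration study with per-axis shifts drawn uniformly
#' from [0, 5] mm.
#'
#' @param seed Integer master seed.
#' @param nm_dim Emission-grid dimensions.
#' @param phantom A [nema_phantom_spec()].
#' @param jaszczak_mCi Cylinder fill activity for the calibration scan.
#' @param jaszczak_dims List with `diameter_mm`, `height_mm` of the cylinder.
#' @param acquisition Arguments passed to [acquisition_config()] (seed is
#'   derived from `seed`).
#' @param recon List with `iterations` and `subsets`.
#' @param margin_mm Partial-volume VOI margin.
#' @param recovery_tolerance_pct Accuracy gate on sphere recovery.
#' @param registration List with `n_sources`, `max_shift_mm`, `offset`
#'   (NULL = random), `noise`, `counts`, and `apply_correction` (default TRUE;
#'   when FALSE the uncorrected offsets are gated directly).
#' @param dosimetry Logical: append the dose-map section.
#' @return An `e2e_config` list.
#' @export
e2e_config <- function(seed = 1L,
                       nm_dim = c(64, 64, 48),
                       phantom = nema_phantom_spec(),
                       jaszczak_mCi = 18,
                       jaszczak_dims = list(diameter_mm = 216, height_mm = 186),
                       acquisition = list(),
                       recon = list(iterations = 5, subsets = 8),
                       margin_mm = 10,
                       recovery_tolerance_pct = 12,
                       registration = list(n_sources = 5, max_shift_mm = 5,
                                           offset = NULL, noise = TRUE,
                                           counts = 2e4),
                       dosimetry = TRUE) {
  structure(
    list(
      seed = as.integer(seed), nm_dim = nm_dim, phantom = phantom,
      jaszczak_mCi = jaszczak_mCi, jaszczak_dims = jaszczak_dims,
      acquisition = acquisition, recon = recon,
      margin_mm = margin_mm, recovery_tolerance_pct = recovery_tolerance_pct,
      registration = registration, dosimetry = isTRUE(dosimetry)
    ),
    class = "e2e_config"
  )
}

#' Run the end-to-end commissioning test
#'
#' Executes the full qualification chain on synthetic data: dose-calibrator
#' constancy and linearity from the bundled ledger; uniform-cylinder
#' acquisition, TEW correction and reconstruction to calibrate the volume
#' sensitivity; NEMA-sphere acquisition, reconstruction and activity recovery
#' through 10-mm-margin CT contours; a point-source registration study with
#' correction shifts; and (optionally) a local-deposition dose map of the
#' recovered activity. Deterministic given the config.
#'
#' @param config An [e2e_config()].
#' @param verbose Print stage progress.
#' @return A `commissioning_report` with sections `calibrator`,
#'   `calibration`, `recovery`, `registration`, `dosimetry`, an
#'   `overall_pass` verdict, the config hash, and a timestamp.
#' @export
run_e2e <- function(config = e2e_config(), verbose = FALSE) {
  stopifnot(inherits(config, "e2e_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("E2E stage '%s' failed: %s", name, conditionMessage(e)),
            class = "luquant_stage_error", parent = e)
    })
  }

  # -- calibrator QA ---------------------------------------------------------
  say("calibrator QA")
  cal <- atomlab_calibration()
  ledger <- atomlab_constancy_ledger()
  constancy <- stage("constancy", constancy_report(
    ledger, cal$activity_mCi, cal$timestamp
  ))
  lin_series <- ledger |>
    dplyr::filter(.data$device_id == "Atom Lab 1") |>
    dplyr::transmute(expected_mCi = .data$calculated_mCi,
                     measured_mCi = .data$activity_mCi)
  linearity <- stage("linearity", linearity_check(lin_series))

  # -- volume-sensitivity calibration (uniform cylinder) ---------------------
  say("cylinder calibration scan")
  grid <- nm_grid(config$nm_dim)
  acq_args <- config$acquisition
  acq_args$seed <- config$seed + 101L
  cyl_cfg <- do.call(acquisition_config, acq_args)
  jas <- build_jaszczak(config$jaszczak_mCi,
                        diameter_mm = config$jaszczak_dims$diameter_mm,
                        height_mm = config$jaszczak_dims$height_mm, grid = grid)
  cyl_proj <- stage("simulate-cylinder",
                    simulate_acquisition(jas$activity, jas$mu, cyl_cfg))
  cyl_recon <- stage("reconstruct-cylinder", mlem_reconstruct(
    tew_correct(cyl_proj), jas$mu,
    iterations = config$recon$iterations, subsets = config$recon$subsets
  ))
  cyl_voi <- dilate_mask(jas$mask, config$margin_mm)
  cf <- stage("calibrate", compute_cf(
    cyl_recon, cyl_voi, mci_to_mbq(config$jaszczak_mCi),
    phantom_id = "uniform-cylinder", settings = config$recon
  ))

  # -- NEMA sphere recovery --------------------------------------------------
  say("NEMA quantification scan")
  acq_args$seed <- config$seed + 202L
  nema_cfg <- do.call(acquisition_config, acq_args)
  ph <- build_nema(config$phantom, grid = grid)
  nema_proj <- stage("simulate-nema",
                     simulate_acquisition(ph$activity, ph$mu, nema_cfg))
  nema_recon <- stage("reconstruct-nema", mlem_reconstruct(
    tew_correct(nema_proj), ph$mu,
    iterations = config$recon$iterations, subsets = config$recon$subsets
  ))
  contours <- sphere_masks(config$phantom$spheres, ct_grid())
  recovery <- stage("recover", sphere_recovery(
    nema_recon, contours, cf, injected = config$phantom$spheres,
    margin_mm = config$margin_mm
  ))
  recovery_pass <- max(abs(recovery$pct_diff)) <= config$recovery_tolerance_pct

  # -- registration QA -------------------------------------------------------
  say("registration QA")
  reg_cfg <- config$registration
  if (is.null(reg_cfg$offset)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(config$seed + 303L)
    ov <- stats::runif(3, 0, reg_cfg$max_shift_mm)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    reg_offset <- rigid_offset(ov[1], ov[2], ov[3])
  } else {
    reg_offset <- reg_cfg$offset
  }
  pairs <- stage("simulate-registration", simulate_registration_pair(
    reg_offset, n_sources = reg_cfg$n_sources,
    noise = isTRUE(reg_cfg$noise), counts = reg_cfg$counts %||% 2e4,
    seed = config$seed + 404L
  ))
  reg_report <- stage("estimate-offsets", estimate_offsets(pairs$nm, pairs$ct))
  residuals <- if (isTRUE(reg_cfg$apply_correction %||% TRUE)) {
    stage("correct-and-verify",
          correct_and_verify(pairs$nm, pairs$ct, reg_report))
  } else {
    # corrections disabled: the uncorrected means are the residuals
    tibble::tibble(
      axis = reg_report$summary$axis,
      residual_mm = reg_report$summary$mean_mm,
      pass = reg_report$summary$pass
    )
  }
  registration_pass <- all(residuals$pass)
  residual_under_1mm <- all(abs(residuals$residual_mm) < 1)

  # -- dosimetry -------------------------------------------------------------
  dosimetry <- NULL
  if (config$dosimetry) {
    say("dose map")
    act_map <- volume_image(
      nema_recon$data / cf$value_cps_per_MBq,
      nema_recon$spacing, nema_recon$origin, frame = "NM",
      quantity = "activity_MBq_per_voxel"
    )
    dose <- ldm_dose(cumulate_stp(act_map))
    nm_masks <- lapply(contours, function(m) {
      dilate_mask(resample(m, grid, method = "mask"), config$margin_mm)
    })
    dosimetry <- list(
      summary = dose_summary(dose, nm_masks),
      total_Gy_kg = sum(dose$data) * prod(dose$spacing) * 1e-6,
      dose = dose
    )
  }

  structure(
    list(
      calibrator = list(
        constancy = constancy,
        constancy_pass = all(constancy$within_warn),
        linearity = glance(linearity)
      ),
      calibration = list(
        cf_cps_per_MBq = cf$value_cps_per_MBq,
        cf = cf,
        jaszczak_mCi = config$jaszczak_mCi
      ),
      recovery = list(
        table = recovery,
        max_abs_pct_diff = max(abs(recovery$pct_diff)),
        tolerance_pct = config$recovery_tolerance_pct,
        pass = recovery_pass
      ),
      registration = list(
        imposed_offset = offset_vec(reg_offset),
        report = tidy(reg_report),
        correction = offset_vec(reg_report$correction),
        residuals = residuals,
        pass = registration_pass,
        residual_under_1mm = residual_under_1mm
      ),
      dosimetry = dosimetry,
      overall_pass = all(constancy$within_warn) && recovery_pass &&
        registration_pass,
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed,
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    class = "commissioning_report"
  )
}

#' @export
print.commissioning_report <- function(x, ...) {
  cat("<commissioning_report>\n")
  cat(sprintf("  calibrator: constancy %s, linearity R = %.4f\n",
              if (x$calibrator$constancy_pass) "pass" else "FLAG",
              x$calibrator$linearity$correlation))
  cat(sprintf("  calibration factor: %.4f cps/MBq\n",
              x$calibration$cf_cps_per_MBq))
  cat(sprintf("  sphere recovery: max |%%diff| = %.2f%% (gate %.0f%%) -> %s\n",
              x$recovery$max_abs_pct_diff, x$recovery$tolerance_pct,
              if (x$recovery$pass) "pass" else "FAIL"))
  cat(sprintf("  registration: max |residual| = %.3f mm -> %s (sub-mm: %s)\n",
              max(abs(x$registration$residuals$residual_mm)),
              if (x$registration$pass) "pass" else "FAIL",
              x$registration$residual_under_1mm))
  cat(sprintf("  overall: %s\n", if (x$overall_pass) "PASS" else "FAIL"))
  invisible(x)
}

# numbers-only view of a report, for serialisation and determinism checks
report_numbers <- function(report) {
  list(
    constancy = as.data.frame(report$calibrator$constancy),
    linearity = as.data.frame(report$calibrator$linearity),
    cf_cps_per_MBq = report$calibration$cf_cps_per_MBq,
    recovery = as.data.frame(report$recovery$table),
    max_abs_pct_diff = report$recovery$max_abs_pct_diff,
    registration = list(
      imposed_offset = report$registration$imposed_offset,
      summary = as.data.frame(report$registration$report),
      residuals = as.data.frame(report$registration$residuals)
    ),
    dosimetry = if (!is.null(report$dosimetry)) {
      as.data.frame(report$dosimetry$summary)
    },
    overall_pass = report$overall_pass,
    config_hash = report$config_hash
  )
}

#' Serialise a commissioning report
#'
#' Writes `report.json` (all section numbers plus config hash and timestamp)
#' and `report.md` (a human-readable summary) into `dir`.
#'
#' @param report A `commissioning_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "commissioning_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  payload <- report_numbers(report)
  payload$timestamp <- report$timestamp
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  md <- c(
    "# SPECT/CT dosimetry commissioning report",
    "",
    sprintf("- Generated: %s (seed %d, config %s)", report$timestamp,
            report$seed, report$config_hash),
    sprintf("- Overall verdict: **%s**",
            if (report$overall_pass) "PASS" else "FAIL"),
    "",
    "## Dose calibrator",
    sprintf("- Constancy: %d readings, max |%% diff| = %.2f%% -> %s",
            nrow(report$calibrator$constancy),
            max(abs(report$calibrator$constancy$pct_diff)),
            if (report$calibrator$constancy_pass) "pass" else "flag"),
    sprintf("- Linearity: R = %.6f (reported %.1f), slope %.4f",
            report$calibrator$linearity$correlation,
            report$calibrator$linearity$correlation_reported,
            report$calibrator$linearity$slope),
    "",
    "## Volume sensitivity",
    sprintf("- CF = %.4f cps/MBq (uniform cylinder, %.0f mCi)",
            report$calibration$cf_cps_per_MBq, report$calibration$jaszczak_mCi),
    "",
    "## Sphere activity recovery",
    sprintf("- Max |%% difference| = %.2f%% (gate %.0f%%) -> %s",
            report$recovery$max_abs_pct_diff, report$recovery$tolerance_pct,
            if (report$recovery$pass) "pass" else "FAIL"),
    knitr_free_table(report$recovery$table),
    "",
    "## Hybrid registration",
    sprintf("- Imposed offset (mm): %.2f / %.2f / %.2f",
            report$registration$imposed_offset[1],
            report$registration$imposed_offset[2],
            report$registration$imposed_offset[3]),
    sprintf("- Post-correction residuals (mm): %s (all < 1 mm: %s)",
            paste(sprintf("%.3f", report$registration$residuals$residual_mm),
                  collapse = " / "),
            report$registration$residual_under_1mm)
  )
  if (!is.null(report$dosimetry)) {
    md <- c(md, "", "## Dosimetry (LDM)",
            knitr_free_table(report$dosimetry$summary))
  }
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  invisible(c(json = json_path, markdown = md_path))
}

# minimal pipe-table formatter (avoids a knitr dependency)
knitr_free_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.4g", x))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}
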