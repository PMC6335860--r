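#' Pipeline configuration
#'
#' Collects the protocol defaults used across the stages: body threshold
#' -200 HU, bone window 120-2000 HU, material law by site, total loads
#' 2000 N (spine) / 1000 N (hip), solver tolerance 1e-8. Any override is
#' recorded in the run manifest.
#'
#' @param site `"spine"` or `"hip"`.
#' @param ... overrides of the named defaults (including `generator`, a
#'   [generator_params()] list for the simulate stage).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(site, ...) {
  site <- match_site(site)
  cfg <- list(
    site = site,
    n_subjects = 39L,
    body_threshold = -200,
    bone_range = c(120, 2000),
    material = if (site == "spine") "spine_power" else "femur_piecewise",
    total_force = if (site == "spine") 2000 else 1000,
    solver_tol = 1e-8,
    modulus_floor = 0.01,
    generator = generator_params(site))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, command, config, seed) {
  manifest <- list(
    command = command,
    seed = seed,
    config = strip_classes(config),
    config_md5 = config_hash(config),
    package = "qctfea",
    package_version = as.character(utils::packageVersion("qctfea")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Simulate a synthetic cohort to disk
#'
#' Writes per-subject HU volumes and truth BMD volumes as NIfTI, the cohort
#' table as CSV, and a run manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param write_volumes write the per-case NIfTI files (disable for large
#'   cohorts where only the table is needed).
#' @return Invisibly, the [generate_cohort()] result.
#' @export
cmd_simulate <- function(config, out_dir, seed, write_volumes = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- stage_error("simulate",
    generate_cohort(config$n_subjects, config$site, config$generator, seed))
  write_cohort(sim$table, file.path(out_dir, "cohort.csv"))
  if (write_volumes) {
    for (i in seq_along(sim$cases)) {
      cs <- sim$cases[[i]]
      write_volume(cs$hu_volume, file.path(out_dir, sprintf("case_%03d_hu.nii.gz", i)))
      write_volume(image_volume(cs$truth_bmd, cs$spacing),
                   file.path(out_dir, sprintf("case_%03d_truth.nii.gz", i)))
    }
  }
  write_manifest(out_dir, "simulate", config, seed)
  invisible(sim)
}

#' Fit the phantom calibration for one volume
#'
#' @param volume an [image_volume] (or path to one).
#' @param rod_rois list of rod ROI index sets.
#' @param nominal_densities rod densities, mg/cc.
#' @param out_dir optional output directory for the model file.
#' @return A [calibration_model].
#' @export
cmd_calibrate <- function(volume, rod_rois, nominal_densities, out_dir = NULL) {
  if (is.character(volume)) volume <- stage_error("calibrate", read_volume(volume))
  model <- stage_error("calibrate",
    fit_calibration(extract_rod_means(volume, rod_rois, nominal_densities)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calibration(model, file.path(out_dir, "calibration.txt"))
  }
  model
}

#' Fit the phantomless conversion model for a cohort
#'
#' @param cohort a `cohort_table` or path to a cohort CSV.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (model YAML + univariate
#'   diagnostics CSV).
#' @return A [conversion_model].
#' @export
cmd_fit <- function(cohort, config, out_dir = NULL) {
  if (is.character(cohort)) cohort <- stage_error("fit-model", read_cohort(cohort))
  model <- stage_error("fit-model", fit_conversion(cohort, config$site))
  screen <- stage_error("fit-model", univariate_screen(cohort))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_conversion(model, file.path(out_dir, "conversion.yaml"))
    utils::write.csv(screen, file.path(out_dir, "univariate_screen.csv"),
                     row.names = FALSE)
  }
  model
}

#' Convert a HU volume to BMD with a phantomless model
#'
#' Patient factors are measured from the volume itself when not supplied.
#'
#' @param volume an [image_volume] or path.
#' @param model a [conversion_model] or path to its YAML.
#' @param config a [pipeline_config()].
#' @param factors optional pre-measured `patient_factors`.
#' @param out_dir optional output directory for the BMD NIfTI.
#' @return A [bmd_volume] masked to the bone window.
#' @export
cmd_convert <- function(volume, model, config, factors = NULL, out_dir = NULL) {
  if (is.character(volume)) volume <- stage_error("convert", read_volume(volume))
  if (is.character(model)) model <- stage_error("convert", read_conversion(model))
  if (is.null(factors))
    factors <- stage_error("convert",
      measure_patient_factors(volume, config$site,
                              body_threshold = config$body_threshold,
                              bone_range = config$bone_range))
  est <- stage_error("convert", apply_conversion(volume, factors, model))
  mask <- volume$voxels >= config$bone_range[1] &
          volume$voxels <= config$bone_range[2]
  out <- bmd_volume(est$values, mask, volume$spacing)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(out, file.path(out_dir, "bmd_estimated.nii.gz"))
  }
  out
}

#' Run the voxel FEA stage
#'
#' @param bmd a [bmd_volume] whose mask defines the bone elements.
#' @param config a [pipeline_config()].
#' @param law optional [material_law()]; defaults to the config's site law.
#' @param intensity HU volume, required for the `linear_bvf` law.
#' @param out_dir optional output directory (VTK export).
#' @return A list with the solved `model` and `result`.
#' @export
cmd_fea <- function(bmd, config, law = NULL, intensity = NULL, out_dir = NULL) {
  if (is.null(law))
    law <- material_law(config$material, modulus_floor = config$modulus_floor)
  model <- stage_error("fea", {
    m <- build_mesh(bmd$mask, bmd$spacing)
    kept <- array(FALSE, dim = dim(bmd$mask)); kept[m$voxel_index] <- TRUE
    field <- map_materials(bmd_volume(bmd$values, kept, bmd$spacing), law, intensity)
    m <- set_materials(m, field)
    apply_boundary_conditions(m, config$site, config$total_force)
  })
  result <- stage_error("fea", solve_fea(model, tol = config$solver_tol))
  message(sprintf("fea: %d elements, %d nodes, total strain energy %.4g mJ",
                  nrow(model$elements), nrow(model$nodes), result$total_energy))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vtk(model, file.path(out_dir, "fea_result.vtk"), result)
  }
  list(model = model, result = result)
}

#' Compare estimated against reference BMD (and strain energy)
#'
#' @param reference reference [bmd_volume].
#' @param estimated estimated [bmd_volume].
#' @param reference_energy,estimated_energy optional total strain energies
#'   (mJ) from two [cmd_fea()] runs.
#' @param subject_reference,subject_estimated optional per-subject BMD
#'   vectors for the Pearson test.
#' @param out_dir optional output directory (JSON report).
#' @return A [comparison_report()].
#' @export
cmd_compare <- function(reference, estimated,
                        reference_energy = NA_real_, estimated_energy = NA_real_,
                        subject_reference = NULL, subject_estimated = NULL,
                        out_dir = NULL) {
  rmse <- stage_error("compare", bmd_rmse(reference, estimated))
  pr <- pp <- NA_real_; n <- NA_integer_
  if (!is.null(subject_reference)) {
    pe <- stage_error("compare", pearson(subject_reference, subject_estimated))
    pr <- pe$r; pp <- pe$p_value; n <- pe$n
  }
  see <- if (is.finite(reference_energy) && is.finite(estimated_energy))
    strain_energy_error(reference_energy, estimated_energy) else NA_real_
  report <- comparison_report(rmse, pr, pp, see, n)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "comparison.json"))
  }
  report
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> calibrate (per subject) -> fit conversion -> convert the
#' first subject -> FEA under reference and estimated materials -> compare.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return A list with the fitted models, FEA results, and the final
#'   [comparison_report()].
#' @export
run_pipeline <- function(config, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cmd_simulate(config, file.path(out_dir, "simulate"), seed,
                      write_volumes = FALSE)
  cs <- sim$cases[[1]]
  calib <- cmd_calibrate(cs$hu_volume, cs$rod_rois, cs$rod_densities,
                         file.path(out_dir, "calibrate"))
  conv <- cmd_fit(sim$table, config, file.path(out_dir, "fit"))
  reference <- apply_calibration(cs$hu_volume, calib, cs$bone_mask)
  factors <- measure_patient_factors(cs$hu_volume, config$site,
                                     body_threshold = config$body_threshold,
                                     bone_range = config$bone_range)
  est_all <- apply_conversion(cs$hu_volume, factors, conv)
  estimated <- bmd_volume(est_all$values, cs$bone_mask, cs$spacing)
  fea_ref <- cmd_fea(reference, config)
  fea_est <- cmd_fea(estimated, config, out_dir = file.path(out_dir, "fea"))
  est_subject <- apply_conversion(sim$table$mean_hu,
                                  list(circumference = sim$table$circumference,
                                       bone_area = sim$table$bone_area,
                                       site = config$site), conv)
  report <- cmd_compare(reference, estimated,
                        fea_ref$result$total_energy, fea_est$result$total_energy,
                        sim$table$reference_bmd, est_subject,
                        out_dir = out_dir)
  write_manifest(out_dir, "pipeline", config, seed)
  list(calibration = calib, conversion = conv, report = report,
       fea_reference = fea_ref$result, fea_estimated = fea_est$result,
       table = sim$table)
}
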