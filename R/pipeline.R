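#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run with its default.  Defaults
#' marked (protocol) come from the validated scan protocol or the published
#' risk thresholds; the rest are implementation choices documented in the
#' methods vignette.
#'
#' @param preset synthetic scene preset (see [synth_preset()]).
#' @param seed RNG seed for every stochastic stage.
#' @param noise_sd CT noise level in HU.
#' @param spacing_mm voxel spacing of the synthetic scan.
#' @param body_weight_kg patient body weight.
#' @param g_N_per_kg weight conversion (9.81 N/kg).
#' @param segmentation_threshold_mg_cm3,closing_radius_mm segmentation knobs.
#' @param target_edge_mm element size of the structured tet mesh.
#' @param law a [material_law].
#' @param cap_angle_deg,displacement_increment_mm,max_displacement_mm,stop_force_fraction
#'   load-case knobs.
#' @param high_cut,moderate_upper risk thresholds (protocol: 7.5 / 8.5).
#' @param db_path score database CSV.
#' @return a validated `bos_config` list.
#' @export
bos_config <- function(preset = "lytic-small", seed = 1, noise_sd = 0,
                       spacing_mm = c(2, 2, 2), body_weight_kg = 75,
                       g_N_per_kg = 9.81,
                       segmentation_threshold_mg_cm3 = 150,
                       closing_radius_mm = 2, target_edge_mm = 4,
                       law = material_law(), cap_angle_deg = 30,
                       displacement_increment_mm = 0.1,
                       max_displacement_mm = 1.5,
                       stop_force_fraction = 0.95, high_cut = 7.5,
                       moderate_upper = 8.5,
                       db_path = system.file("extdata",
                                             "score_db_synthetic.csv",
                                             package = "bosscore")) {
  stopifnot(body_weight_kg > 0, target_edge_mm > 0,
            displacement_increment_mm > 0,
            max_displacement_mm >= displacement_increment_mm,
            high_cut < moderate_upper, inherits(law, "material_law"))
  as.list(environment())
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full strength-score pipeline on a synthetic scan
#'
#' Generate (or accept) a raw scan, calibrate, segment, align and crop, mesh,
#' map materials, simulate to the peak reaction force, score, classify and
#' render the report.  A manifest recording every parameter, seed and
#' artifact checksum is returned (and written when `out_dir` is given), so a
#' run can be reproduced exactly.
#'
#' @param config a [bos_config].
#' @param out_dir optional output directory for the report and manifest.
#' @param raw_volume optional pre-generated `bos_raw_volume` (overrides the
#'   preset).
#' @return list with `score`, `category`, `simulation`, `mesh`, `report`,
#'   `calibration`, `manifest`.
#' @export
run_pipeline <- function(config = bos_config(), out_dir = NULL,
                         raw_volume = NULL) {
  raw <- run_stage("synthetic_ct", {
    if (is.null(raw_volume))
      synth_preset(config$preset, seed = config$seed,
                   noise_sd = config$noise_sd,
                   spacing_mm = config$spacing_mm)
    else raw_volume
  })
  gt <- run_stage("ground_truth", ground_truth_masks(raw))
  fit <- run_stage("calibration", {
    f <- fit_calibration(raw, gt$rods,
                         raw$ground_truth$phantom$rod_densities_mg_cm3)
    apply_calibration(raw, f)
  })
  mask <- run_stage("segmentation",
    segment_femur(fit, config$segmentation_threshold_mg_cm3,
                  config$closing_radius_mm, rod_masks = gt$rods))
  head <- run_stage("head_fit", find_head_center(mask))
  knee <- run_stage("knee_fit", find_knee_center(mask, head$center))
  lesion_pts <- NULL
  if (any(gt$lesion)) {
    lvol <- mask
    lvol$voxels <- gt$lesion
    lesion_pts <- mask_world_coords(lvol)
  }
  aligned <- run_stage("alignment",
    align_and_crop(fit, mask, head$center, knee,
                   lesion_points = lesion_pts,
                   margin_mm = config$target_edge_mm))
  mesh <- run_stage("meshing",
                    voxels_to_tets(aligned, config$target_edge_mm))
  materials <- run_stage("materials", map_materials(mesh, config$law))
  load <- run_stage("load_case", {
    # head center is at the aligned-frame origin by construction
    stance_load_case(mesh, head_center = c(0, 0, 0),
                     head_radius = head$radius,
                     cap_angle_deg = config$cap_angle_deg,
                     displacement_increment_mm =
                       config$displacement_increment_mm,
                     max_displacement_mm = config$max_displacement_mm,
                     stop_force_fraction = config$stop_force_fraction)
  })
  sim <- run_stage("fe_solver", solve_to_failure(mesh, materials, load))
  score <- run_stage("scoring",
    compute_bos(sim$F_max_N, bos_patient(config$body_weight_kg),
                config$g_N_per_kg))
  category <- classify_risk(score, config$high_cut, config$moderate_upper)
  db <- if (file.exists(config$db_path)) load_score_database(config$db_path)
        else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("bosscore")),
    config = config_to_manifest(config),
    calibration = fit$provenance,
    head = head, knee_center = knee,
    rotation = aligned$rotation, crop_plane_z = aligned$crop_plane_z,
    n_nodes = nrow(mesh$nodes), n_elements = nrow(mesh$elements),
    n_loaded = length(load$loaded_nodes), n_fixed = length(load$fixed_nodes),
    F_max_N = sim$F_max_N, bos_score = score$value, category = category)
  report <- NULL
  if (!is.null(out_dir)) {
    report <- run_stage("report",
      render_report(score, category, db, sim, mesh, out_dir,
                    cut = config$high_cut))
    files <- list.files(out_dir, full.names = TRUE)
    manifest$artifacts <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    report <- run_stage("report", {
      st <- if (!is.null(db)) database_stats(db, config$high_cut, score)
            else NULL
      list(bos_score = score$value, risk_category = category,
           ppv = st$ppv, npv = st$npv, percentile = st$percentile)
    })
  }
  list(score = score, category = category, simulation = sim, mesh = mesh,
       report = report, calibration = fit$provenance, manifest = manifest)
}

config_to_manifest <- function(config) {
  cfg <- config
  cfg$law <- unclass(cfg$law)
  cfg
}
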