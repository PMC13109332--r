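#' End-to-end pipeline configuration
#'
#' Collects every knob of the desk pipeline: input (a PLY file or a simulated
#' scene), per-region HSV ranges, outlier-removal parameters, the tray prior,
#' and the phenotype estimator parameters.  All randomness flows from the
#' single `seed` used by the scene simulator; the library stages themselves
#' are deterministic.
#'
#' @param input path to an input PLY, or `NULL` to simulate a scene.
#' @param output_dir directory for stage artifacts (intermediate PLYs and the
#'   JSON report); `NULL` keeps everything in memory.
#' @param scene a [scene_config()] used when `input` is `NULL`.
#' @param ranges per-region HSV ranges ([default_region_ranges()]).
#' @param sor_m,sor_k statistical outlier removal parameters.
#' @param prior a [tray_prior()].
#' @param use_height_scale include the height factor in the mean scale.
#' @param top_fraction,cell_mm,voxel_mm,crosssection_z_mm,crosssection_hw_mm
#'   phenotype parameters.
#' @param seed integer seed forwarded to the simulator.
#' @param verbose log stage point counts to standard error.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output_dir = NULL,
                            scene = scene_config(), ranges = default_region_ranges(),
                            sor_m = 16L, sor_k = 1.0,
                            prior = tray_prior(), use_height_scale = FALSE,
                            top_fraction = 0.05, cell_mm = 1.0,
                            voxel_mm = 5.0, crosssection_z_mm = 163,
                            crosssection_hw_mm = 5,
                            seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) scene$rng_seed <- as.integer(seed)
  structure(list(input = input, output_dir = output_dir, scene = scene,
                 ranges = ranges, sor_m = as.integer(sor_m), sor_k = sor_k,
                 prior = prior, use_height_scale = use_height_scale,
                 top_fraction = top_fraction, cell_mm = cell_mm,
                 voxel_mm = voxel_mm, crosssection_z_mm = crosssection_z_mm,
                 crosssection_hw_mm = crosssection_hw_mm,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `scene` holds
#' [scene_config()] fields, `prior` the tray dimensions, and `ranges` named
#' regions with `hue_min`..`val_max` bounds.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scene <- do.call(scene_config, y$scene %||% list())
  prior <- do.call(tray_prior, y$prior %||% list())
  ranges <- default_region_ranges()
  for (nm in names(y$ranges %||% list())) {
    ranges[[nm]] <- do.call(hsv_range, y$ranges[[nm]])
  }
  args <- y[setdiff(names(y), c("scene", "prior", "ranges"))]
  do.call(pipeline_config,
          c(args, list(scene = scene, prior = prior, ranges = ranges)))
}

pipeline_log <- function(cfg, ...) {
  if (cfg$verbose) message("[trayphen] ", ...)
}

#' Run the full desk pipeline
#'
#' Stages, in order: load or simulate the scene; color filtering (points
#' matching any of the plant/tray/soil ranges are foreground, everything
#' else -- reflections, background clutter -- is dropped); statistical
#' outlier removal; tray-prior calibration of the denoised cloud; phenotype
#' extraction on the calibrated plant region.  When `output_dir` is set,
#' intermediate clouds (`filtered.ply`, `denoised.ply`, `calibrated.ply`),
#' the calibration summary (`calibration.json`) and the phenotype report
#' (`report.json`) are written there; the pipeline is deterministic, so a
#' rerun with the same configuration reproduces every artifact byte for
#' byte.
#'
#' @param config a [pipeline_config()].
#' @return list with `report` (a [phenotype_report()]), `calibration` (a
#'   `calibration_result`), `counts` (per-stage point ledger), `cloud`
#'   (the calibrated cloud) and, for simulated scenes, `ground_truth`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  gt <- NULL
  if (is.null(config$input)) {
    sim <- generate_scene(config$scene)
    cloud <- sim$cloud
    gt <- sim$ground_truth
    pipeline_log(config, "simulated scene: ", n_points(cloud), " points")
  } else {
    cloud <- read_ply(config$input)
    pipeline_log(config, "read ", config$input, ": ", n_points(cloud),
                 " points")
  }
  counts <- list(input = n_points(cloud))

  ## stage 1: color filter (keep scene structure, drop color noise)
  hsv <- rgb_to_hsv_deg(cloud$colors)
  fg <- hsv_in_range(hsv, config$ranges$plant) |
    hsv_in_range(hsv, config$ranges$tray) |
    hsv_in_range(hsv, config$ranges$soil)
  filtered <- subset_cloud(cloud, fg)
  color_removed <- subset_cloud(cloud, !fg)
  counts$color_kept <- n_points(filtered)
  counts$color_removed <- n_points(color_removed)
  pipeline_log(config, "color filter: kept ", counts$color_kept,
               ", removed ", counts$color_removed)

  ## stage 2: statistical outlier removal
  sor <- remove_statistical_outliers(filtered, m = config$sor_m,
                                     k = config$sor_k)
  denoised <- sor$kept
  counts$sor_kept <- n_points(denoised)
  counts$sor_removed <- n_points(sor$removed)
  pipeline_log(config, "outlier removal: kept ", counts$sor_kept,
               ", removed ", counts$sor_removed)

  ## stage 3: tray calibration
  cal <- calibrate_cloud(denoised, ranges = config$ranges,
                         prior = config$prior, sor_m = config$sor_m,
                         sor_k = config$sor_k,
                         use_height_scale = config$use_height_scale)
  calibrated <- cal$calibrated
  pipeline_log(config, "calibration: scale ",
               format(cal$result$scale_factors$s_mean))

  ## stage 4: phenotypes on the calibrated plant region
  plant <- extract_region(calibrated, config$ranges, "plant")
  counts$plant <- n_points(plant)
  report <- phenotype_report(plant, prior = config$prior,
                             top_fraction = config$top_fraction,
                             cell_mm = config$cell_mm,
                             voxel_mm = config$voxel_mm,
                             crosssection_z_mm = config$crosssection_z_mm,
                             crosssection_hw_mm = config$crosssection_hw_mm)
  pipeline_log(config, "phenotypes: height ", format(report$height_mm),
               " mm over ", counts$plant, " plant points")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_ply(filtered, file.path(config$output_dir, "filtered.ply"))
    write_ply(denoised, file.path(config$output_dir, "denoised.ply"))
    write_ply(calibrated, file.path(config$output_dir, "calibrated.ply"))
    jsonlite::write_json(calibration_json(cal$result),
                         file.path(config$output_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(c(unclass(report), list(stage_counts = counts)),
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, calibration = cal$result, counts = counts,
       cloud = calibrated, ground_truth = gt)
}

## JSON-friendly view of a calibration result (rotations row-major)
calibration_json <- function(res) {
  list(
    plane_normal = as.numeric(res$plane$normal),
    plane_residual = res$plane$residual,
    r_align = as.numeric(t(res$r_align)),
    theta_rad = res$theta,
    r_z = as.numeric(t(res$r_z)),
    flipped = res$flipped,
    scale_factors = res$scale_factors,
    rotation = as.numeric(t(res$transform$rotation)),
    translation = res$transform$translation,
    scale = res$transform$scale,
    sigma_hat = res$sigma_hat,
    tray_extents_mm = as.numeric(res$tray_extents_mm),
    n_tray_points = res$n_tray_points
  )
}
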