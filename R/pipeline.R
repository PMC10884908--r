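#' Pipeline configuration
#'
#' End-to-end configuration for `simulate -> ivm -> detect -> evaluate ->
#' fov -> report`. Round-trips losslessly through YAML via
#' [read_pipeline_config()] / [write_pipeline_config()]; unknown keys in a
#' config file are rejected rather than ignored.
#'
#' The default pipeline dish is a 500 x 500 px (0.25 cm^2) scene so that a
#' full multi-dish run stays interactive; all sizes are configurable.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed single top-level seed; every random stage derives from it.
#' @param scene a [scene_params()] for the main dish.
#' @param detector a [detector_config()].
#' @param max_dist_px detection-to-truth matching radius.
#' @param debris_radius_px image-origin classification radius.
#' @param fov_field_w_px,fov_field_h_px field size for the FOV simulation
#'   (must fit 5x5 in the scene).
#' @param fov_ks field-count levels for the FOV simulation.
#' @param fov_combos subsets per level.
#' @param n_dishes number of replicate dishes for the detected-vs-true
#'   correlation.
#' @param dish_cells_range range of cell counts across replicate dishes.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` (list).
#' @export
pipeline_config <- function(out_dir = "sheetscan-out", seed = 1L,
                            scene = scene_params(width_px = 500,
                                                 height_px = 500,
                                                 n_cells = 120,
                                                 n_debris = 4,
                                                 seed = seed),
                            detector = detector_config(),
                            max_dist_px = 5, debris_radius_px = 5,
                            fov_field_w_px = 96, fov_field_h_px = 72,
                            fov_ks = c(1, 3, 5, 10, 20), fov_combos = 5,
                            n_dishes = 15,
                            dish_cells_range = c(30, 300),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(inherits(scene, "scene_params"),
            inherits(detector, "detector_config"),
            max_dist_px > 0, debris_radius_px > 0,
            fov_field_w_px >= 1, fov_field_h_px >= 1,
            all(fov_ks >= 1), fov_combos >= 1,
            n_dishes >= 3, length(dish_cells_range) == 2)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 scene = scene, detector = detector,
                 max_dist_px = max_dist_px,
                 debris_radius_px = debris_radius_px,
                 fov_field_w_px = as.integer(fov_field_w_px),
                 fov_field_h_px = as.integer(fov_field_h_px),
                 fov_ks = as.integer(fov_ks),
                 fov_combos = as.integer(fov_combos),
                 n_dishes = as.integer(n_dishes),
                 dish_cells_range = as.integer(dish_cells_range),
                 log_level = log_level),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$scene <- params_to_list(lst$scene)
  lst$detector <- unclass(lst$detector)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lst$scene <- params_from_list(lst$scene)
  lst$detector <- do.call(detector_config, lst$detector)
  do.call(pipeline_config, lst)
}

#' Run the full pipeline
#'
#' Generates the main synthetic dish, computes and writes its IVM and image
#' metrics, detects and counts cells, scores the four-way error taxonomy
#' against the nuclei ground truth, simulates field-of-view sampling on the
#' dish, renders `n_dishes` replicate dishes across a density range and
#' correlates detected with true totals, and writes a summary JSON. All
#' artifacts are deterministic functions of the config (byte-identical
#' reruns for the same seed).
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `scene`, `detections`, `report`
#'   (`error_report`), `fov` (`fov_result`), `dishes` (tibble) and `summary`
#'   (the written summary list).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) {
    if (config$log_level == "info") message("[sheetscan] ", sprintf(...))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say("seed %d; writing to %s", config$seed, out)

  say("stage simulate")
  scene <- render_scene(config$scene)
  write_scene(scene, file.path(out, "scene"))

  say("stage ivm")
  ivm <- compute_ivm(scene$scan)
  display <- amplify_clip(ivm, 200)
  write_gray(display, file.path(out, "ivm.tif"))
  region <- cell_region_from_phase(scene$phase)
  bs <- brightness_stats(scene$scan)
  metrics <- list(brightness_mean = bs$mean,
                  brightness_sd = bs$deviation,
                  object_contrast = object_contrast(ivm),
                  cross_entropy = cross_entropy(region, display))

  say("stage detect")
  det <- detect_cells(display, config$detector)
  utils::write.csv(as.data.frame(det[, c("row_px", "col_px", "area_px")]),
                   file.path(out, "detections.csv"), row.names = FALSE)

  say("stage evaluate")
  matching <- match_detections(det, scene$truth$cells, config$max_dist_px)
  report <- classify_errors(matching, det, scene$truth$cells, scene$truth,
                            debris_radius_px = config$debris_radius_px,
                            pixel_size_um = config$scene$pixel_size_um)
  rep_lst <- unclass(report)
  rep_lst$items <- NULL
  jsonlite::write_json(rep_lst, file.path(out, "error_report.json"),
                       auto_unbox = TRUE, digits = NA)

  say("stage fov")
  mask <- matrix(TRUE, config$scene$height_px, config$scene$width_px)
  grid <- place_fields(mask, config$fov_field_w_px, config$fov_field_h_px,
                       pixel_size_um = config$scene$pixel_size_um)
  counts <- count_per_field(scene$truth$cells, grid)
  fov <- if (nrow(scene$truth$cells) > 0) {
    purrr::map_dfr(config$fov_ks, function(k) {
      estimate_from_fields(counts, grid, k,
                           true_total = nrow(scene$truth$cells),
                           n_combos = config$fov_combos,
                           seed = config$seed + k)
    })
  } else {
    tibble::tibble(k = integer(0), combo = integer(0), fields = list(),
                   estimated_total = numeric(0), true_total = numeric(0),
                   discrepancy_pct = numeric(0))
  }
  fov_flat <- fov
  fov_flat$fields <- vapply(fov$fields, paste, character(1), collapse = ";")
  utils::write.csv(as.data.frame(fov_flat), file.path(out, "fov.csv"),
                   row.names = FALSE)

  say("stage dishes (%d replicates)", config$n_dishes)
  n_seq <- as.integer(round(seq(config$dish_cells_range[1],
                                config$dish_cells_range[2],
                                length.out = config$n_dishes)))
  dishes <- purrr::map_dfr(seq_len(config$n_dishes), function(i) {
    p <- config$scene
    p$n_cells <- n_seq[i]
    p$n_debris <- 0L
    p$seed <- config$seed + 1000L + i
    sc <- render_scene(p)
    d <- detect_cells(amplify_clip(compute_ivm(sc$scan), 200),
                      config$detector)
    tibble::tibble(dish = i, true_total = n_seq[i], detected_total = nrow(d))
  })
  r2 <- r_squared(dishes$true_total, dishes$detected_total)

  area_px <- config$scene$width_px * config$scene$height_px
  summary <- list(
    seed = config$seed,
    total_count = nrow(det),
    true_count = nrow(scene$truth$cells),
    detected_density_cells_cm2 = cell_density(nrow(det), area_px,
                                              config$scene$pixel_size_um),
    true_density_cells_cm2 = cell_density(nrow(scene$truth$cells), area_px,
                                          config$scene$pixel_size_um),
    brightness_mean = metrics$brightness_mean,
    brightness_sd = metrics$brightness_sd,
    object_contrast = metrics$object_contrast,
    cross_entropy = metrics$cross_entropy,
    r_squared_dishes = r2
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: %d detected / %d true; dish R^2 %.3f",
      nrow(det), nrow(scene$truth$cells), r2)
  invisible(list(scene = scene, detections = det, report = report,
                 fov = fov, dishes = dishes, summary = summary))
}
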