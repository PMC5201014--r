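#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Unknown keys are
#' rejected; the effective configuration is serialized into the output
#' directory so every run is self-describing.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed master seed; every stage derives its own stream from it.
#' @param stages stages to run, in order, from `c("simulate", "detect",
#'   "correct", "cluster", "fit", "quantify", "map")`.
#' @param input optional named list: `stack_prefixes` (character vector of
#'   [write_stack()] prefixes) for image input; omit when simulating.
#' @param channel_roles named list mapping channel names to roles.
#' @param voxel_size optional length-3 voxel-size override (um).
#' @param simulate parameters forwarded to [simulate_population()]
#'   (`n_nuclei`, `kind`, ...), plus `render` (logical; also write rendered
#'   stacks).
#' @param detection list: `min_separation`, `threshold_k`, `linkage_radius`,
#'   `min_detections`, `spb_brightness_factor`.
#' @param aberration list: `eccentricity_max`, `model_path` (load a stored
#'   model instead of refitting).
#' @param envelope list: `model` ("anchor"/"spline"), `iterations`,
#'   `voxel_pitch`, `export_meshes`.
#' @param maps list: `secondary_landmark`, `pitch`, `s_range`, `r_range`,
#'   `n_bins`, `min_points`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            stages = c("simulate", "detect", "correct",
                                       "cluster", "fit", "quantify", "map"),
                            input = NULL,
                            channel_roles = list(npc = "npc", nucleolus = "nucleolus"),
                            voxel_size = NULL,
                            simulate = list(), detection = list(),
                            aberration = list(), envelope = list(),
                            maps = list()) {
  all_stages <- c("simulate", "detect", "correct", "cluster", "fit",
                  "quantify", "map")
  stopifnot(all(stages %in% all_stages))
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "))
    x
  }
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    input = check_keys(input, c("stack_prefixes"), "input"),
    channel_roles = channel_roles, voxel_size = voxel_size,
    simulate = utils::modifyList(
      list(n_nuclei = 50, kind = "sphere", npc_median = 22, render = FALSE,
           aberration_coef = c(0.26, 0.0029)),
      check_keys(simulate, c("n_nuclei", "kind", "npc_median", "render",
                             "aberration_coef", "radius_median", "radius_sdlog"),
                 "simulate")),
    detection = utils::modifyList(
      list(min_separation = 0.3, threshold_k = 5, linkage_radius = 2.5,
           min_detections = 8, spb_brightness_factor = 3),
      check_keys(detection, c("min_separation", "threshold_k", "linkage_radius",
                              "min_detections", "spb_brightness_factor"),
                 "detection")),
    aberration = utils::modifyList(
      list(eccentricity_max = 1.15, model_path = NULL),
      check_keys(aberration, c("eccentricity_max", "model_path"), "aberration")),
    envelope = utils::modifyList(
      list(model = "anchor", iterations = 3, voxel_pitch = 0.05,
           export_meshes = FALSE),
      check_keys(envelope, c("model", "iterations", "voxel_pitch",
                             "export_meshes"), "envelope")),
    maps = utils::modifyList(
      list(secondary_landmark = "nucleolus", pitch = 0.05,
           s_range = c(-2.5, 2.5), r_range = c(0, 2.5), n_bins = 18,
           min_points = 50),
      check_keys(maps, c("secondary_landmark", "pitch", "s_range", "r_range",
                         "n_bins", "min_points"), "maps")))
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(cfg, stage) {
  all_stages <- c("simulate", "detect", "correct", "cluster", "fit",
                  "quantify", "map")
  derive_seeds(cfg$seed, length(all_stages))[match(stage, all_stages)]
}

art_path <- function(cfg, name) file.path(cfg$out_dir, name)

need_artifact <- function(cfg, name, producer) {
  p <- art_path(cfg, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "': run the '", producer,
         "' stage first", call. = FALSE)
  p
}

write_csv_plain <- function(x, path) {
  df <- as.data.frame(x)
  # flatten list columns, if any slipped through
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
}

# rebuild the nested nuclei tibble from the flat stage artifacts
nuclei_from_artifacts <- function(det_path, nuc_path) {
  det <- tibble::as_tibble(read.csv(det_path))
  nuc <- tibble::as_tibble(read.csv(nuc_path))
  nuc$detections <- lapply(nuc$nucleus_id, function(id) {
    d <- det[det$nucleus_id == id, ]
    d$nucleus_id <- NULL
    d
  })
  nuc
}

nuclei_to_artifacts <- function(nuclei, cfg, det_name, nuc_name) {
  det <- dplyr::bind_rows(lapply(seq_len(nrow(nuclei)), function(i) {
    d <- nuclei$detections[[i]]
    d$nucleus_id <- nuclei$nucleus_id[i]
    d
  }))
  det <- det[, c("nucleus_id", setdiff(names(det), "nucleus_id"))]
  flat <- nuclei[, !vapply(nuclei, is.list, TRUE)]
  write_csv_plain(det, art_path(cfg, det_name))
  write_csv_plain(flat, art_path(cfg, nuc_name))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order, each reading its predecessor's
#' CSV/JSON artifacts from the output directory and writing its own, so any
#' stage can be rerun in isolation. Stage order: simulate (or image input) ->
#' detect (spot detection, nucleus grouping, nucleolus segmentation, SPB
#' identification) -> correct (round-nucleus aberration fit + correction) ->
#' cluster (1-3 k-means clusters per nucleus) -> fit (envelope reconstruction,
#' geometry) -> quantify (axis statistics, cumulative curves) -> map
#' (landmark-aligned density maps and axial profile).
#'
#' @param config a [pipeline_config()].
#' @return the run report (also written to `report.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- unclass(config)
  jsonlite::write_json(cfg_json, art_path(config, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  report <- list()
  for (stage in config$stages) {
    report[[stage]] <- switch(stage,
      simulate = stage_simulate(config),
      detect = stage_detect(config),
      correct = stage_correct(config),
      cluster = stage_cluster(config),
      fit = stage_fit(config),
      quantify = stage_quantify(config),
      map = stage_map(config))
  }
  report$parameters <- cfg_json
  jsonlite::write_json(report, art_path(config, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

stage_simulate <- function(cfg) {
  sm <- cfg$simulate
  pop <- simulate_population(
    n_nuclei = sm$n_nuclei, kind = sm$kind, npc_median = sm$npc_median,
    radius_median = sm$radius_median %||% 0.894,
    radius_sdlog = sm$radius_sdlog %||% 0.12,
    seed = stage_seed(cfg, "simulate"))
  # inject axial aberration so the correction stage has something to remove
  if (!is.null(sm$aberration_coef)) {
    for (i in seq_len(nrow(pop))) {
      ctr <- c(pop$true_center_x[i], pop$true_center_y[i], pop$true_center_z[i])
      pop$detections[[i]] <- apply_axial_stretch(
        pop$detections[[i]], ctr, mode = "polynomial", coef = sm$aberration_coef)
    }
  }
  # flatten to a raw detections table (one field of view)
  det <- dplyr::bind_rows(lapply(seq_len(nrow(pop)), function(i) {
    d <- pop$detections[[i]]
    tibble::tibble(channel = "npc", x_um = d$x, y_um = d$y, z_um = d$z,
                   amplitude = d$amplitude, background = 0,
                   sigma_xy_um = NA_real_, sigma_z_um = NA_real_,
                   residual = NA_real_)
  }))
  write_csv_plain(det, art_path(cfg, "detections_raw.csv"))
  truth <- pop[, !vapply(pop, is.list, TRUE)]
  write_csv_plain(truth, art_path(cfg, "ground_truth.csv"))
  # simulated landmark positions stand in for the nucleolus channel
  write_csv_plain(
    truth[, c("nucleus_id", "nucleolus_x", "nucleolus_y", "nucleolus_z",
              "nucleolar_volume")],
    art_path(cfg, "nucleolus_truth.csv"))
  list(n_nuclei = nrow(pop), n_detections = nrow(det))
}

stage_detect <- function(cfg) {
  dt <- cfg$detection
  if (!is.null(cfg$input$stack_prefixes)) {
    dets <- lapply(cfg$input$stack_prefixes, function(pfx) {
      st <- read_stack(pfx, voxel_size = cfg$voxel_size)
      detect_spots(st, channel = "npc", min_separation = dt$min_separation,
                   threshold_k = dt$threshold_k)
    })
    det <- dplyr::bind_rows(dets)
  } else {
    det <- tibble::as_tibble(read.csv(
      need_artifact(cfg, "detections_raw.csv", "simulate")))
  }
  nuclei <- group_into_nuclei(det, linkage_radius = dt$linkage_radius,
                              min_detections = dt$min_detections)
  grp_report <- attr(nuclei, "report")
  nuclei <- detect_spb(nuclei, brightness_factor = dt$spb_brightness_factor)
  # nucleolus: segment from image channel, else adopt simulated landmarks
  if (!is.null(cfg$input$stack_prefixes)) {
    st <- read_stack(cfg$input$stack_prefixes[[1]], voxel_size = cfg$voxel_size)
    if ("nucleolus" %in% names(st$channels))
      nuclei <- segment_nucleolus(st, nuclei)
  } else if (file.exists(art_path(cfg, "nucleolus_truth.csv"))) {
    tru <- read.csv(art_path(cfg, "nucleolus_truth.csv"))
    truth <- read.csv(art_path(cfg, "ground_truth.csv"))
    nuclei$nucleolus_x <- nuclei$nucleolus_y <- nuclei$nucleolus_z <- NA_real_
    nuclei$nucleolar_volume <- NA_real_
    # match simulated nuclei to detected groups by nearest center
    for (i in seq_len(nrow(nuclei))) {
      d2 <- (truth$true_center_x - nuclei$center_x[i])^2 +
            (truth$true_center_y - nuclei$center_y[i])^2 +
            (truth$true_center_z - nuclei$center_z[i])^2
      j <- which.min(d2)
      nuclei$nucleolus_x[i] <- tru$nucleolus_x[j]
      nuclei$nucleolus_y[i] <- tru$nucleolus_y[j]
      nuclei$nucleolus_z[i] <- tru$nucleolus_z[j]
      nuclei$nucleolar_volume[i] <- tru$nucleolar_volume[j]
    }
  }
  nuclei_to_artifacts(nuclei, cfg, "detections_grouped.csv", "nuclei.csv")
  c(list(n_nuclei = nrow(nuclei),
         n_with_spb = sum(is.finite(nuclei$spb_x))), grp_report)
}

stage_correct <- function(cfg) {
  nuclei <- nuclei_from_artifacts(
    need_artifact(cfg, "detections_grouped.csv", "detect"),
    need_artifact(cfg, "nuclei.csv", "detect"))
  sd_ <- stage_seed(cfg, "correct")
  if (!is.null(cfg$aberration$model_path)) {
    model <- read_aberration_model(cfg$aberration$model_path)
    n_round <- NA_integer_
  } else {
    round_nuclei <- select_round_nuclei(
      nuclei, eccentricity_max = cfg$aberration$eccentricity_max, seed = sd_)
    samples <- compute_samples(round_nuclei)
    model <- fit_aberration(samples)
    n_round <- nrow(round_nuclei)
  }
  write_aberration_model(model, art_path(cfg, "aberration_model.json"))
  corrected <- correct_detections(nuclei, model)
  rep_ <- attr(corrected, "correction_report")
  nuclei_to_artifacts(corrected, cfg, "detections_corrected.csv",
                      "nuclei_corrected.csv")
  list(n_nuclei = nrow(corrected), n_round_used = n_round,
       a = model$a, b = model$b, c = model$c,
       n_clamped = rep_$n_clamped, n_dropped = rep_$n_dropped)
}

stage_cluster <- function(cfg) {
  nuclei <- nuclei_from_artifacts(
    need_artifact(cfg, "detections_corrected.csv", "correct"),
    need_artifact(cfg, "nuclei_corrected.csv", "correct"))
  seeds <- derive_seeds(stage_seed(cfg, "cluster"), max(1, nrow(nuclei)))
  ks <- integer(nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    det <- nuclei$detections[[i]]
    P <- as_xyz_matrix(det)
    k <- if (nrow(P) >= 12) choose_k(P, seed = seeds[i]) else 1L
    asg <- kmeans_cluster(P, k, seed = seeds[i])
    det$cluster_id <- asg$labels
    nuclei$detections[[i]] <- det
    ks[i] <- k
  }
  nuclei$k <- ks
  nuclei_to_artifacts(nuclei, cfg, "detections_clustered.csv",
                      "nuclei_clustered.csv")
  list(n_nuclei = nrow(nuclei), k_table = as.list(table(ks)))
}

stage_fit <- function(cfg) {
  nuclei <- nuclei_from_artifacts(
    need_artifact(cfg, "detections_clustered.csv", "cluster"),
    need_artifact(cfg, "nuclei_clustered.csv", "cluster"))
  en <- cfg$envelope
  nuclei <- fit_envelopes(nuclei, model = en$model, iterations = en$iterations,
                          seed = stage_seed(cfg, "fit"),
                          voxel_pitch = en$voxel_pitch,
                          keep_meshes = isTRUE(en$export_meshes))
  if (isTRUE(en$export_meshes)) {
    mesh_dir <- art_path(cfg, "meshes")
    dir.create(mesh_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(nuclei))) {
      for (cl in seq_along(nuclei$meshes[[i]] %||% list())) {
        write_ply(nuclei$meshes[[i]][[cl]],
                  file.path(mesh_dir, sprintf("%s_cluster%d.ply",
                                              nuclei$cell_id[i], cl)))
      }
    }
    nuclei$meshes <- NULL
  }
  geom <- tibble::tibble(cell_id = nuclei$cell_id, n_clusters = nuclei$k,
                         model = nuclei$model, surface_um2 = nuclei$surface,
                         volume_um3 = nuclei$volume,
                         sphericity = nuclei$sphericity)
  write_csv_plain(geom, art_path(cfg, "geometry.csv"))
  nuclei_to_artifacts(nuclei, cfg, "detections_fitted.csv", "nuclei_fitted.csv")
  list(n_nuclei = nrow(nuclei), n_fitted = sum(is.finite(nuclei$volume)),
       median_volume_um3 = median(nuclei$volume, na.rm = TRUE),
       median_sphericity = median(nuclei$sphericity, na.rm = TRUE))
}

stage_quantify <- function(cfg) {
  nuclei <- nuclei_from_artifacts(
    need_artifact(cfg, "detections_fitted.csv", "fit"),
    need_artifact(cfg, "nuclei_fitted.csv", "fit"))
  stats_ <- nucleus_statistics(nuclei)
  write_csv_plain(stats_, art_path(cfg, "statistics.csv"))
  curves <- list(alpha_deg = stats_$alpha_deg,
                 sphericity = nuclei$sphericity,
                 volume_um3 = nuclei$volume)
  for (nm in names(curves)) {
    v <- curves[[nm]][is.finite(curves[[nm]])]
    if (length(v))
      write_csv_plain(cumulative_frequency(v),
                      art_path(cfg, sprintf("cumfreq_%s.csv", nm)))
  }
  list(n_nuclei = nrow(stats_),
       median_alpha_deg = median(stats_$alpha_deg, na.rm = TRUE))
}

stage_map <- function(cfg) {
  nuclei <- nuclei_from_artifacts(
    need_artifact(cfg, "detections_fitted.csv", "fit"),
    need_artifact(cfg, "nuclei_fitted.csv", "fit"))
  mp <- cfg$maps
  ali <- align_population(nuclei, secondary_landmark = mp$secondary_landmark,
                          target = "npc")
  map <- kde_map(ali, pitch = mp$pitch, s_range = mp$s_range,
                 r_range = mp$r_range, min_points = mp$min_points)
  grid <- tidy(map)
  write_csv_plain(grid, art_path(cfg, "map_npc.csv"))
  prof <- axial_density_profile(ali, n_bins = mp$n_bins,
                                min_points = mp$min_points)
  write_csv_plain(prof, art_path(cfg, "axial_profile.csv"))
  spb_ok <- sum(is.finite(nuclei$spb_x))
  if (spb_ok >= mp$min_points) {
    ali_spb <- align_population(nuclei, secondary_landmark = mp$secondary_landmark,
                                target = "spb")
    map_spb <- kde_map(ali_spb, pitch = mp$pitch, s_range = mp$s_range,
                       r_range = mp$r_range, min_points = mp$min_points)
    write_csv_plain(tidy(map_spb), art_path(cfg, "map_spb.csv"))
  }
  list(n_points = nrow(ali), n_skipped = attr(ali, "n_skipped"),
       n_spb_points = spb_ok)
}
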