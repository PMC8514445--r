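# End-to-end pipelines wired from the module functions, configured by a
# flat YAML section or an R list; the command-line interface in
# inst/cli/mesomap is a thin wrapper around run_pipeline().

pipeline_params <- list(
  simulate = c("out_dir", "seed", "rotation_deg", "scale", "translation_px",
               "jitter_sigma", "dropout", "noise_sigma", "vessel_count"),
  `atlas-to-brain` = c("landmarks", "mask", "image", "out_dir", "mode",
                       "min_confidence", "boundary", "dilate", "export",
                       "mm_per_px"),
  `brain-to-atlas` = c("landmarks", "mask", "image", "out_dir", "mode",
                       "min_confidence", "boundary", "mm_per_px"),
  sensory = c("movie", "events", "pre", "post", "baseline_frames", "out_dir",
              "centroid_frac"),
  `mbfm-build` = c("movie", "mask", "k_motifs", "motif_len", "lambda",
                   "n_iter", "seed", "knn_k", "n_templates", "out_dir"),
  `mbfm-match` = c("motifs", "templates", "r_threshold", "mask", "out_dir"),
  evaluate = c("landmarks_a", "landmarks_b", "mm_per_px", "out_dir"))

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[mesomap] ", fmt), ...))
}

load_config <- function(config, pipeline = NULL) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(pipeline)) {
      if (is.null(cfg[[pipeline]])) stop("config has no section: ", pipeline)
      cfg <- c(list(pipeline = pipeline), cfg[[pipeline]])
    }
    cfg
  } else {
    config
  }
}

#' Run an end-to-end pipeline
#'
#' Available pipelines: `simulate` (phantom scene + mock landmark files),
#' `atlas-to-brain` (warped atlas labels, boundary overlay, region ROIs),
#' `brain-to-atlas` (image registered to the atlas canvas),
#' `sensory` (stimulus-triggered peak map and activation centroid),
#' `mbfm-build` (motif discovery, clustering, template MBFM) and
#' `mbfm-match` (template matching + new MBFM), plus `evaluate` (landmark
#' error report between two landmark files).
#'
#' @param config a named list with a `pipeline` entry plus pipeline
#'   parameters, or a YAML path (with `pipeline` naming the flat section to
#'   run). Unknown keys are rejected. All randomness is controlled by seeds
#'   in the config, so a rerun with the same config writes byte-identical
#'   CSV/JSON artifacts.
#' @param pipeline pipeline name when `config` is a YAML path.
#' @param quiet suppress progress messages.
#' @return invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config, pipeline = NULL, quiet = FALSE) {
  cfg <- load_config(config, pipeline)
  name <- cfg$pipeline
  if (is.null(name) || !name %in% names(pipeline_params)) {
    stop("unknown pipeline: ", if (is.null(name)) "<missing>" else name)
  }
  extra <- setdiff(names(cfg), c("pipeline", pipeline_params[[name]]))
  if (length(extra)) {
    stop("unknown config keys for pipeline ", name, ": ",
         paste(extra, collapse = ", "))
  }
  for (key in c("landmarks", "mask", "image", "movie", "events", "motifs",
                "templates", "landmarks_a", "landmarks_b")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("pipeline ", name, ": input file not found: ", cfg[[key]])
    }
  }
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage(quiet, "pipeline %s -> %s", name, out_dir)
  fn <- switch(name,
               simulate = pipeline_simulate,
               `atlas-to-brain` = pipeline_atlas_to_brain,
               `brain-to-atlas` = pipeline_brain_to_atlas,
               sensory = pipeline_sensory,
               `mbfm-build` = pipeline_mbfm_build,
               `mbfm-match` = pipeline_mbfm_match,
               evaluate = pipeline_evaluate)
  artifacts <- fn(cfg, out_dir, quiet)
  log_stage(quiet, "done: %d artifacts", length(artifacts))
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_simulate <- function(cfg, out_dir, quiet) {
  seed <- cfg$seed %||% 1L
  spec <- phantom_spec(noise_sigma = cfg$noise_sigma %||% 5,
                       vessel_count = cfg$vessel_count %||% 6L,
                       seed = seed)
  scene <- make_phantom(spec)
  mis <- misalignment_spec(
    rotation_deg = cfg$rotation_deg %||% c(-30, 30),
    scale = cfg$scale %||% c(0.8, 1.2),
    translation_px = cfg$translation_px %||% c(-20, 20),
    seed = seed)
  log_stage(quiet, "simulate: phantom + misalignment (seed %d)", seed)
  scene <- perturb_alignment(scene, mis)
  save_phantom(scene, out_dir)
  obs <- mock_landmarks(scene, jitter_sigma = cfg$jitter_sigma %||% 0,
                        dropout = cfg$dropout %||% 0, seed = seed)
  write_landmarks_csv(obs, file.path(out_dir, "observed_landmarks.csv"))
  list(scene = out_dir,
       landmarks = file.path(out_dir, "observed_landmarks.csv"))
}

resolve_mask <- function(cfg, image) {
  boundary <- cfg$boundary %||% "file"
  if (boundary == "otsu") {
    if (is.null(image)) stop("boundary=otsu requires an image")
    otsu_segment(image)$mask
  } else {
    if (is.null(cfg$mask)) stop("boundary=file requires a mask path")
    read_mask_png(cfg$mask)
  }
}

pipeline_atlas_to_brain <- function(cfg, out_dir, quiet) {
  ref <- synthetic_atlas(cfg$mm_per_px %||% 0.05)
  obs <- read_landmarks_csv(cfg$landmarks)
  image <- if (!is.null(cfg$image)) read_image(cfg$image) else NULL
  mask <- resolve_mask(cfg, image)
  log_stage(quiet, "atlas-to-brain: %d landmark observations", nrow(obs))
  fit <- atlas_to_brain(ref$atlas, obs, ref$defs, ref$ccs, mask,
                        mode = cfg$mode %||% "default",
                        min_confidence = cfg$min_confidence %||% 0.5)
  labs <- fit$labels
  if (isTRUE(cfg$dilate)) labs <- dilate_once(labs)
  write_label_image(labs, file.path(out_dir, "warped_labels.png"))
  write_mask_png(fit$boundary, file.path(out_dir, "warped_boundary.png"))
  rois <- label_by_id(labs, mask, ref$atlas$regions)
  bcol <- obs$col[obs$index == 5L]
  bregma_col <- if (length(bcol)) bcol[1] else ncol(mask) / 2
  rois <- order_spatial(rois, bregma_col)
  export_rois(rois, file.path(out_dir, "rois.json"), "json")
  arts <- list(labels = file.path(out_dir, "warped_labels.png"),
               boundary = file.path(out_dir, "warped_boundary.png"),
               rois = file.path(out_dir, "rois.json"))
  if (!is.null(cfg$export) && grepl("mat", cfg$export)) {
    export_rois(rois, file.path(out_dir, "rois.mat"), "matfile")
    arts$rois_mat <- file.path(out_dir, "rois.mat")
  }
  roi_table <- data.frame(
    roi_number = vapply(rois, `[[`, integer(1), "roi_number"),
    region_id = vapply(rois, `[[`, integer(1), "region_id"),
    acronym = vapply(rois, `[[`, character(1), "acronym"),
    center_row = vapply(rois, function(r) r$center[1], numeric(1)),
    center_col = vapply(rois, function(r) r$center[2], numeric(1)))
  utils::write.csv(roi_table, file.path(out_dir, "rois.csv"),
                   row.names = FALSE)
  arts$roi_table <- file.path(out_dir, "rois.csv")
  arts
}

pipeline_brain_to_atlas <- function(cfg, out_dir, quiet) {
  ref <- synthetic_atlas(cfg$mm_per_px %||% 0.05)
  obs <- read_landmarks_csv(cfg$landmarks)
  image <- read_image(cfg$image)
  mask <- resolve_mask(cfg, image)
  log_stage(quiet, "brain-to-atlas: registering %d x %d image",
            nrow(image), ncol(image))
  reg <- brain_to_atlas(image, obs, ref$defs, ref$ccs, mask,
                        atlas = ref$atlas,
                        mode = cfg$mode %||% "default",
                        min_confidence = cfg$min_confidence %||% 0.5)
  write_image(reg$image, file.path(out_dir, "registered.tiff"))
  write_mask_png(reg$mask, file.path(out_dir, "registered_mask.png"))
  write_affine_json(reg$maps$left, file.path(out_dir, "transform_left.json"))
  write_affine_json(reg$maps$right, file.path(out_dir, "transform_right.json"))
  list(image = file.path(out_dir, "registered.tiff"),
       mask = file.path(out_dir, "registered_mask.png"),
       left = file.path(out_dir, "transform_left.json"),
       right = file.path(out_dir, "transform_right.json"))
}

pipeline_sensory <- function(cfg, out_dir, quiet) {
  movie <- read_movie_tiff(cfg$movie)
  events <- utils::read.csv(cfg$events)$frame
  pre <- cfg$pre %||% 5L
  post <- cfg$post %||% 15L
  baseline <- if (!is.null(cfg$baseline_frames)) {
    seq_len(cfg$baseline_frames)
  } else seq_len(dim(movie)[1])
  log_stage(quiet, "sensory: %d events, window %d+%d", length(events), pre, post)
  dff <- compute_dff(movie, baseline, offset = 1e-6)
  avg <- stimulus_average(dff, events, pre, post)
  sm <- peak_map(avg$epoch, avg$stim_frame,
                 centroid_frac = cfg$centroid_frac %||% 0.75)
  write_image(sm$peak_map, file.path(out_dir, "peak_map.tiff"),
              max_value = max(sm$peak_map, 1e-9))
  utils::write.csv(
    data.frame(peak_row = sm$peak_px[1], peak_col = sm$peak_px[2],
               centroid_row = sm$centroid_px[1],
               centroid_col = sm$centroid_px[2]),
    file.path(out_dir, "sensory_peaks.csv"), row.names = FALSE)
  list(peak_map = file.path(out_dir, "peak_map.tiff"),
       peaks = file.path(out_dir, "sensory_peaks.csv"))
}

pipeline_mbfm_build <- function(cfg, out_dir, quiet) {
  movie <- read_movie_tiff(cfg$movie)
  mask <- read_mask_png(cfg$mask)
  K <- cfg$k_motifs %||% 3L
  L <- cfg$motif_len %||% 5L
  log_stage(quiet, "mbfm-build: convNMF K=%d L=%d on %d frames",
            K, L, dim(movie)[1])
  X <- movie_to_matrix(movie, mask)
  ms <- convnmf(X, K = K, L = L, lambda = cfg$lambda %||% 0,
                n_iter = cfg$n_iter %||% 100, seed = cfg$seed %||% 1L)
  imgs <- motif_images(ms, mask)
  for (k in seq_along(imgs)) {
    write_image(imgs[[k]], file.path(out_dir, sprintf("motif_%02d.tiff", k)),
                max_value = 1)
  }
  cl <- cluster_motifs(imgs, mask, k = cfg$knn_k %||% 15,
                       seed = cfg$seed %||% 1L)
  utils::write.csv(data.frame(motif_id = seq_along(imgs), cluster = cl$labels),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  tpl <- if (cl$n_clusters >= 2L) {
    suppressWarnings(make_templates(imgs, cl$labels,
                                    n_templates = cfg$n_templates %||% 6,
                                    mask = mask))
  } else {
    list(templates = imgs, mbfm = make_mbfm(imgs))
  }
  write_image(tpl$mbfm, file.path(out_dir, "template_mbfm.tiff"), max_value = 1)
  list(clusters = file.path(out_dir, "clusters.csv"),
       mbfm = file.path(out_dir, "template_mbfm.tiff"))
}

pipeline_mbfm_match <- function(cfg, out_dir, quiet) {
  new_stack <- read_movie_tiff(cfg$motifs)
  tpl_stack <- read_movie_tiff(cfg$templates)
  mask <- if (!is.null(cfg$mask)) read_mask_png(cfg$mask) else NULL
  to_list <- function(stack) {
    lapply(seq_len(dim(stack)[1]), function(i) stack[i, , ])
  }
  log_stage(quiet, "mbfm-match: %d motifs vs %d templates",
            dim(new_stack)[1], dim(tpl_stack)[1])
  res <- match_motifs(to_list(new_stack), to_list(tpl_stack),
                      r_threshold = cfg$r_threshold %||% 0.5, mask = mask)
  utils::write.csv(res$assignment, file.path(out_dir, "assignment.csv"),
                   row.names = FALSE)
  arts <- list(assignment = file.path(out_dir, "assignment.csv"))
  if (!is.null(res$mbfm)) {
    write_image(res$mbfm, file.path(out_dir, "mbfm.tiff"), max_value = 1)
    arts$mbfm <- file.path(out_dir, "mbfm.tiff")
  }
  arts
}

pipeline_evaluate <- function(cfg, out_dir, quiet) {
  a <- read_landmarks_csv(cfg$landmarks_a)
  b <- read_landmarks_csv(cfg$landmarks_b)
  rep <- landmark_errors(a, b, mm_per_px = cfg$mm_per_px %||% 0.05)
  log_stage(quiet, "evaluate: %d shared landmarks", rep$n)
  jsonlite::write_json(
    list(mean = rep$mean, sem = rep$sem, rmse = rep$rmse, n = rep$n,
         per_landmark = rep$per_landmark),
    file.path(out_dir, "landmark_errors.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  list(report = file.path(out_dir, "landmark_errors.json"))
}
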