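#' Run configuration
#'
#' A single structured configuration driving every pipeline command.
#' Recognized top-level keys: `seed`, `log_level`, `paths` (with
#' `workdir`), `study` (`n_subjects`, `clips_per_subject`,
#' `distance_range`), `scene`, `denoise`, `features`, `forest` and
#' `grid` (`n_trees`, `max_depth`, `max_features` vectors). Unknown keys
#' are rejected; sub-configuration entries are validated by their
#' constructors.
#'
#' @param x Path to a YAML file, or a named list of overrides.
#' @return An object of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  known <- c("seed", "log_level", "paths", "study", "scene", "denoise",
             "features", "forest", "grid")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- list(
    seed = if (is.null(x$seed)) 1L else as.integer(x$seed),
    log_level = if (is.null(x$log_level)) "info" else x$log_level,
    paths = modifyList(list(workdir = "neomotion-run"),
                       if (is.null(x$paths)) list() else x$paths),
    study = modifyList(list(n_subjects = 20, clips_per_subject = 6,
                            distance_range = c(230, 800)),
                       if (is.null(x$study)) list() else x$study),
    grid = modifyList(list(n_trees = c(50, 100, 200),
                           max_depth = c(4, 8, 0),
                           max_features = c(2, 4, 8)),
                      if (is.null(x$grid)) list() else x$grid)
  )
  scene_args <- if (is.null(x$scene)) list() else x$scene
  if (!is.null(scene_args$frame_shape))
    scene_args$frame_shape <- as.integer(unlist(scene_args$frame_shape))
  cfg$scene <- do.call(scene_config, c(scene_args, list(seed = cfg$seed)))
  cfg$denoise <- do.call(denoise_config,
                         if (is.null(x$denoise)) list() else x$denoise)
  cfg$features <- do.call(feature_config,
                          if (is.null(x$features)) list() else x$features)
  cfg$forest <- do.call(forest_config,
                        c(if (is.null(x$forest)) list() else x$forest,
                          list(seed = cfg$seed)))
  structure(cfg, class = "run_config")
}

log_msg <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(...)
  invisible(NULL)
}

dataset_dir <- function(cfg) file.path(cfg$paths$workdir, "dataset")
features_dir <- function(cfg) file.path(cfg$paths$workdir, "features")

study_from_config <- function(cfg) {
  generate_study(cfg$study$n_subjects, cfg$study$clips_per_subject,
                 cfg = cfg$scene, distance_range = cfg$study$distance_range,
                 seed = cfg$seed)
}

#' Simulate a synthetic study to disk
#'
#' Generates the configured multi-subject study and writes every clip in
#' the on-disk formats of the I/O layer (NPY depth stack + JSON sidecar
#' with metadata, label CSV), plus a `manifest.json` listing all clips.
#' Reruns with the same configuration are byte-identical.
#'
#' @param cfg A [run_config] (or path / list accepted by it).
#' @return Path of the written manifest, invisibly.
#' @export
run_simulate <- function(cfg) {
  cfg <- run_config_of(cfg)
  dir.create(dataset_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  study <- study_from_config(cfg)
  entries <- lapply(study, function(cl) {
    stem <- file.path(dataset_dir(cfg), cl$clip_id)
    frames <- cl$source$get(seq_len(cl$source$n_frames))
    write_depth_stack(frames, paste0(stem, ".npy"), fps = cl$source$fps,
                      metadata = cl$metadata)
    write_labels(cl$labels, paste0(stem, "_labels.csv"))
    log_msg(cfg, "wrote clip ", cl$clip_id)
    c(list(clip_id = cl$clip_id, subject_id = cl$subject_id,
           stack = paste0(cl$clip_id, ".npy"),
           labels = paste0(cl$clip_id, "_labels.csv"),
           n_frames = cl$source$n_frames, fps = cl$source$fps),
      unclass(cl$metadata))
  })
  manifest <- file.path(dataset_dir(cfg), "manifest.json")
  jsonlite::write_json(list(n_clips = length(entries), clips = entries),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_manifest <- function(cfg) {
  manifest <- file.path(dataset_dir(cfg), "manifest.json")
  if (!file.exists(manifest))
    stop("no dataset manifest at ", manifest, "; run run_simulate() first")
  jsonlite::read_json(manifest, simplifyVector = FALSE)
}

#' Denoise and featurize a simulated dataset
#'
#' Reads every clip in the manifest, runs the denoising cascade and
#' feature extraction, and writes one feature CSV per clip. Corrupt
#' clips are skipped with a logged error; if every clip fails, the
#' command itself fails.
#'
#' @param cfg A [run_config] (or path / list accepted by it).
#' @return Invisible character vector of written feature CSV paths.
#' @export
run_extract <- function(cfg) {
  cfg <- run_config_of(cfg)
  man <- read_manifest(cfg)
  dir.create(features_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (e in man$clips) {
    out <- tryCatch({
      stack <- read_depth_stack(file.path(dataset_dir(cfg), e$stack))
      pp <- preprocess_clip(stack$frames, cfg$denoise)
      feats <- extract_features(pp$diffs, pp$depths, cfg$features)
      path <- file.path(features_dir(cfg),
                        paste0(e$clip_id, "_features.csv"))
      write_feature_table(feats, path)
      nv <- vapply(pp$diffs, function(d) sum(d$valid), numeric(1))
      log_msg(cfg, sprintf(
        "clip %s: %d s, mean valid diff px %.0f", e$clip_id,
        length(pp$diffs), mean(nv)))
      path
    }, error = function(err) {
      warning("clip ", e$clip_id, " failed: ", conditionMessage(err))
      NULL
    })
    if (!is.null(out)) written <- c(written, out)
  }
  if (length(written) == 0) stop("feature extraction failed for every clip")
  invisible(written)
}

load_labelled_dataset <- function(cfg) {
  man <- read_manifest(cfg)
  clips <- list()
  for (e in man$clips) {
    fpath <- file.path(features_dir(cfg), paste0(e$clip_id, "_features.csv"))
    if (!file.exists(fpath)) next
    clips[[length(clips) + 1]] <- list(
      subject_id = e$subject_id, clip_id = e$clip_id,
      features = read_feature_table(fpath),
      labels = read_labels(file.path(dataset_dir(cfg), e$labels)),
      metadata = clip_metadata(e$subject_id, e$bed_type, e$cover_type,
                               e$camera_location, e$distance_mm,
                               if (is.null(e$gestational_age_weeks) ||
                                   is.na(e$gestational_age_weeks)) NA_real_
                               else e$gestational_age_weeks))
  }
  if (length(clips) == 0) stop("no extracted features found; run run_extract()")
  motion_dataset(clips)
}

#' Train a motion model on every extracted clip
#'
#' Pools all extracted seconds, fits the forest, selects the optimal
#' operating threshold from the out-of-bag training ROC and persists the
#' model (with configurations and threshold) to `model.rds` in the work
#' directory.
#'
#' @param cfg A [run_config] (or path / list accepted by it).
#' @return Path of the written model file, invisibly.
#' @export
run_train <- function(cfg) {
  cfg <- run_config_of(cfg)
  dataset <- load_labelled_dataset(cfg)
  pooled <- pool_clips(dataset)
  model <- fit_forest(pooled$features, pooled$labels, cfg$forest)
  ok <- !is.na(model$oob_probs)
  troc <- roc_curve(model$oob_probs[ok], pooled$labels[ok])
  model$threshold <- troc$optimal_threshold
  path <- file.path(cfg$paths$workdir, "model.rds")
  write_motion_model(model, path, denoise_cfg = cfg$denoise,
                     feature_cfg = cfg$features)
  log_msg(cfg, sprintf("trained on %d seconds; OOB AUC %.3f; threshold %.3f",
                       length(pooled$labels), troc$auc, model$threshold))
  invisible(path)
}

#' Predict per-second motion for every extracted clip
#'
#' Applies the persisted model and its stored operating threshold,
#' writing one CSV per clip with columns `second_index`, `probability`,
#' `predicted`.
#'
#' @param cfg A [run_config] (or path / list accepted by it).
#' @return Invisible character vector of written prediction CSV paths.
#' @export
run_predict <- function(cfg) {
  cfg <- run_config_of(cfg)
  obj <- read_motion_model(file.path(cfg$paths$workdir, "model.rds"))
  model <- obj$model
  dataset <- load_labelled_dataset(cfg)
  outdir <- file.path(cfg$paths$workdir, "predictions")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(dataset, function(cl) {
    sig <- predict_proba(model, cl$features, threshold = model$threshold)
    df <- data.frame(second_index = cl$features$second_index,
                     probability = sig$probs,
                     predicted = classify_motion(sig))
    p <- file.path(outdir, paste0(cl$clip_id, "_predictions.csv"))
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Leave-one-out evaluation of a simulated, extracted dataset
#'
#' Runs [loocv()] on the extracted features and writes per-clip and
#' summary CSVs, the per-fold thresholds, and diagnostic plots (per-clip
#' AUC against camera distance; AUC histogram).
#'
#' @param cfg A [run_config] (or path / list accepted by it).
#' @return The `loocv_report`, invisibly.
#' @export
run_evaluate <- function(cfg) {
  cfg <- run_config_of(cfg)
  dataset <- load_labelled_dataset(cfg)
  report <- loocv(dataset, cfg$forest, seed = cfg$seed)
  outdir <- file.path(cfg$paths$workdir, "evaluation")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$per_clip, file.path(outdir, "per_clip.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(report$summary, file.path(outdir, "summary.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(report$thresholds$per_fold, file.path(outdir, "thresholds.csv"),
            row.names = FALSE, quote = FALSE)
  pc <- report$per_clip[!is.na(report$per_clip$auc), ]
  grDevices::png(file.path(outdir, "auc_vs_distance.png"), 800, 600)
  graphics::plot(pc$distance_mm, pc$auc, xlab = "camera distance (mm)",
                 ylab = "per-clip test ROC-AUC",
                 main = "Per-clip AUC vs camera distance", pch = 19)
  grDevices::dev.off()
  grDevices::png(file.path(outdir, "auc_hist.png"), 800, 600)
  graphics::hist(pc$auc, breaks = 20, xlab = "per-clip test ROC-AUC",
                 main = "Distribution of per-clip AUC")
  grDevices::dev.off()
  log_msg(cfg, sprintf("evaluated %d clips: mean AUC %.3f", nrow(pc),
                       mean(pc$auc)))
  invisible(report)
}

#' Grid-search forest and denoise parameters on the configured study
#'
#' Builds the configured synthetic study in memory, sweeps the forest
#' grid of the configuration (optionally combined with a list of
#' denoising configurations) and writes the score table and the winning
#' configuration.
#'
#' @param cfg A [run_config] (or path / list accepted by it).
#' @param denoise_grid Optional list of [denoise_config] objects;
#'   defaults to the single configured one.
#' @return The [grid_search()] result, invisibly.
#' @export
run_grid_search <- function(cfg, denoise_grid = NULL) {
  cfg <- run_config_of(cfg)
  study <- study_from_config(cfg)
  g <- cfg$grid
  forest_grid <- list()
  for (nt in g$n_trees) for (md in g$max_depth) for (mf in g$max_features)
    forest_grid[[length(forest_grid) + 1]] <-
      forest_config(n_trees = nt, max_depth = md, max_features = mf,
                    seed = cfg$seed)
  if (is.null(denoise_grid)) denoise_grid <- list(cfg$denoise)
  res <- grid_search(study, forest_grid, denoise_grid, cfg$features,
                     seed = cfg$seed)
  outdir <- file.path(cfg$paths$workdir, "grid")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$scores, file.path(outdir, "scores.csv"),
            row.names = FALSE, quote = FALSE)
  yaml::write_yaml(unclass(res$best_forest),
                   file.path(outdir, "best_forest.yaml"))
  invisible(res)
}

run_config_of <- function(x) {
  if (inherits(x, "run_config")) x else run_config(x)
}
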