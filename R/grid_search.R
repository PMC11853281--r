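#' Grid search over forest and denoising parameters
#'
#' Evaluates every combination of the supplied forest and denoising
#' configurations under the per-subject leave-one-out protocol of
#' [loocv()] and scores each combination by the mean of the square roots
#' of the per-clip test ROC-AUCs; maximizing this objective discourages
#' both false positives and false negatives. Features are recomputed for
#' every denoising configuration. Ties are broken toward the smaller
#' model (fewer trees, then shallower).
#'
#' @param study A `motion_study`: clips with frame sources and labels
#'   (raw frames are needed so each denoising configuration can be
#'   applied from scratch).
#' @param forest_grid List of [forest_config] objects.
#' @param denoise_grid List of [denoise_config] objects.
#' @param feature_cfg A [feature_config] shared by all combinations.
#' @param seed Base seed passed to [loocv()].
#' @return List with `best_forest`, `best_denoise` and `scores` (one row
#'   per combination: indices, n_trees, max_depth, objective).
#' @export
grid_search <- function(study, forest_grid = list(forest_config()),
                        denoise_grid = list(denoise_config()),
                        feature_cfg = feature_config(), seed = 1) {
  if (length(forest_grid) == 0 || length(denoise_grid) == 0)
    stop("empty parameter grid")
  rows <- list()
  for (di in seq_along(denoise_grid)) {
    dataset <- extract_study_features(study, denoise_grid[[di]], feature_cfg)
    for (fi in seq_along(forest_grid)) {
      rep_ <- loocv(dataset, forest_grid[[fi]], seed = seed)
      auc <- rep_$per_clip$auc
      obj <- mean(sqrt(auc[!is.na(auc)]))
      fc <- forest_grid[[fi]]
      rows[[length(rows) + 1]] <- data.frame(
        denoise_index = di, forest_index = fi, n_trees = fc$n_trees,
        max_depth = fc$max_depth, max_features = fc$max_features,
        objective = obj)
    }
  }
  scores <- do.call(rbind, rows)
  # argmax; ties -> fewer trees, then shallower (0 = unlimited = deepest)
  depth_rank <- ifelse(scores$max_depth == 0, Inf, scores$max_depth)
  ord <- order(-scores$objective, scores$n_trees, depth_rank)
  best <- scores[ord[1], ]
  list(best_forest = forest_grid[[best$forest_index]],
       best_denoise = denoise_grid[[best$denoise_index]],
       scores = scores)
}
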