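#' Bundle per-clip features, labels and metadata into a dataset
#'
#' @param clips List of labelled clips; each clip is a list with
#'   `subject_id`, `clip_id`, `features` (data frame from
#'   [extract_features()]), `labels` (0/1 per second, same row count) and
#'   `metadata` (a [clip_metadata]).
#' @return An object of class `motion_dataset`.
#' @export
motion_dataset <- function(clips) {
  for (cl in clips) {
    if (nrow(cl$features) != length(cl$labels))
      stop("clip ", cl$clip_id, ": features and labels differ in length")
    if (!inherits(cl$metadata, "clip_metadata"))
      stop("clip ", cl$clip_id, ": missing clip_metadata")
  }
  structure(clips, class = "motion_dataset")
}

#' @export
print.motion_dataset <- function(x, ...) {
  subj <- unique(vapply(x, `[[`, character(1), "subject_id"))
  cat(sprintf("<motion_dataset: %d clips, %d subjects, %d labelled seconds>\n",
              length(x), length(subj),
              sum(vapply(x, function(cl) length(cl$labels), integer(1)))))
  invisible(x)
}

pool_clips <- function(clips) {
  list(features = do.call(rbind, lapply(clips, function(cl)
         strip_second_index(cl$features))),
       labels = unlist(lapply(clips, `[[`, "labels"), use.names = FALSE))
}

#' Per-subject leave-one-out cross-validation
#'
#' For each subject in turn, the forest is trained on the pooled seconds
#' of every other subject; a training ROC curve is built from the
#' model's out-of-bag probabilities on that pooled training data and its
#' optimal operating threshold (maximum mean of sensitivity and
#' specificity) is selected. The model and the transferred threshold are
#' then applied to each positional clip of the held-out subject
#' separately, yielding a per-clip test ROC-AUC and the
#' sensitivity/specificity at the transferred threshold. Clips whose
#' truth labels are single-class have no defined ROC: their rows are kept
#' with `NA` scores but excluded from the summaries (with a warning).
#'
#' @param dataset A [motion_dataset] with at least two subjects.
#' @param forest_cfg A [forest_config].
#' @param seed Base seed; fold `k` trains with seed `seed + k`.
#' @return An object of class `loocv_report`: `per_clip` (one row per
#'   positional clip), `summary` (mean/SD of sensitivity, specificity and
#'   AUC over clips with defined scores), `thresholds` (per-fold training
#'   thresholds with mean/SD) and `excluded` (clip ids without a ROC).
#' @export
loocv <- function(dataset, forest_cfg = forest_config(),
                  seed = forest_cfg$seed) {
  subjects <- unique(vapply(dataset, `[[`, character(1), "subject_id"))
  if (length(subjects) < 2) stop("need >= 2 subjects for leave-one-out")

  rows <- list()
  folds <- data.frame(subject_id = subjects, threshold = NA_real_,
                      train_auc = NA_real_, train_sensitivity = NA_real_,
                      train_specificity = NA_real_)
  excluded <- character(0)
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    train <- pool_clips(dataset[vapply(dataset, function(cl)
      cl$subject_id != s, logical(1))])
    cfg <- forest_cfg
    cfg$seed <- as.integer(seed + k)
    model <- fit_forest(train$features, train$labels, cfg)
    oob <- model$oob_probs
    ok <- !is.na(oob)
    troc <- roc_curve(oob[ok], train$labels[ok], id = paste0("fold-", s))
    thr <- troc$optimal_threshold
    folds$threshold[k] <- thr
    folds$train_auc[k] <- troc$auc
    folds$train_sensitivity[k] <- troc$optimal$sensitivity
    folds$train_specificity[k] <- troc$optimal$specificity

    for (cl in dataset[vapply(dataset, function(cl)
      cl$subject_id == s, logical(1))]) {
      sig <- predict_proba(model, cl$features, threshold = thr)
      md <- cl$metadata
      if (length(unique(cl$labels)) < 2) {
        warning("clip ", cl$clip_id,
                " has single-class truth labels; excluded from summaries")
        excluded <- c(excluded, cl$clip_id)
        auc <- sens <- spec <- NA_real_
      } else {
        auc <- roc_curve(sig, cl$labels, id = cl$clip_id)$auc
        ss <- sens_spec_at(sig$probs, cl$labels, thr)
        sens <- ss[["sensitivity"]]
        spec <- ss[["specificity"]]
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s, clip_id = cl$clip_id,
        bed_type = md$bed_type, cover_type = md$cover_type,
        camera_location = md$camera_location, distance_mm = md$distance_mm,
        gestational_age_weeks = md$gestational_age_weeks,
        n_seconds = length(cl$labels), threshold = thr,
        auc = auc, sensitivity = sens, specificity = spec)
    }
  }
  per_clip <- do.call(rbind, rows)
  scored <- per_clip[!is.na(per_clip$auc), ]
  summary <- data.frame(
    metric = c("sensitivity", "specificity", "auc"),
    mean = c(mean(scored$sensitivity), mean(scored$specificity),
             mean(scored$auc)),
    sd = c(sd(scored$sensitivity), sd(scored$specificity), sd(scored$auc)))
  thresholds <- list(per_fold = folds,
                     mean = mean(folds$threshold), sd = sd(folds$threshold))
  structure(list(per_clip = per_clip, summary = summary,
                 thresholds = thresholds, excluded = excluded),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<loocv_report: %d clips, %d subjects>\n", nrow(x$per_clip),
              length(unique(x$per_clip$subject_id))))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  mean %-11s %.3f (SD %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  cat(sprintf("  mean training threshold %.3f (SD %.3f)\n",
              x$thresholds$mean, x$thresholds$sd))
  invisible(x)
}

#' Per-clip AUC split by a capture condition
#'
#' Tags every per-clip AUC row of a LOOCV report with the requested
#' grouping (bed type, cover type, camera location, or the term/preterm
#' split at 37 weeks) alongside the camera distance, mirroring the
#' distance-versus-condition performance analysis.
#'
#' @param report A `loocv_report`.
#' @param key One of `"bed_type"`, `"cover_type"`, `"camera_location"`,
#'   `"term_preterm"`.
#' @return Data frame with columns `group`, `distance_mm`, `auc`,
#'   `subject_id`, `clip_id`.
#' @export
subgroup_auc <- function(report, key) {
  pc <- report$per_clip
  group <- switch(key,
    bed_type = pc$bed_type,
    cover_type = pc$cover_type,
    camera_location = pc$camera_location,
    term_preterm = ifelse(pc$gestational_age_weeks > 37, "term", "preterm"),
    stop("unknown grouping key: ", key)
  )
  data.frame(group = group, distance_mm = pc$distance_mm, auc = pc$auc,
             subject_id = pc$subject_id, clip_id = pc$clip_id)
}
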