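# Small random fixtures built in code.

# Random depth frame with a mix of valid, dropout and out-of-range pixels.
random_depth_frame <- function(h = 10, w = 10, valid_range = c(200, 1000),
                               p_dropout = 0.1, depth_lim = c(150, 1100)) {
  d <- matrix(runif(h * w, depth_lim[1], depth_lim[2]), h, w)
  d[runif(h * w) < p_dropout] <- 0
  depth_frame(round(d), valid_range = valid_range)
}

# Random difference frame with a validity mask.
random_diff_frame <- function(h = 10, w = 10, p_valid = 0.85,
                              diff_sd = 60, second_index = 0L) {
  v <- matrix(runif(h * w) < p_valid, h, w)
  x <- matrix(rnorm(h * w, 0, diff_sd), h, w)
  # sprinkle exact zeros so region labelling sees inactive valid pixels
  x[runif(h * w) < 0.2] <- 0
  depth_diff_frame(x, v, second_index)
}

# A constant-rate list of frames from a 3-D array [h, w, t].
frames_from_array <- function(arr, fps = 30, valid_range = c(0.5, 1e9)) {
  lapply(seq_len(dim(arr)[3]), function(k)
    depth_frame(arr[, , k], timestamp = (k - 1) / fps,
                valid_range = valid_range))
}

# Tiny directly constructed labelled clips for protocol-level tests:
# features carry an informative column so folds are learnable.
toy_labelled_clip <- function(subject_id, clip_id, n_seconds = 12,
                              distance = 500, informative = TRUE) {
  labels <- rep_len(c(0L, 1L), n_seconds)   # both classes guaranteed
  f <- as.data.frame(matrix(rnorm(n_seconds * 16, 0, 0.05), n_seconds, 16))
  names(f) <- feature_names()
  if (informative) f$spatial_scale_1 <- labels + rnorm(n_seconds, 0, 0.1)
  f <- cbind(second_index = seq_len(n_seconds) - 1L, f)
  list(subject_id = subject_id, clip_id = clip_id, features = f,
       labels = labels,
       metadata = clip_metadata(subject_id, "bassinet", "sleep suit",
                                "above", distance, 36))
}

toy_dataset <- function(n_subjects = 4, clips_per_subject = 2,
                        n_seconds = 12, seed = 42) {
  set.seed(seed)
  clips <- list()
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(if (length(clips_per_subject) == 1) clips_per_subject
                      else clips_per_subject[i])) {
      sid <- sprintf("T%02d", i)
      clips[[length(clips) + 1]] <- toy_labelled_clip(
        sid, sprintf("%s-C%d", sid, j), n_seconds,
        distance = runif(1, 230, 800))
    }
  }
  motion_dataset(clips)
}

# Fast scene configuration for pipeline-level unit tests.
small_scene <- function(duration_s = 20, seed = 1, ...) {
  scene_config(frame_shape = c(64, 80), duration_s = duration_s,
               events = list(region_px_range = c(45, 120)),
               seed = seed, ...)
}
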