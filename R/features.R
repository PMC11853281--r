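#' Feature configuration
#'
#' Thresholds for the graded motion features. `area_thresholds_mm` grade
#' the spatial-scale features (fraction of the frame moving by more than
#' each threshold); `sum_thresholds_mm` grade the summed-difference
#' features (per-pixel motion magnitude above each threshold);
#' `reference_depth_mm` anchors the quadratic distance normalization of
#' the spatial-scale features.
#'
#' @param area_thresholds_mm Five strictly ascending thresholds in mm.
#' @param sum_thresholds_mm Four strictly ascending thresholds in mm.
#' @param reference_depth_mm Reference camera distance in mm.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(area_thresholds_mm = c(1, 3, 6, 12, 25),
                           sum_thresholds_mm = c(1, 5, 15, 40),
                           reference_depth_mm = 500) {
  if (length(area_thresholds_mm) != 5 || any(diff(area_thresholds_mm) <= 0))
    stop("`area_thresholds_mm` must be 5 strictly ascending values")
  if (length(sum_thresholds_mm) != 4 || any(diff(sum_thresholds_mm) <= 0))
    stop("`sum_thresholds_mm` must be 4 strictly ascending values")
  if (reference_depth_mm <= 0) stop("`reference_depth_mm` must be > 0")
  structure(
    list(area_thresholds_mm = as.numeric(area_thresholds_mm),
         sum_thresholds_mm = as.numeric(sum_thresholds_mm),
         reference_depth_mm = as.numeric(reference_depth_mm)),
    class = "feature_config"
  )
}

#' Names of the 16 per-second features, in their fixed column order
#'
#' The order is stable across package versions so that persisted models
#' and feature tables remain portable:
#' `spatial_scale_1..5` (graded moving-area fractions, distance
#' normalized), `summed_diff_1..4` (graded per-pixel summed |difference|),
#' `depth_mean`, `depth_median`, `depth_p25`, `depth_p75` (valid-depth
#' summaries in mm), `depth_sd_sub75` (standard deviation of depths at or
#' below their 75th percentile), `depth_kurtosis` (excess kurtosis of
#' valid depths) and `scene_p75` (75th percentile of valid depths, a
#' camera-distance proxy).
#'
#' @return Character vector of length 16.
#' @export
feature_names <- function() {
  c(paste0("spatial_scale_", 1:5), paste0("summed_diff_", 1:4),
    "depth_mean", "depth_median", "depth_p25", "depth_p75",
    "depth_sd_sub75", "depth_kurtosis", "scene_p75")
}

#' Spatial-scale-of-motion features
#'
#' For each graded threshold `T`, the fraction of valid depth pixels
#' whose absolute depth difference exceeds `T`, multiplied by
#' `(mean valid depth / reference depth)^2`. The quadratic factor
#' compensates the shrinking of apparent (pixel) area with camera
#' distance, so the features track the physical spatial scale of motion.
#' All five are 0 when the frame has no valid depth pixels.
#'
#' @param diff A [depth_diff_frame].
#' @param depth The clipped averaged [depth_frame] aligned with `diff`.
#' @param cfg A [feature_config].
#' @return Numeric vector of 5 non-negative values.
#' @export
spatial_scale_features <- function(diff, depth, cfg = feature_config()) {
  vd <- depth_valid_mask(depth)
  nd <- sum(vd)
  if (nd == 0) return(numeric(5))
  scale <- (mean(depth$depths[vd]) / cfg$reference_depth_mm)^2
  a <- abs(diff$diffs[diff$valid])
  vapply(cfg$area_thresholds_mm,
         function(T) sum(a > T) / nd * scale, numeric(1))
}

#' Magnitude-of-motion (summed difference) features
#'
#' For each graded threshold `U`, the sum of absolute depth differences
#' over valid pixels exceeding `U`, divided by the number of valid
#' difference pixels. Sensitive to strong motion confined to small areas.
#'
#' @param diff A [depth_diff_frame].
#' @param cfg A [feature_config].
#' @return Numeric vector of 4 non-negative values (0 on empty frames).
#' @export
summed_diff_features <- function(diff, cfg = feature_config()) {
  nv <- sum(diff$valid)
  if (nv == 0) return(numeric(4))
  a <- abs(diff$diffs[diff$valid])
  vapply(cfg$sum_thresholds_mm,
         function(U) sum(a[a > U]) / nv, numeric(1))
}

#' Average-depth features
#'
#' Mean, median, 25th and 75th percentile of the valid depths (mm).
#' These let the classifier normalize motion evidence with respect to
#' camera distance. A fully invalid frame yields sentinel zeros (with a
#' warning).
#'
#' @param depth A [depth_frame].
#' @return Numeric vector of 4 values in mm.
#' @export
average_depth_features <- function(depth) {
  v <- depth$depths[depth_valid_mask(depth)]
  if (length(v) == 0) {
    warning("frame has no valid depth pixels; depth summaries set to 0")
    return(numeric(4))
  }
  c(mean(v), median(v), quantile(v, 0.25, names = FALSE, type = 7),
    quantile(v, 0.75, names = FALSE, type = 7))
}

#' Skewed-placement features
#'
#' Three features that help when the camera views the scene at a skewed
#' angle (head's or foot's end), where depths spread over a wide band:
#' the standard deviation of valid depths at or below their 75th
#' percentile (a robust spread measure), the excess kurtosis of valid
#' depths (Fisher convention, 0 for Gaussian; indicative of noise in the
#' frame), and the 75th percentile of valid depths (a measure of how far
#' the scene is from the camera). Kurtosis is defined as 0 when fewer
#' than 4 valid pixels are present or when the depths are constant.
#'
#' @param depth A [depth_frame].
#' @return Numeric vector of 3 values.
#' @export
skew_features <- function(depth) {
  v <- depth$depths[depth_valid_mask(depth)]
  if (length(v) == 0) return(numeric(3))
  p75 <- quantile(v, 0.75, names = FALSE, type = 7)
  sub <- v[v <= p75]
  s <- if (length(sub) >= 2) sd(sub) else 0
  k <- 0
  if (length(v) >= 4 && var(v) > 0) {
    k <- e1071::kurtosis(v, type = 1)
    if (!is.finite(k)) k <- 0
  }
  c(s, k, p75)
}

#' Extract the 16 per-second features of a clip
#'
#' Combines [spatial_scale_features()], [summed_diff_features()],
#' [average_depth_features()] and [skew_features()] for every second.
#' The depth-based features for second `t` use the clipped averaged
#' frame of span `t` (the earlier of the two spans differenced).
#'
#' @param diffs List of cleaned [depth_diff_frame] objects.
#' @param depths List of clipped averaged [depth_frame] objects, of
#'   length `length(diffs)` or `length(diffs) + 1`.
#' @param cfg A [feature_config].
#' @return Data frame with `second_index` plus the 16 columns of
#'   [feature_names()], one row per difference frame.
#' @export
extract_features <- function(diffs, depths, cfg = feature_config()) {
  n <- length(diffs)
  if (!length(depths) %in% c(n, n + 1L))
    stop(sprintf("length mismatch: %d diff frames vs %d depth frames",
                 n, length(depths)))
  rows <- lapply(seq_len(n), function(t) {
    c(spatial_scale_features(diffs[[t]], depths[[t]], cfg),
      summed_diff_features(diffs[[t]], cfg),
      average_depth_features(depths[[t]]),
      skew_features(depths[[t]]))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- feature_names()
  cbind(second_index = vapply(diffs, `[[`, integer(1), "second_index"), out)
}
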