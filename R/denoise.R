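#' Denoising configuration
#'
#' Parameters of the temporal averaging and the five-stage noise-removal
#' cascade applied to the depth stream before feature extraction.
#'
#' @param span_s Length of a span in seconds (the classification period).
#' @param frames_per_median Number of frames whose per-pixel median forms
#'   the averaged frame of each span (split between the start and the end
#'   of the span).
#' @param lower_pct,upper_pct Percentile clipping bounds: depths below the
#'   `lower_pct`-th or above the `upper_pct`-th percentile of in-range
#'   depths are removed (defaults 3 and 87).
#' @param pct_range_mm Depth range (mm) over which percentiles are
#'   computed; depths outside it are always removed. Default 200--1000 mm.
#' @param median_kernels Spatial median filter kernel sizes, applied in
#'   order (default 5x5 then 3x3).
#' @param max_diff_mm Absolute depth differences above this are removed as
#'   too large to be neonatal motion (default 150 mm).
#' @param min_region_px Connected regions of active difference pixels
#'   smaller than this are removed (default 40 px).
#' @param connectivity Pixel connectivity for region labelling, 4 or 8.
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(span_s = 1, frames_per_median = 10,
                           lower_pct = 3, upper_pct = 87,
                           pct_range_mm = c(200, 1000),
                           median_kernels = c(5, 3),
                           max_diff_mm = 150, min_region_px = 40,
                           connectivity = 8) {
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100))
    stop("require 0 <= lower_pct < upper_pct <= 100")
  if (any(median_kernels < 1) || any(median_kernels %% 2 != 1))
    stop("median kernels must be odd and >= 1")
  if (max_diff_mm <= 0) stop("max_diff_mm must be > 0")
  if (min_region_px < 1) stop("min_region_px must be >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (span_s <= 0 || frames_per_median < 1) stop("invalid span parameters")
  structure(
    list(span_s = span_s, frames_per_median = as.integer(frames_per_median),
         lower_pct = lower_pct, upper_pct = upper_pct,
         pct_range_mm = as.numeric(pct_range_mm),
         median_kernels = as.integer(median_kernels),
         max_diff_mm = max_diff_mm, min_region_px = as.integer(min_region_px),
         connectivity = as.integer(connectivity)),
    class = "denoise_config"
  )
}

# Median-average one span's worth of frames: the first ceiling(m/2) and
# last floor(m/2) frames of the span are pooled into one median, so the
# state reflects both ends of the span. Pooling two sub-windows ~0.8 s
# apart also comb-averages periodic respiratory displacement out of the
# span state, which keeps breathing off the motion-evidence raster. A
# pixel invalid in more than half of the contributing frames is invalid.
span_median_frame <- function(frames, frames_per_median, timestamp) {
  m <- frames_per_median
  n <- length(frames)
  if (n < m) stop("span has fewer frames than frames_per_median")
  pick <- if (n == m) seq_len(n) else
    c(seq_len(ceiling(m / 2)), n - seq_len(floor(m / 2)) + 1L)
  vr <- frames[[1]]$valid_range
  med <- cpp_span_median(lapply(frames[pick], `[[`, "depths"), vr[1], vr[2])
  depth_frame(matrix(med, nrow = nrow(frames[[1]]$depths)),
              timestamp = timestamp, valid_range = vr)
}

infer_fps <- function(frames) {
  if (length(frames) < 2) stop("need at least 2 frames to infer fps")
  dt <- frames[[2]]$timestamp - frames[[1]]$timestamp
  if (dt <= 0) stop("timestamps must be strictly increasing")
  round(1 / dt)
}

#' Temporal median averaging
#'
#' Splits a clip into consecutive spans of `span_s` seconds and computes,
#' for every span, a per-pixel median over the `frames_per_median` frames
#' at the start and end of the span (half each). This robustly averages
#' away single-frame outliers, and pooling the two sub-windows averages
#' periodic respiratory displacement out of the span state while genuine
#' sustained surface change passes through.
#'
#' @param frames List of [depth_frame] objects at a constant frame rate.
#' @param cfg A [denoise_config].
#' @return List of averaged [depth_frame] objects, one per span,
#'   timestamped at span starts.
#' @export
temporal_median <- function(frames, cfg = denoise_config()) {
  fps <- infer_fps(frames)
  fpspan <- round(fps * cfg$span_s)
  n_spans <- floor(length(frames) / fpspan)
  if (n_spans < 2)
    stop("clip shorter than 2 spans: no depth differences computable")
  lapply(seq_len(n_spans), function(t) {
    idx <- ((t - 1) * fpspan + 1):(t * fpspan)
    span_median_frame(frames[idx], cfg$frames_per_median,
                      timestamp = (t - 1) * cfg$span_s)
  })
}

#' Percentile clipping of a depth frame
#'
#' Computes the `lower_pct`-th and `upper_pct`-th percentiles (linear
#' interpolation between order statistics, the default type-7 estimator)
#' over pixels inside `pct_range_mm`, then invalidates pixels strictly
#' outside those percentiles or outside the range. This retains only the
#' depth band where the neonate lies.
#'
#' Frames with no in-range pixel are returned fully invalid and carry
#' attribute `all_invalid = TRUE` so downstream stages can skip them.
#'
#' @param frame A [depth_frame] (typically a temporally averaged one).
#' @param cfg A [denoise_config].
#' @return The clipped [depth_frame]; removed pixels are set to 0.
#' @export
clip_depth_percentiles <- function(frame, cfg = denoise_config()) {
  d <- frame$depths
  inr <- depth_valid_mask(frame) &
    d >= cfg$pct_range_mm[1] & d <= cfg$pct_range_mm[2]
  if (!any(inr)) {
    out <- depth_frame(matrix(0, nrow(d), ncol(d)), frame$timestamp,
                       frame$valid_range)
    out$valid <- matrix(FALSE, nrow(d), ncol(d))
    attr(out, "all_invalid") <- TRUE
    return(out)
  }
  q <- quantile(d[inr], c(cfg$lower_pct, cfg$upper_pct) / 100,
                names = FALSE, type = 7)
  keep <- inr & d >= q[1] & d <= q[2]
  d[!keep] <- 0
  out <- depth_frame(d, frame$timestamp, frame$valid_range)
  out$valid <- keep   # cache: later stages reuse the mask
  out
}

#' Depth differencing
#'
#' Subtracts consecutive averaged (and clipped) depth frames; the
#' difference is defined only where both frames are valid.
#'
#' @param prev,curr Consecutive [depth_frame] objects of equal shape.
#' @param second_index 0-based second index assigned to the difference.
#' @return A [depth_diff_frame] with `diffs = curr - prev`.
#' @export
depth_difference <- function(prev, curr, second_index = 0L) {
  stop_if_shape_mismatch(prev$depths, curr$depths, "depth frames")
  v <- depth_valid_mask(prev) & depth_valid_mask(curr)
  d <- curr$depths - prev$depths
  d[!v] <- 0
  depth_diff_frame(d, v, second_index)
}

#' Masked spatial median filtering
#'
#' Applies the configured median kernels in order (default 5x5 then 3x3).
#' Each valid pixel is replaced by the median over the valid pixels in
#' its window; invalid pixels are ignored rather than zero-filled, so
#' medians are not dragged toward zero at mask borders. This removes
#' small pixel regions of unusually high or low difference values and
#' smooths genuine motion regions.
#'
#' @param diff A [depth_diff_frame].
#' @param cfg A [denoise_config].
#' @return The filtered [depth_diff_frame] (validity mask unchanged).
#' @export
spatial_median_filter <- function(diff, cfg = denoise_config()) {
  d <- diff$diffs
  for (k in cfg$median_kernels)
    d <- cpp_masked_median_filter(d, diff$valid, k)
  depth_diff_frame(d, diff$valid, diff$second_index)
}

#' Large-difference removal
#'
#' Invalidates pixels whose absolute depth difference exceeds
#' `max_diff_mm` (default 150 mm): such changes are too large to be
#' neonatal motion, in either direction.
#'
#' @param diff A [depth_diff_frame].
#' @param cfg A [denoise_config].
#' @return The cleaned [depth_diff_frame].
#' @export
remove_large_differences <- function(diff, cfg = denoise_config()) {
  v <- diff$valid & abs(diff$diffs) <= cfg$max_diff_mm
  d <- diff$diffs
  d[!v] <- 0
  depth_diff_frame(d, v, diff$second_index)
}

#' Small-region removal
#'
#' Labels connected components (configured connectivity) of valid,
#' nonzero difference pixels and invalidates components smaller than
#' `min_region_px` (default 40 px): regions that small are considered
#' spurious rather than genuine neonatal motion. Zero-valued valid
#' pixels carry no motion evidence and are left untouched.
#'
#' @param diff A [depth_diff_frame].
#' @param cfg A [denoise_config].
#' @return The cleaned [depth_diff_frame].
#' @export
remove_small_regions <- function(diff, cfg = denoise_config()) {
  active <- diff$valid & diff$diffs != 0
  if (!any(active)) return(diff)
  lab <- cpp_label_components(active, cfg$connectivity)
  sizes <- tabulate(lab[lab > 0])
  small <- lab > 0 & sizes[pmax(lab, 1)] < cfg$min_region_px
  v <- diff$valid & !small
  d <- diff$diffs
  d[!v] <- 0
  depth_diff_frame(d, v, diff$second_index)
}

# ---------------------------------------------------------------------------
# Frame sources: a clip is either a materialized list of depth_frame or a
# lazy source that renders requested frame indices on demand (used by the
# synthetic generator so long clips never have to be held in memory).

#' Lazy frame source
#'
#' Wraps a frame-producing function so clips can be processed span by
#' span without materializing every frame.
#'
#' @param n_frames Total frame count.
#' @param fps Frame rate.
#' @param get Function taking a vector of 1-based frame indices and
#'   returning a list of [depth_frame] objects.
#' @return An object of class `frame_source`.
#' @export
frame_source <- function(n_frames, fps, get) {
  structure(list(n_frames = as.integer(n_frames), fps = fps, get = get),
            class = "frame_source")
}

as_frame_source <- function(x) {
  if (inherits(x, "frame_source")) return(x)
  if (is.list(x) && length(x) > 0 && inherits(x[[1]], "depth_frame"))
    return(frame_source(length(x), infer_fps(x), function(idx) x[idx]))
  stop("expected a list of depth_frame objects or a frame_source")
}

#' Preprocess a clip into cleaned depth-difference frames
#'
#' Runs the full per-clip pipeline: temporal median averaging per span,
#' percentile clipping, consecutive-span depth differencing, spatial
#' median filtering, large-difference removal and small-region removal,
#' in that order. A clip of `n` spans yields `n - 1` difference frames,
#' numbered by the index of the earlier span.
#'
#' @param x A list of [depth_frame] objects or a [frame_source].
#' @param cfg A [denoise_config].
#' @return List with `diffs` (list of cleaned [depth_diff_frame]) and
#'   `depths` (list of clipped averaged [depth_frame], one per span).
#' @export
preprocess_clip <- function(x, cfg = denoise_config()) {
  src <- as_frame_source(x)
  fpspan <- round(src$fps * cfg$span_s)
  if (fpspan < cfg$frames_per_median)
    stop("span too short for frames_per_median frames")
  n_spans <- floor(src$n_frames / fpspan)
  if (n_spans < 2)
    stop("clip shorter than 2 spans: no depth differences computable")

  m <- cfg$frames_per_median
  pick <- c(seq_len(ceiling(m / 2)), fpspan - seq_len(floor(m / 2)) + 1L)
  depths <- vector("list", n_spans)
  for (t in seq_len(n_spans)) {
    idx <- (t - 1L) * fpspan + pick
    avg <- span_median_frame(src$get(idx), m, timestamp = (t - 1) * cfg$span_s)
    depths[[t]] <- clip_depth_percentiles(avg, cfg)
  }
  diffs <- vector("list", n_spans - 1L)
  for (t in seq_len(n_spans - 1L)) {
    d <- depth_difference(depths[[t]], depths[[t + 1L]], second_index = t - 1L)
    d <- spatial_median_filter(d, cfg)
    d <- remove_large_differences(d, cfg)
    diffs[[t]] <- remove_small_regions(d, cfg)
  }
  list(diffs = diffs, depths = depths)
}
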