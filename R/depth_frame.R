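#' Depth frame
#'
#' A single-channel raster of distances (mm) from the depth camera to the
#' nearest surface. Pixels are "invalid" when they carry no genuine sensor
#' return; the sensor convention adopted here encodes such dropouts as 0,
#' and any depth outside `valid_range` is likewise treated as invalid.
#'
#' @param depths Numeric matrix of depths in mm (row-major scene raster,
#'   origin top-left). All finite entries must be non-negative.
#' @param timestamp Time of the frame in seconds from clip start.
#' @param valid_range Length-2 numeric, the plausible depth range in mm;
#'   pixels outside it are invalid. Default 200--1000 mm brackets the
#'   230--800 mm camera-to-chest distances the monitor is designed for.
#' @return An object of class `depth_frame`.
#' @export
depth_frame <- function(depths, timestamp = 0, valid_range = c(200, 1000)) {
  if (!is.matrix(depths) || !is.numeric(depths))
    stop("`depths` must be a numeric matrix")
  if (isTRUE(min(depths, na.rm = TRUE) < 0))
    stop("depths must be non-negative")
  if (length(valid_range) != 2 || valid_range[1] >= valid_range[2])
    stop("`valid_range` must be (min_mm, max_mm) with min < max")
  structure(
    list(depths = depths, timestamp = as.numeric(timestamp),
         valid_range = as.numeric(valid_range)),
    class = "depth_frame"
  )
}

#' Validity mask of a depth frame
#'
#' A pixel is valid iff its depth is strictly positive and inside the
#' frame's `valid_range`. Pipeline stages that already know the mask
#' cache it on the frame (`valid` element) to avoid recomputation.
#'
#' @param frame A `depth_frame`.
#' @return Logical matrix of the same shape as the frame.
#' @export
depth_valid_mask <- function(frame) {
  if (!is.null(frame[["valid"]])) return(frame[["valid"]])
  d <- frame$depths
  v <- d > 0 & d >= frame$valid_range[1] & d <= frame$valid_range[2]
  v & !is.na(v)
}

#' @export
print.depth_frame <- function(x, ...) {
  d <- dim(x$depths)
  nv <- sum(depth_valid_mask(x))
  cat(sprintf("<depth_frame %dx%d px, t = %.3f s, %d valid px (%.1f%%)>\n",
              d[1], d[2], x$timestamp, nv, 100 * nv / length(x$depths)))
  invisible(x)
}

#' Depth-difference frame
#'
#' Per-pixel signed depth change (mm) between two temporally averaged
#' depth frames one second apart: the motion-evidence raster. `diffs` is
#' meaningful only where `valid` is `TRUE`; invalid entries are stored
#' as 0.
#'
#' @param diffs Numeric matrix of signed depth changes in mm.
#' @param valid Logical matrix; `TRUE` where the difference is defined.
#' @param second_index 0-based index of the second this difference covers.
#' @return An object of class `depth_diff_frame`.
#' @export
depth_diff_frame <- function(diffs, valid, second_index = 0L) {
  if (!is.matrix(diffs) || !is.numeric(diffs))
    stop("`diffs` must be a numeric matrix")
  if (!is.matrix(valid) || !is.logical(valid) || !all(dim(valid) == dim(diffs)))
    stop("`valid` must be a logical matrix with the shape of `diffs`")
  diffs[!valid] <- 0
  structure(
    list(diffs = diffs, valid = valid, second_index = as.integer(second_index)),
    class = "depth_diff_frame"
  )
}

#' @export
print.depth_diff_frame <- function(x, ...) {
  d <- dim(x$diffs)
  act <- sum(x$valid & x$diffs != 0)
  cat(sprintf("<depth_diff_frame %dx%d px, second %d, %d valid px, %d active px>\n",
              d[1], d[2], x$second_index, sum(x$valid), act))
  invisible(x)
}

stop_if_shape_mismatch <- function(a, b, what = "frames") {
  if (!all(dim(a) == dim(b)))
    stop(sprintf("%s have mismatched shapes: %dx%d vs %dx%d",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)))
  invisible(NULL)
}
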