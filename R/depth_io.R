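#' @name capture-conditions
#' @title Capture-condition vocabularies
#' @description Enumerations of the bed, covering and camera-placement
#'   conditions under which clips are recorded.
#' @export
BED_TYPES <- c("bassinet", "covered isolette", "uncovered isolette")

#' @rdname capture-conditions
#' @export
COVER_TYPES <- c("bare skin", "sleep suit", "loosely covered",
                 "loosely swaddled", "tightly swaddled", "nested")

#' @rdname capture-conditions
#' @export
CAMERA_LOCATIONS <- c("above", "above-side", "foots end", "heads end", "side")

#' Clip metadata
#'
#' Capture conditions for one positional test run: bed and covering type,
#' camera placement, and the camera-to-chest distance.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param bed_type One of [BED_TYPES].
#' @param cover_type One of [COVER_TYPES].
#' @param camera_location One of [CAMERA_LOCATIONS].
#' @param distance_mm Camera-to-chest distance in mm, within 230--800.
#' @param gestational_age_weeks Optional gestational age (weeks), used for
#'   the term/preterm (> 37 / <= 37 weeks) subgroup split.
#' @return An object of class `clip_metadata`.
#' @export
clip_metadata <- function(subject_id, bed_type, cover_type, camera_location,
                          distance_mm, gestational_age_weeks = NA_real_) {
  bed_type <- match.arg(bed_type, BED_TYPES)
  cover_type <- match.arg(cover_type, COVER_TYPES)
  camera_location <- match.arg(camera_location, CAMERA_LOCATIONS)
  distance_mm <- as.numeric(distance_mm)
  if (distance_mm < 230 || distance_mm > 800)
    stop("`distance_mm` must lie in [230, 800]")
  structure(
    list(subject_id = as.character(subject_id), bed_type = bed_type,
         cover_type = cover_type, camera_location = camera_location,
         distance_mm = distance_mm,
         gestational_age_weeks = as.numeric(gestational_age_weeks)),
    class = "clip_metadata"
  )
}

# ---------------------------------------------------------------------------
# Depth stacks: NPY (uint16 mm, C order, shape T x H x W) + JSON sidecar.

npy_write_u16 <- function(frames_list, path) {
  t_ <- length(frames_list)
  h <- nrow(frames_list[[1]]); w <- ncol(frames_list[[1]])
  hdr <- sprintf("{'descr': '<u2', 'fortran_order': False, 'shape': (%d, %d, %d), }",
                 t_, h, w)
  # pad so magic(6) + version(2) + hlen(2) + header is a multiple of 64
  pad <- 64 - ((10 + nchar(hdr) + 1) %% 64)
  if (pad == 64) pad <- 0
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(hdr)), con, size = 2, endian = "little")
  writeBin(charToRaw(hdr), con)
  for (m in frames_list) {
    v <- as.integer(round(t(m)))          # C order: row by row
    if (any(v < 0 | v > 65535))
      stop("depths outside uint16 range [0, 65535] mm cannot be stored")
    writeBin(v, con, size = 2, endian = "little")
  }
  invisible(path)
}

npy_read_u16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  hdr <- rawToChar(readBin(con, "raw", hlen))
  if (!grepl("'<u2'", hdr, fixed = TRUE))
    stop("unsupported NPY dtype (expected '<u2') in ", path)
  if (!grepl("False", hdr, fixed = TRUE))
    stop("unsupported NPY layout (expected C order) in ", path)
  m <- regmatches(hdr, regexec("\\(([0-9]+),\\s*([0-9]+),\\s*([0-9]+)", hdr))[[1]]
  if (length(m) != 4) stop("could not parse NPY shape in ", path)
  shp <- as.integer(m[2:4])
  n <- prod(shp)
  v <- readBin(con, "integer", n, size = 2, endian = "little", signed = FALSE)
  if (length(v) != n) stop("truncated NPY payload in ", path)
  lapply(seq_len(shp[1]), function(k) {
    off <- (k - 1) * shp[2] * shp[3]
    matrix(v[(off + 1):(off + shp[2] * shp[3])], nrow = shp[2],
           ncol = shp[3], byrow = TRUE)
  })
}

sidecar_path <- function(path) paste0(sub("\\.npy$", "", path), ".json")

#' Write a depth-frame stack
#'
#' Stores frames as a `T x H x W` uint16 NPY array (integer millimetres)
#' plus a JSON sidecar holding `fps`, `valid_range_mm` and, optionally,
#' the clip metadata. Depths are rounded to integer mm on write;
#' processing elsewhere in the package is done in floating point.
#'
#' @param frames List of [depth_frame] objects with identical shapes.
#' @param path Output path (a `.json` sidecar is written next to it).
#' @param fps Frame rate in frames per second.
#' @param metadata Optional [clip_metadata] stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_depth_stack <- function(frames, path, fps = 30, metadata = NULL) {
  if (length(frames) == 0) stop("no frames to write")
  d0 <- dim(frames[[1]]$depths)
  for (k in seq_along(frames)) {
    dk <- dim(frames[[k]]$depths)
    if (!all(dk == d0))
      stop(sprintf("inconsistent frame shapes: frame %d is %dx%d, expected %dx%d",
                   k, dk[1], dk[2], d0[1], d0[2]))
  }
  npy_write_u16(lapply(frames, `[[`, "depths"), path)
  side <- list(fps = fps, valid_range_mm = frames[[1]]$valid_range)
  if (!is.null(metadata)) side$metadata <- unclass(metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a depth-frame stack
#'
#' Counterpart to [write_depth_stack()]. Timestamps are reconstructed as
#' `(0:(T-1)) / fps` from the sidecar frame rate.
#'
#' @param path Path to the NPY stack written by [write_depth_stack()].
#' @return List with `frames` (list of [depth_frame]), `fps`, and
#'   `metadata` ([clip_metadata] or `NULL`).
#' @export
read_depth_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar file ", sp,
         " (required keys: fps, valid_range_mm)")
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (key in c("fps", "valid_range_mm"))
    if (is.null(side[[key]]))
      stop("sidecar ", sp, " lacks required key `", key, "`")
  mats <- npy_read_u16(path)
  fps <- as.numeric(side$fps)
  vr <- as.numeric(side$valid_range_mm)
  frames <- lapply(seq_along(mats), function(k)
    depth_frame(mats[[k]] + 0.0, timestamp = (k - 1) / fps, valid_range = vr))
  md <- NULL
  if (!is.null(side$metadata)) {
    m <- side$metadata
    md <- clip_metadata(m$subject_id, m$bed_type, m$cover_type,
                        m$camera_location, m$distance_mm,
                        if (is.null(m$gestational_age_weeks)) NA_real_
                        else m$gestational_age_weeks)
  }
  list(frames = frames, fps = fps, metadata = md)
}

# ---------------------------------------------------------------------------
# Per-second label tables.

#' Read per-second motion truth labels
#'
#' Expects a CSV with header columns `second_index` (0-based, dense) and
#' `label` in \{0, 1\}. One label per second; a clip of `n` one-second
#' spans carries `n - 1` labels because classification operates on
#' differences between consecutive spans.
#'
#' @param path CSV path.
#' @return Integer vector of 0/1 labels, ordered by second.
#' @export
read_labels <- function(path) {
  df <- read.csv(path)
  req <- c("second_index", "label")
  if (!all(req %in% names(df)))
    stop("label file must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$second_index))
    stop("duplicate second_index in ", path, ": ",
         df$second_index[duplicated(df$second_index)][1])
  if (!all(df$label %in% c(0, 1)))
    stop("labels must be 0 or 1")
  df <- df[order(df$second_index), ]
  expect_idx <- seq(0, nrow(df) - 1)
  if (!all(df$second_index == expect_idx))
    stop("label series is not dense: missing second ",
         setdiff(expect_idx, df$second_index)[1])
  as.integer(df$label)
}

#' Write per-second motion truth labels
#'
#' @param labels Integer vector of 0/1 labels.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  df <- data.frame(second_index = seq_along(labels) - 1L,
                   label = as.integer(labels))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature tables.

#' Write a per-second feature table
#'
#' One row per second: `second_index` followed by the 16 named feature
#' columns of [feature_names()] (stable order across versions, so trained
#' models remain portable).
#'
#' @param features Data frame as produced by [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  need <- c("second_index", feature_names())
  if (!identical(names(features), need))
    stop("feature table columns must be exactly: ",
         paste(need, collapse = ", "))
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-second feature table
#'
#' @param path CSV path written by [write_feature_table()].
#' @return Data frame with `second_index` and the 16 feature columns.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path)
  need <- c("second_index", feature_names())
  if (!identical(names(df), need))
    stop("unexpected feature table columns in ", path)
  df
}
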