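# Run `code` with its own RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so generator determinism never interferes
# with user-level randomness.
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Synthetic scene configuration
#'
#' Describes a synthetic depth clip: a neonate-like half-ellipsoid
#' surface in front of a flat background, small periodic respiratory
#' displacement of a chest sub-ellipse, intermittent larger limb/torso
#' motion events, and depth-sensor noise (per-pixel Gaussian error
#' growing with distance, dropout pixels encoded as 0, and sporadic
#' outlier returns).
#'
#' Motion events are ellipses on the body, displaced along the camera
#' axis with a half-cosine onset/offset ramp (0.3 s) and a slow
#' within-event oscillation (0.25--0.75 Hz), so one-second depth
#' differences take graded intermediate values rather than a single
#' step.
#'
#' @param frame_shape `(H, W)` in pixels.
#' @param fps Frame rate (frames per second).
#' @param duration_s Clip duration in seconds.
#' @param background_depth_mm Flat background (mattress) depth.
#' @param body_depth_mm Camera-to-chest distance in mm (apex of the body
#'   surface); must be closer than the background.
#' @param body_axes_px Optional ellipse semi-axes `(rows, cols)` of the
#'   body; by default scaled inversely with distance.
#' @param respiration List: `amplitude_mm` (peak chest displacement,
#'   default 2) and `rate_bpm` (default 50).
#' @param events List: `rate_per_min` (Poisson arrival rate, default 4),
#'   `duration_s_range` (default 1--5 s), `region_px_range` (event area,
#'   default 50--500 px), `amplitude_mm_range` (default 5--120 mm; must
#'   stay below the 150 mm large-difference cut so real events survive
#'   denoising).
#' @param noise List: `sigma_mm` (Gaussian depth error at 300 mm, default
#'   0.5), `sigma_mm_far` (error at 900 mm, default 2; interpolated
#'   linearly in between, emulating stereo-depth error growth),
#'   `dropout_prob`, `outlier_prob`, `outlier_mm` (outlier magnitude
#'   scale).
#' @param seed Integer seed; every frame is a deterministic function of
#'   `(seed, frame_index)`.
#' @param valid_range_mm Valid depth range stored with the frames.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(frame_shape = c(240, 320), fps = 30,
                         duration_s = 300, background_depth_mm = 950,
                         body_depth_mm = 500, body_axes_px = NULL,
                         respiration = list(), events = list(),
                         noise = list(), seed = 1,
                         valid_range_mm = c(200, 1000)) {
  respiration <- modifyList(list(amplitude_mm = 2, rate_bpm = 50), respiration)
  events <- modifyList(list(rate_per_min = 4, duration_s_range = c(1, 5),
                            region_px_range = c(50, 500),
                            amplitude_mm_range = c(5, 120)), events)
  noise <- modifyList(list(sigma_mm = 0.5, sigma_mm_far = 2,
                           dropout_prob = 0.002, outlier_prob = 5e-4,
                           outlier_mm = 300), noise)
  if (body_depth_mm >= background_depth_mm)
    stop("body_depth_mm must be closer than background_depth_mm")
  if (max(events$amplitude_mm_range) >= 150)
    stop("event amplitudes must stay below 150 mm to survive denoising")
  if (duration_s < 2) stop("duration_s must be >= 2 seconds")
  structure(
    list(frame_shape = as.integer(frame_shape), fps = fps,
         duration_s = duration_s,
         background_depth_mm = background_depth_mm,
         body_depth_mm = body_depth_mm, body_axes_px = body_axes_px,
         respiration = respiration, events = events, noise = noise,
         seed = as.integer(seed), valid_range_mm = as.numeric(valid_range_mm)),
    class = "scene_config"
  )
}

# Elliptical weight field: indices of pixels inside the ellipse and a
# smooth sqrt(1 - rho^2) taper (1 at the centre, 0 at the rim).
ellipse_field <- function(H, W, centre, axes) {
  r <- matrix(seq_len(H), H, W)
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  rho2 <- ((r - centre[1]) / axes[1])^2 + ((c_ - centre[2]) / axes[2])^2
  idx <- which(rho2 <= 1)
  list(idx = idx, w = sqrt(pmax(0, 1 - rho2[idx])))
}

#' Build a synthetic scene
#'
#' Precomputes the static surface, the per-pixel noise level and the
#' full event schedule (arrivals, regions, amplitudes, oscillation
#' frequencies) so individual frames can be rendered independently and
#' deterministically with [render_scene_frame()].
#'
#' @param cfg A [scene_config].
#' @return An object of class `scene`, carrying `labels` (the per-second
#'   motion truth derived from the event schedule) and `events`.
#' @export
make_scene <- function(cfg) {
  with_rng_seed(cfg$seed, {
    H <- cfg$frame_shape[1]; W <- cfg$frame_shape[2]
    scale <- 500 / cfg$body_depth_mm
    # apparent size scales inversely with distance; at close range the
    # body genuinely overfills the view (the ellipse is clipped at the
    # frame edge), as a ~65-degree depth camera at 230-330 mm would see
    axes <- cfg$body_axes_px
    if (is.null(axes))
      axes <- pmax(c(8, 8), pmin(c(0.75 * H, 0.75 * W),
                                 c(0.30 * H, 0.35 * W) * scale))
    centre <- c((H + 1) / 2, (W + 1) / 2)
    body <- ellipse_field(H, W, centre, axes)
    base <- matrix(cfg$background_depth_mm, H, W)
    base[body$idx] <- cfg$background_depth_mm -
      (cfg$background_depth_mm - cfg$body_depth_mm) * body$w
    # static body relief: head, knees, arms and bedding folds raise or dip
    # parts of the surface, so the scene's closest depth band is scattered
    # over several structures rather than one smooth apex cap
    for (b in 1:8) {
      th <- runif(1, 0, 2 * pi)
      rad <- 0.9 * sqrt(runif(1))
      bc <- centre + rad * axes * c(cos(th), sin(th))
      ba <- pmax(3, runif(2, 6, 20) * scale)
      h <- sample(c(1, 1, 1, -1), 1) * runif(1, 15, 70)
      fld <- ellipse_field(H, W, bc, ba)
      on_body <- fld$idx %in% body$idx
      base[fld$idx[on_body]] <- base[fld$idx[on_body]] - h * fld$w[on_body]
    }
    base[body$idx] <- pmin(pmax(base[body$idx], cfg$body_depth_mm - 40),
                           cfg$background_depth_mm - 1)
    chest <- ellipse_field(H, W, centre - c(0.3 * axes[1], 0),
                           0.4 * axes)
    sigma <- cfg$noise$sigma_mm + (cfg$noise$sigma_mm_far - cfg$noise$sigma_mm) *
      pmin(1, pmax(0, (base - 300) / 600))
    body_area <- length(body$idx)

    ev_cfg <- cfg$events
    evs <- list()
    if (ev_cfg$rate_per_min > 0) {
      max_d <- max(ev_cfg$duration_s_range)
      lambda <- ev_cfg$rate_per_min / 60
      n_ev <- rpois(1, lambda * (cfg$duration_s + max_d))
      if (n_ev > 0) {
        starts <- sort(runif(n_ev, -max_d, cfg$duration_s))
        for (i in seq_len(n_ev)) {
          area <- runif(1, ev_cfg$region_px_range[1], ev_cfg$region_px_range[2])
          if (area > body_area)
            stop("event region (", round(area), " px) larger than body (",
                 body_area, " px)")
          q <- runif(1, 0.7, 1.4)
          r0 <- sqrt(area / pi)
          raxes <- c(r0 * sqrt(q), r0 / sqrt(q))
          # the whole patch stays on the body (limbs live at the
          # periphery too, so the feasible disc is not shrunk further)
          radmax <- max(0.25, 1 - 0.05 - max(raxes / axes))
          pick_pos <- function() {
            th <- runif(1, 0, 2 * pi)
            centre + radmax * sqrt(runif(1)) * axes * c(cos(th), sin(th))
          }
          evs[[i]] <- list(
            start = starts[i], duration = runif(1, ev_cfg$duration_s_range[1],
                                                ev_cfg$duration_s_range[2]),
            amplitude = runif(1, ev_cfg$amplitude_mm_range[1],
                              ev_cfg$amplitude_mm_range[2]),
            freq = runif(1, 0.25, 0.75), phase = runif(1, 0, 2 * pi),
            sign = sample(c(-1, 1), 1),
            # a limb both lifts/lowers (axial) and sweeps across the
            # scene (lateral): the patch travels from `from` to `to`
            from = pick_pos(), to = pick_pos(), axes_px = raxes)
        }
      }
    }
    ev_start <- vapply(evs, `[[`, numeric(1), "start")
    ev_end <- ev_start + vapply(evs, `[[`, numeric(1), "duration")

    # truth: second t (0-based) is motion iff an event observably alters
    # the state of span t or span t+1 -- the two spans whose averaged
    # frames are differenced. A span's state is the median over its ten
    # start/end frames, so an event must cover a majority of those
    # samples to register; that is exactly the "visible motion between
    # consecutive one-second frames" convention a human scorer applies.
    lo <- 4 / cfg$fps            # event must persist past the 5th sample
    hi <- 1 - 5 / cfg$fps        # or begin before the trailing window
    n_sec <- cfg$duration_s - 1
    labels <- vapply(seq_len(n_sec) - 1, function(t)
      as.integer(length(evs) > 0 &&
                   any(ev_start <= t + 1 + hi & ev_end > t + lo)),
      integer(1))

    structure(
      list(cfg = cfg, base = base, sigma = sigma, chest = chest,
           events = evs, labels = labels, body_idx = body$idx,
           n_frames = as.integer(round(cfg$duration_s * cfg$fps))),
      class = "scene")
  })
}

#' Render one frame of a synthetic scene
#'
#' Deterministic in `(scene seed, frame index)`: frames can be rendered
#' in any order or subset and always reproduce bit-identically.
#'
#' @param scene A `scene` from [make_scene()].
#' @param frame_idx 0-based frame index.
#' @return A [depth_frame] at timestamp `frame_idx / fps`.
#' @export
render_scene_frame <- function(scene, frame_idx) {
  cfg <- scene$cfg
  t <- frame_idx / cfg$fps
  d <- scene$base
  resp <- cfg$respiration
  if (resp$amplitude_mm > 0) {
    disp <- resp$amplitude_mm * 0.5 *
      (1 - cos(2 * pi * resp$rate_bpm / 60 * t))
    d[scene$chest$idx] <- d[scene$chest$idx] - disp * scene$chest$w
  }
  H <- nrow(d); W <- ncol(d)
  for (ev in scene$events) {
    if (t < ev$start || t >= ev$start + ev$duration) next
    edge <- min(t - ev$start, ev$start + ev$duration - t)
    ramp <- 0.5 * (1 - cos(pi * min(1, edge / 0.3)))
    # the limb is displaced away from rest for the whole event, with a
    # within-event oscillation so consecutive span states always differ
    osc <- 0.55 + 0.45 * sin(2 * pi * ev$freq * (t - ev$start) + ev$phase)
    disp <- ev$sign * ev$amplitude * ramp * osc
    # patch centre sweeps smoothly from `from` to `to` over the event
    u <- 0.5 * (1 - cos(pi * (t - ev$start) / ev$duration))
    pos <- ev$from + u * (ev$to - ev$from)
    i0 <- max(1, floor(pos[1] - ev$axes_px[1]))
    i1 <- min(H, ceiling(pos[1] + ev$axes_px[1]))
    j0 <- max(1, floor(pos[2] - ev$axes_px[2]))
    j1 <- min(W, ceiling(pos[2] + ev$axes_px[2]))
    if (i0 > i1 || j0 > j1) next
    rho2 <- outer(((i0:i1 - pos[1]) / ev$axes_px[1])^2,
                  ((j0:j1 - pos[2]) / ev$axes_px[2])^2, `+`)
    # near-rigid patch: full displacement over the core, soft rim band
    w <- pmin(1, 2.5 * sqrt(pmax(0, 1 - rho2)))
    d[i0:i1, j0:j1] <- pmin(cfg$background_depth_mm,
                            pmax(1, d[i0:i1, j0:j1] - disp * w))
  }
  nz <- cfg$noise
  if (nz$sigma_mm > 0 || nz$dropout_prob > 0 || nz$outlier_prob > 0) {
    fseed <- (cfg$seed %% 20011 + 1) * 100003 + frame_idx
    with_rng_seed(fseed, {
      np <- length(d)
      if (nz$sigma_mm > 0) d <- d + rnorm(np) * scene$sigma
      if (nz$outlier_prob > 0) {
        k <- rbinom(1, np, nz$outlier_prob)
        if (k > 0) {
          i <- sample.int(np, k)
          d[i] <- pmax(0, d[i] + sample(c(-1, 1), k, replace = TRUE) *
                            runif(k, 50, 50 + nz$outlier_mm))
        }
      }
      if (nz$dropout_prob > 0) {
        k <- rbinom(1, np, nz$dropout_prob)
        if (k > 0) d[sample.int(np, k)] <- 0
      }
    })
  }
  depth_frame(d, timestamp = t, valid_range = cfg$valid_range_mm)
}

default_metadata <- function(cfg, subject_id = "S1") {
  clip_metadata(subject_id, "bassinet", "sleep suit", "above",
                min(800, max(230, cfg$body_depth_mm)))
}

#' Generate a labelled synthetic clip
#'
#' @param cfg A [scene_config].
#' @param metadata Optional [clip_metadata]; a default is derived from
#'   the scene distance when omitted.
#' @return List with `frames` (all rendered [depth_frame] objects),
#'   `labels` (per-second truth, length `duration_s - 1`), `metadata`
#'   and the underlying `scene`.
#' @export
generate_clip <- function(cfg, metadata = NULL) {
  scene <- make_scene(cfg)
  frames <- lapply(seq_len(scene$n_frames) - 1L,
                   function(i) render_scene_frame(scene, i))
  list(frames = frames, labels = scene$labels,
       metadata = if (is.null(metadata)) default_metadata(cfg) else metadata,
       scene = scene)
}

#' Generate a lazily rendered synthetic clip
#'
#' Like [generate_clip()] but returns a [frame_source] instead of
#' materialized frames, so long clips can be denoised span by span
#' without ever holding the whole stack in memory.
#'
#' @inheritParams generate_clip
#' @param subject_id,clip_id Identifiers attached to the clip.
#' @return List with `source`, `labels`, `metadata`, `scene`,
#'   `subject_id`, `clip_id`.
#' @export
generate_clip_source <- function(cfg, metadata = NULL, subject_id = "S1",
                                 clip_id = "S1-C1") {
  scene <- make_scene(cfg)
  src <- frame_source(scene$n_frames, cfg$fps, function(idx)
    lapply(idx - 1L, function(i) render_scene_frame(scene, i)))
  list(source = src, labels = scene$labels,
       metadata = if (is.null(metadata)) default_metadata(cfg) else metadata,
       scene = scene, subject_id = subject_id, clip_id = clip_id)
}

#' Generate a synthetic multi-subject study
#'
#' Draws per-subject capture conditions (bed, covering, gestational age)
#' and per-clip camera placements and distances, then builds one
#' deterministic scene per positional clip. Per-clip seeds derive
#' reproducibly from the master seed.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param clips_per_subject Scalar or length-`n_subjects` vector of
#'   positional clips per subject.
#' @param cfg Base [scene_config] shared by all clips (per-clip distance
#'   and seed are overridden).
#' @param distance_range Camera-to-chest distance range (mm) sampled per
#'   clip; default 230--800.
#' @param seed Master seed.
#' @return An object of class `motion_study`: list of clip entries as
#'   returned by [generate_clip_source()].
#' @export
generate_study <- function(n_subjects, clips_per_subject,
                           cfg = scene_config(), distance_range = c(230, 800),
                           seed = 1) {
  if (n_subjects < 2) stop("need >= 2 subjects")
  ncl <- if (length(clips_per_subject) == 1)
    rep(clips_per_subject, n_subjects) else clips_per_subject
  if (length(ncl) != n_subjects)
    stop("clips_per_subject must be scalar or length n_subjects")
  clips <- list()
  with_rng_seed(seed, {
    for (i in seq_len(n_subjects)) {
      sid <- sprintf("S%02d", i)
      bed <- sample(BED_TYPES, 1)
      cover <- sample(COVER_TYPES, 1)
      ga <- runif(1, 28, 42)
      for (j in seq_len(ncl[i])) {
        dist <- runif(1, distance_range[1], distance_range[2])
        loc <- sample(CAMERA_LOCATIONS, 1)
        ccfg <- cfg
        ccfg$body_depth_mm <- dist
        ccfg$body_axes_px <- NULL
        ccfg$seed <- as.integer((seed + i * 1009L + j * 9176L) %% 2147483647L)
        md <- clip_metadata(sid, bed, cover, loc, dist, ga)
        clips[[length(clips) + 1]] <- generate_clip_source(
          ccfg, metadata = md, subject_id = sid,
          clip_id = sprintf("%s-C%d", sid, j))
      }
    }
  })
  structure(clips, class = "motion_study")
}

#' @export
print.motion_study <- function(x, ...) {
  subj <- unique(vapply(x, `[[`, character(1), "subject_id"))
  cat(sprintf("<motion_study: %d clips, %d subjects, %.0f s each>\n",
              length(x), length(subj), x[[1]]$scene$cfg$duration_s))
  invisible(x)
}

#' Denoise and featurize one study clip
#'
#' @param clip A clip entry from [generate_study()] or
#'   [generate_clip_source()].
#' @param denoise_cfg A [denoise_config].
#' @param feature_cfg A [feature_config].
#' @return A labelled clip: list with `subject_id`, `clip_id`,
#'   `features`, `labels`, `metadata`.
#' @export
extract_clip_features <- function(clip, denoise_cfg = denoise_config(),
                                  feature_cfg = feature_config()) {
  pp <- preprocess_clip(clip$source, denoise_cfg)
  feats <- extract_features(pp$diffs, pp$depths, feature_cfg)
  if (nrow(feats) != length(clip$labels))
    stop("clip ", clip$clip_id, ": ", nrow(feats), " feature rows vs ",
         length(clip$labels), " labels")
  list(subject_id = clip$subject_id, clip_id = clip$clip_id,
       features = feats, labels = clip$labels, metadata = clip$metadata)
}

#' Denoise and featurize a whole study
#'
#' @param study A `motion_study`.
#' @param denoise_cfg A [denoise_config].
#' @param feature_cfg A [feature_config].
#' @param verbose Print per-clip progress.
#' @return A [motion_dataset] ready for [loocv()].
#' @export
extract_study_features <- function(study, denoise_cfg = denoise_config(),
                                   feature_cfg = feature_config(),
                                   verbose = FALSE) {
  out <- lapply(study, function(cl) {
    if (verbose) message("featurizing ", cl$clip_id)
    extract_clip_features(cl, denoise_cfg, feature_cfg)
  })
  motion_dataset(out)
}
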