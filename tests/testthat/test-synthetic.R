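test_that("scene_config enforces its geometric invariants", {
  expect_error(scene_config(body_depth_mm = 960), "closer")
  expect_error(scene_config(events = list(amplitude_mm_range = c(10, 200))),
               "150")
  expect_error(generate_clip(
    scene_config(frame_shape = c(16, 16), body_axes_px = c(3, 3),
                 duration_s = 3,
                 events = list(region_px_range = c(400, 500),
                               rate_per_min = 240))),
    "larger than body")
})

test_that("an event-free scene is labelled all quiet", {
  scn <- small_scene(duration_s = 10)
  scn$events$rate_per_min <- 0
  clip <- generate_clip(scn)
  expect_equal(sum(clip$labels), 0)
  expect_length(clip$labels, 9)
})

test_that("a noise-free static scene renders identical frames", {
  scn <- small_scene(duration_s = 4)
  scn$events$rate_per_min <- 0
  scn$respiration$amplitude_mm <- 0
  scn$noise <- list(sigma_mm = 0, sigma_mm_far = 0, dropout_prob = 0,
                    outlier_prob = 0, outlier_mm = 0)
  clip <- generate_clip(scn)
  for (k in 2:length(clip$frames))
    expect_identical(clip$frames[[k]]$depths, clip$frames[[1]]$depths)
})

test_that("generated depths respect the frame invariants", {
  clip <- generate_clip(small_scene(duration_s = 6, seed = 8))
  for (f in clip$frames[c(1, 60, 120)]) {
    expect_true(all(f$depths >= 0))
    expect_true(all(is.finite(f$depths)))
  }
  # dropouts are encoded as zeros and therefore invalid
  scn <- small_scene(duration_s = 4, seed = 9)
  scn$noise$dropout_prob <- 0.2
  f <- generate_clip(scn)$frames[[5]]
  expect_gt(sum(f$depths == 0), 0)
  expect_false(any(depth_valid_mask(f) & f$depths == 0))
})

test_that("rendering is deterministic and order-independent", {
  scn <- small_scene(duration_s = 6, seed = 12)
  a <- generate_clip(scn)
  b <- generate_clip(scn)
  for (k in c(1, 31, 90))
    expect_identical(a$frames[[k]]$depths, b$frames[[k]]$depths)
  expect_identical(a$labels, b$labels)
  # lazy sources render arbitrary subsets bit-identically
  src <- generate_clip_source(scn)
  sub <- src$source$get(c(90, 1, 31))
  expect_identical(sub[[1]]$depths, a$frames[[90]]$depths)
  expect_identical(sub[[2]]$depths, a$frames[[1]]$depths)
})

test_that("label prevalence matches the renewal-process expectation", {
  # a second is labelled when an event covers a majority of the sampled
  # frames of one of its two spans: a start window of length 1.7 + d per
  # event; with Poisson arrivals (rate r/min) and durations U(d0, d1) the
  # chance a second is quiet is exp(-r/60 * (1.7 + mean duration))
  scn <- scene_config(frame_shape = c(16, 16), body_axes_px = c(5, 5),
                      duration_s = 600,
                      events = list(region_px_range = c(5, 10)),
                      seed = 21)
  p_busy <- 1 - exp(-4 / 60 * (1.7 + 3))
  prev <- numeric(6)
  for (s in 1:6) {
    scn$seed <- s
    prev[s] <- mean(make_scene(scn)$labels)
  }
  n <- 599 * 6
  se <- sqrt(p_busy * (1 - p_busy) / n)
  # renewal overlap induces correlation; allow 3 SD with a safety factor
  expect_lt(abs(mean(prev) - p_busy), 6 * se + 0.02)
})

test_that("studies are reproducible with the configured structure", {
  scn <- small_scene(duration_s = 4)
  s1 <- generate_study(4, 2, cfg = scn, seed = 31)
  s2 <- generate_study(4, 2, cfg = scn, seed = 31)
  expect_length(s1, 8)
  expect_equal(length(unique(vapply(s1, `[[`, character(1), "subject_id"))), 4)
  for (k in seq_along(s1)) {
    expect_identical(s1[[k]]$labels, s2[[k]]$labels)
    expect_identical(s1[[k]]$metadata, s2[[k]]$metadata)
    d <- s1[[k]]$metadata$distance_mm
    expect_true(d >= 230 && d <= 800)
  }
  # uneven clip counts: the 17x6 + 3 + 5 + 5 protocol gives 115 clips
  s3 <- generate_study(20, c(rep(6, 17), 3, 5, 5), cfg = scn, seed = 32)
  expect_length(s3, 115)
})

test_that("stronger events never hurt detectability in expectation", {
  aucs <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    for (a in 1:2) {
      amp <- list(c(6, 12), c(60, 110))[[a]]
      scfg <- scene_config(frame_shape = c(64, 80), duration_s = 40,
                           events = list(region_px_range = c(60, 140),
                                         amplitude_mm_range = amp),
                           seed = 40 + s)
      study <- generate_study(3, 1, cfg = scfg,
                              distance_range = c(350, 550), seed = 40 + s)
      ds <- extract_study_features(study)
      rep_ <- suppressWarnings(loocv(ds, forest_config(n_trees = 40,
                                                       seed = s)))
      aucs[s, a] <- rep_$summary$mean[rep_$summary$metric == "auc"]
    }
  }
  expect_gte(mean(aucs[, 2]), mean(aucs[, 1]) - 0.02)
})
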