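cfg <- denoise_config()

test_that("denoise_config validates its parameters", {
  expect_error(denoise_config(lower_pct = 90, upper_pct = 87), "lower_pct")
  expect_error(denoise_config(median_kernels = c(4, 3)), "odd")
  expect_error(denoise_config(max_diff_mm = -1), "max_diff_mm")
  expect_error(denoise_config(connectivity = 6), "connectivity")
})

test_that("temporal median of identical frames reproduces the frame", {
  arr <- array(rep(matrix(300 + 1:16, 4, 4), 20), dim = c(4, 4, 20))
  frames <- frames_from_array(arr, fps = 10, valid_range = c(1, 1e5))
  avg <- temporal_median(frames, denoise_config(frames_per_median = 10))
  expect_length(avg, 2)
  expect_equal(avg[[1]]$depths, arr[, , 1])
  expect_equal(avg[[2]]$depths, arr[, , 1])
})

test_that("temporal median rejects a single outlier frame", {
  arr <- array(500, dim = c(3, 3, 20))
  arr[2, 2, 7] <- 9000   # one wild sample in the first span
  frames <- frames_from_array(arr, fps = 10, valid_range = c(1, 1e5))
  avg <- temporal_median(frames, denoise_config(frames_per_median = 10))
  expect_equal(avg[[1]]$depths[2, 2], 500)
})

test_that("boundary medians equal the brute-force oracle on random stacks", {
  set.seed(101)
  for (rep in 1:25) {
    arr <- array(runif(4 * 4 * 20, 100, 900), dim = c(4, 4, 20))
    arr[sample(length(arr), 50)] <- 0          # invalid dropouts
    frames <- frames_from_array(arr, fps = 10, valid_range = c(50, 1000))
    avg <- temporal_median(frames, denoise_config(frames_per_median = 10,
                                                  span_s = 1))
    # at 10 fps each 1-s span contributes exactly its own 10 frames
    for (case in list(list(avg[[1]], 1:10), list(avg[[2]], 11:20))) {
      mats <- lapply(case[[2]], function(k) arr[, , k])
      valids <- lapply(frames[case[[2]]], depth_valid_mask)
      expect_identical(case[[1]]$depths, oracle_temporal_median(mats, valids))
    }
  }
})

test_that("majority-invalid pixels come out invalid from the span median", {
  arr <- array(500, dim = c(2, 2, 20))
  arr[1, 1, 1:6] <- 0    # invalid in 6 of the 10 contributing frames
  arr[2, 2, 1:5] <- 0    # invalid in exactly half: still defined
  frames <- frames_from_array(arr, fps = 10, valid_range = c(50, 1000))
  avg <- temporal_median(frames, denoise_config(frames_per_median = 10))[[1]]
  expect_equal(avg$depths[1, 1], 0)
  expect_equal(avg$depths[2, 2], 500)
})

test_that("clips shorter than two spans are rejected", {
  arr <- array(500, dim = c(2, 2, 12))
  frames <- frames_from_array(arr, fps = 10)
  expect_error(temporal_median(frames, denoise_config(frames_per_median = 10)),
               "2 spans")
})

test_that("percentile clipping keeps a constant frame intact", {
  f <- depth_frame(matrix(500, 5, 5))
  out <- clip_depth_percentiles(f, cfg)
  expect_equal(out$depths, f$depths)
  expect_true(all(depth_valid_mask(out)))
})

test_that("percentile clipping matches the order-statistic oracle", {
  set.seed(7)
  for (rep in 1:60) {
    f <- random_depth_frame(10, 10)
    out <- clip_depth_percentiles(f, cfg)
    want <- oracle_clip(f$depths, depth_valid_mask(f), 3, 87, c(200, 1000))
    expect_identical(depth_valid_mask(out), want)
    # surviving values unchanged
    expect_equal(out$depths[want], f$depths[want])
  }
})

test_that("a frame with no in-range pixels is flagged fully invalid", {
  f <- depth_frame(matrix(c(0, 50, 1500, 1800), 2, 2))
  out <- clip_depth_percentiles(f, cfg)
  expect_true(attr(out, "all_invalid"))
  expect_false(any(depth_valid_mask(out)))
})

test_that("depth differencing subtracts where both frames are valid", {
  prev <- depth_frame(matrix(c(500, 500, 0, 500), 2, 2))
  curr <- depth_frame(matrix(c(530, 500, 400, 0), 2, 2))
  d <- depth_difference(prev, curr, second_index = 3L)
  expect_equal(d$diffs[1, 1], 30)           # +30 mm toward background
  expect_equal(d$diffs[2, 1], 0)
  expect_false(d$valid[1, 2])               # invalid in prev only
  expect_false(d$valid[2, 2])               # invalid in curr only
  expect_equal(d$second_index, 3L)
  expect_error(depth_difference(prev, depth_frame(matrix(500, 3, 2))),
               "mismatch")
  # identical frames give an all-zero difference
  z <- depth_difference(prev, prev)
  expect_true(all(z$diffs == 0))
})

test_that("spatial median filtering is exact against the windowed oracle", {
  set.seed(11)
  for (k in c(3, 5)) {
    for (rep in 1:30) {
      d <- random_diff_frame(9, 9)
      got <- spatial_median_filter(d, denoise_config(median_kernels = k))
      want <- oracle_median_filter(d$diffs, d$valid, k)
      expect_identical(got$diffs, want)
      expect_identical(got$valid, d$valid)
    }
  }
})

test_that("spatial median suppresses isolated spikes, keeps constants", {
  z <- matrix(0, 9, 9)
  z[5, 5] <- 100
  d <- depth_diff_frame(z, matrix(TRUE, 9, 9))
  out <- spatial_median_filter(d, denoise_config(median_kernels = 5))
  expect_true(all(out$diffs == 0))
  cst <- depth_diff_frame(matrix(7, 6, 6), matrix(TRUE, 6, 6))
  expect_equal(spatial_median_filter(cst, cfg)$diffs, cst$diffs)
})

test_that("large-difference removal drops |diff| > 150 mm, both signs", {
  d <- depth_diff_frame(matrix(c(-10, 120, 160, -200), 2, 2),
                        matrix(TRUE, 2, 2))
  out <- remove_large_differences(d, cfg)
  expect_equal(as.vector(out$valid), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$diffs[1, 1], -10)
  expect_equal(out$diffs[2, 1], 120)
  # idempotent; exact matches against a direct scan on random frames
  set.seed(3)
  for (rep in 1:40) {
    r <- random_diff_frame(8, 8, diff_sd = 120)
    once <- remove_large_differences(r, cfg)
    expect_identical(once$valid, r$valid & abs(r$diffs) <= 150)
    expect_identical(remove_large_differences(once, cfg), once)
  }
})

test_that("small-region removal enforces the 40-pixel area boundary", {
  m <- matrix(0, 20, 20)
  m[2:5, 2:11] <- 5          # 40-pixel blob: retained
  m[10:12, 2:14] <- 5        # 39-pixel blob: removed
  stopifnot(sum(m[10:12, 2:14] != 0) == 39)
  d <- depth_diff_frame(m, matrix(TRUE, 20, 20))
  out <- remove_small_regions(d, cfg)
  expect_true(all(out$valid[2:5, 2:11]))
  expect_true(all(!out$valid[10:12, 2:14]))
  # empty frames pass through untouched
  e <- depth_diff_frame(matrix(0, 4, 4), matrix(TRUE, 4, 4))
  expect_identical(remove_small_regions(e, cfg), e)
})

test_that("small-region removal agrees with a flood-fill oracle", {
  set.seed(13)
  for (connectivity in c(4, 8)) {
    ccfg <- denoise_config(min_region_px = 6, connectivity = connectivity)
    for (rep in 1:30) {
      d <- random_diff_frame(12, 12, p_valid = 0.9)
      active <- d$valid & d$diffs != 0
      lab <- oracle_components(active, connectivity)
      keep_lab <- which(tabulate(lab[lab > 0]) >= 6)
      want_valid <- d$valid & !(lab > 0 & !(lab %in% keep_lab))
      out <- remove_small_regions(d, ccfg)
      expect_identical(out$valid, want_valid)
      expect_identical(remove_small_regions(out, ccfg), out)
    }
  }
})

test_that("cascade stages never increase the count of valid pixels", {
  set.seed(17)
  for (rep in 1:20) {
    d <- random_diff_frame(12, 12, diff_sd = 100)
    n0 <- sum(d$valid)
    a <- spatial_median_filter(d, cfg);          n1 <- sum(a$valid)
    b <- remove_large_differences(a, cfg);       n2 <- sum(b$valid)
    c_ <- remove_small_regions(b, cfg);          n3 <- sum(c_$valid)
    expect_true(n0 >= n1 && n1 >= n2 && n2 >= n3)
  }
})

test_that("preprocess_clip yields n_spans - 1 differences in stage order", {
  # a 300-s clip at 30 fps -> 299 difference frames (tiny raster for speed)
  set.seed(23)
  scn <- scene_config(frame_shape = c(8, 8), fps = 30, duration_s = 300,
                      body_axes_px = c(3, 3),
                      events = list(rate_per_min = 0),
                      noise = list(sigma_mm = 0, dropout_prob = 0,
                                   outlier_prob = 0),
                      respiration = list(amplitude_mm = 0))
  clip <- generate_clip_source(scn)
  pp <- preprocess_clip(clip$source, cfg)
  expect_length(pp$diffs, 299)
  expect_length(pp$depths, 300)
  expect_equal(vapply(pp$diffs, `[[`, integer(1), "second_index"), 0:298)
  # static noise-free scene: no valid nonzero pixel anywhere
  expect_true(all(vapply(pp$diffs, function(d)
    sum(d$valid & d$diffs != 0), numeric(1)) == 0))
})

test_that("a moving 60-mm, 200-px patch survives all five stages", {
  H <- 40; W <- 40
  base <- matrix(600, H, W)
  patch <- base
  patch[11:20, 11:30] <- 540   # 10x20 patch lifted by 60 mm
  # the patch appears late in span 0, so span 1's median reflects the
  # lifted state while span 0's still reflects rest
  frames <- lapply(1:20, function(k)
    depth_frame(if (k >= 9) patch else base, timestamp = (k - 1) / 10))
  pp <- preprocess_clip(frames, denoise_config(frames_per_median = 10))
  d <- pp$diffs[[1]]
  expect_gte(sum(d$valid & abs(d$diffs) >= 59), 160)
})
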