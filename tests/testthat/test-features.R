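fcfg <- feature_config()

make_pair <- function(depths, diffs, valid = NULL,
                      valid_range = c(1, 1e9)) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(diffs), ncol(diffs))
  list(diff = depth_diff_frame(diffs, valid),
       depth = depth_frame(depths, valid_range = valid_range))
}

test_that("feature_config validates threshold lists", {
  expect_error(feature_config(area_thresholds_mm = c(1, 2, 3, 4)), "5")
  expect_error(feature_config(sum_thresholds_mm = c(1, 1, 2, 3)), "ascending")
})

test_that("spatial-scale features count graded moving area", {
  # 100 valid pixels, 20 of them moving by 10 mm, at the reference depth
  diffs <- matrix(0, 10, 10)
  diffs[1:20] <- 10
  p <- make_pair(matrix(500, 10, 10), diffs)
  expect_equal(spatial_scale_features(p$diff, p$depth, fcfg),
               c(0.2, 0.2, 0.2, 0, 0))
  # all-zero differences give the zero vector
  z <- make_pair(matrix(500, 10, 10), matrix(0, 10, 10))
  expect_equal(spatial_scale_features(z$diff, z$depth, fcfg), rep(0, 5))
})

test_that("spatial-scale features scale quadratically with depth", {
  set.seed(31)
  for (rep in 1:20) {
    diffs <- matrix(rnorm(100, 0, 10), 10, 10)
    depths <- matrix(runif(100, 250, 400), 10, 10)
    p1 <- make_pair(depths, diffs)
    base <- spatial_scale_features(p1$diff, p1$depth, fcfg)
    for (c_ in c(0.5, 2, 3.7)) {
      p2 <- make_pair(depths * c_, diffs)
      expect_equal(spatial_scale_features(p2$diff, p2$depth, fcfg),
                   base * c_^2, tolerance = 1e-9)
    }
  }
})

test_that("summed-difference features gate on graded thresholds", {
  diffs <- matrix(0, 2, 5)
  diffs[1:2] <- c(50, -50)
  p <- make_pair(matrix(500, 2, 5), diffs)
  expect_equal(summed_diff_features(p$diff, fcfg), rep(10, 4))
  # adding a 3-mm pixel only moves the lowest-threshold feature
  diffs[3] <- 3
  p2 <- make_pair(matrix(500, 2, 5), diffs)
  got <- summed_diff_features(p2$diff, fcfg)
  expect_equal(got, c(10.3, 10, 10, 10))
  # empty frame
  e <- depth_diff_frame(matrix(0, 2, 2), matrix(FALSE, 2, 2))
  expect_equal(summed_diff_features(e, fcfg), rep(0, 4))
})

test_that("average-depth features are order-statistic summaries", {
  f <- depth_frame(matrix(500, 3, 3))
  expect_equal(average_depth_features(f), rep(500, 4))
  v <- matrix(as.numeric(1:100), 10, 10)
  f2 <- depth_frame(v, valid_range = c(0.5, 1e9))
  x <- as.vector(v)
  expect_equal(average_depth_features(f2),
               c(mean(x), oracle_percentile(x, 0.5),
                 oracle_percentile(x, 0.25), oracle_percentile(x, 0.75)))
  # fully invalid frame: sentinel zeros plus a warning
  dead <- depth_frame(matrix(0, 3, 3))
  expect_warning(got <- average_depth_features(dead), "no valid")
  expect_equal(got, rep(0, 4))
})

test_that("skew features behave distributionally", {
  cst <- depth_frame(matrix(640, 5, 5))
  expect_equal(skew_features(cst), c(0, 0, 640))
  set.seed(37)
  gauss <- depth_frame(matrix(500 + rnorm(10000), 100, 100),
                       valid_range = c(1, 1e9))
  kg <- skew_features(gauss)[2]
  expect_lt(abs(kg), 0.15)          # excess kurtosis ~ 0 for Gaussian
  heavy <- depth_frame(matrix(500 + 3 * rt(10000, df = 5), 100, 100),
                       valid_range = c(1, 1e9))
  expect_gt(skew_features(heavy)[2], 0.5)   # heavy tails: positive
  # fewer than 4 valid pixels: kurtosis defined as 0
  tiny <- depth_frame(matrix(c(400, 500, 600, 0), 2, 2))
  expect_equal(skew_features(tiny)[2], 0)
})

test_that("graded features are monotone and finite on random frames", {
  set.seed(41)
  for (rep in 1:120) {
    d <- random_diff_frame(8, 8, p_valid = runif(1, 0, 1))
    f <- random_depth_frame(8, 8, p_dropout = runif(1, 0, 1))
    ss <- spatial_scale_features(d, f, fcfg)
    sm <- summed_diff_features(d, fcfg)
    expect_true(all(diff(ss) <= 1e-12))
    expect_true(all(diff(sm) <= 1e-12))
    all16 <- c(ss, sm, suppressWarnings(average_depth_features(f)),
               skew_features(f))
    expect_length(all16, 16)
    expect_true(all(is.finite(all16)))
  }
})

test_that("extract_features aligns seconds and flags motion fixtures", {
  # constructed clip: 25 spans, one drifting patch active t = 11.2-13.8 s
  H <- 24; W <- 24
  fps <- 10
  frames <- lapply(1:250, function(fr) {
    d <- matrix(600, H, W)
    if (fr >= 113 && fr <= 138) d[6:15, 6:15] <- 540 - 0.5 * (fr - 113)
    depth_frame(d, timestamp = (fr - 1) / fps)
  })
  pp <- preprocess_clip(frames, denoise_config(frames_per_median = 10))
  feats <- extract_features(pp$diffs, pp$depths)
  expect_equal(nrow(feats), 24)
  expect_identical(names(feats), c("second_index", feature_names()))
  # the patch registers from the second comparing spans 10 and 11
  moving <- feats$spatial_scale_1[feats$second_index %in% 10:13]
  still <- feats$spatial_scale_1[!feats$second_index %in% 10:13]
  expect_true(min(moving) > max(still))
  expect_true(all(still == 0))
  # length mismatch is rejected
  expect_error(extract_features(pp$diffs, pp$depths[1:10]), "mismatch")
})
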