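test_that("intensity, contrast and pixel change match brute force", {
  v <- tiny_video(6, 7, 4, seed = 2)
  # intensity
  ints <- as.numeric(pixel_intensity(v))
  expect_equal(ints, vapply(1:4, function(t) mean(v[, , , t]), numeric(1)),
               tolerance = 1e-10)
  cv <- video_tensor(array(0.3, c(4, 4, 3, 3)))
  expect_equal(as.numeric(pixel_intensity(cv)), rep(0.3, 3))
  # contrast: constant video is 0; half-black/half-white frame is 0.5
  expect_equal(as.numeric(contrast(cv)), rep(0, 3))
  half <- array(0, c(4, 4, 3, 2))
  half[, 3:4, , ] <- 1
  expect_equal(as.numeric(contrast(video_tensor(half))), rep(0.5, 2))
  # contrast depends only on the grayscale image
  g <- to_grayscale(get_frame(v, 1))[, , 1]
  expect_equal(as.numeric(contrast(v))[1], stst:::pop_sd(g), tolerance = 1e-10)
  # pixel change
  pc <- as.numeric(pixel_change(v))
  expect_equal(pc[2], mean(abs(get_frame(v, 3) - get_frame(v, 2))),
               tolerance = 1e-10)
  expect_equal(as.numeric(pixel_change(cv)), rep(0, 2))
  alt <- video_tensor(array(rep(c(0, 1), each = 4 * 4 * 3), c(4, 4, 3, 2)))
  expect_equal(as.numeric(pixel_change(alt)), 1)
})

test_that("optical flow recovers known translation and is deterministic", {
  # static video: negligible flow
  vs <- translating_texture(32, 32, 3, speed = 0, seed = 5)
  expect_lt(max(as.numeric(optical_flow_stats(vs)$magnitude)), 0.05)
  # downward translation at 2 px/frame: arithmetic mean angle is safe here
  vd <- translating_texture(48, 48, 4, speed = 2, direction = pi / 2, seed = 4)
  fl <- optical_flow_stats(vd)
  expect_true(all(abs(as.numeric(fl$magnitude) - 2) < 0.5))
  expect_true(all(abs(as.numeric(fl$angle) - pi / 2) < 0.3))
  # rightward motion straddles the 0/2pi wrap: circular mean handles it
  vr <- translating_texture(48, 48, 3, speed = 2, direction = 0, seed = 3)
  flr <- optical_flow_stats(vr, circular_mean = TRUE)
  expect_true(all(ang_diff(as.numeric(flr$angle), 0) < 0.3))
  # determinism
  f1 <- optical_flow_stats(vd)
  expect_identical(as.numeric(f1$magnitude), as.numeric(fl$magnitude))
})

test_that("optical flow recovers drifting-grating motion (aperture case)", {
  # a 1-D grating is the degenerate aperture-problem input: the estimator
  # falls back to normal flow, which equals the true velocity here
  vg <- drifting_grating(48, 48, 4, spatial_freq = 4, direction = 0,
                         speed = 2)
  fl <- optical_flow_stats(vg, circular_mean = TRUE)
  expect_true(all(abs(as.numeric(fl$magnitude) - 2) / 2 < 0.25))
  expect_true(all(ang_diff(as.numeric(fl$angle), 0) < 0.3))
})

test_that("series similarity implements Pearson and Euclidean exactly", {
  a <- c(0.2, 0.5, 0.9, 0.4)
  s <- series_similarity(a, a)
  expect_equal(s$pcc, 1)
  expect_equal(s$ed, 0)
  b <- -(a - mean(a))
  expect_equal(series_similarity(a - mean(a), b)$pcc, -1)
  x <- withr::with_seed(1, rnorm(10))
  y <- withr::with_seed(2, rnorm(10))
  s2 <- series_similarity(x, y)
  expect_equal(s2$pcc,
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-10)
  expect_equal(s2$ed, sqrt(sum((x - y)^2)), tolerance = 1e-10)
  expect_warning(sz <- series_similarity(rep(1, 5), x[1:5]), "zero-variance")
  expect_true(is.na(sz$pcc))
  expect_error(series_similarity(1:3, 1:4), "length mismatch")
})

test_that("color KL divergence is a smoothed histogram divergence", {
  v <- tiny_video(8, 8, 2, seed = 6)
  expect_equal(color_distribution_distance(v, v), 0)
  w <- tiny_video(8, 8, 2, seed = 7)
  expect_gte(color_distribution_distance(v, w), 0)
  # closed form for two constant videos in distinct bins
  bins <- 16L
  ca <- video_tensor(array(0.05, c(4, 4, 3, 2)))  # bin (0,0,0)
  cb <- video_tensor(array(0.95, c(4, 4, 3, 2)))  # bin (15,15,15)
  N <- 4 * 4 * 2
  eps <- 1e-9
  tot <- N + bins^3 * eps
  p_hot <- (N + eps) / tot
  p_cold <- eps / tot
  expected <- p_hot * log(p_hot / p_cold) + p_cold * log(p_cold / p_hot)
  expect_equal(color_distribution_distance(ca, cb, bins), expected,
               tolerance = 1e-6)
})

test_that("palette recovery via k-means on pooled pixels", {
  one <- colored_blobs(8, 8, 2, palette = rbind(c(0.3, 0.6, 0.9)))
  p1 <- video_palette(one, k = 1, seed = 1)
  expect_equal(unname(p1[1, ]), c(0.3, 0.6, 0.9))
  # fewer distinct colors than k: centroids duplicated, not an error
  p3 <- video_palette(one, k = 3, seed = 1)
  expect_equal(nrow(p3), 3L)
  expect_true(all(apply(p3, 1, function(r) all(r == c(0.3, 0.6, 0.9)))))
  two <- colored_blobs(12, 12, 2, palette = rbind(c(0.9, 0.1, 0.1),
                                                  c(0.1, 0.2, 0.9)))
  # add slight jitter so k-means sees a cloud per blob
  jit <- withr::with_seed(3, array(runif(length(two), -0.02, 0.02), dim(two)))
  vj <- video_tensor(stst:::clamp01(unclass(two) + jit))
  p2 <- video_palette(vj, k = 2, seed = 2)
  d <- as.matrix(dist(rbind(p2, c(0.9, 0.1, 0.1), c(0.1, 0.2, 0.9))))
  expect_lt(min(d[1, 3:4]), 0.05)
  expect_lt(min(d[2, 3:4]), 0.05)
  expect_identical(video_palette(vj, k = 2, seed = 2), p2)
})

test_that("video_features returns the tidy frame/feature/value table", {
  v <- translating_texture(24, 24, 3, speed = 1, seed = 9)
  df <- video_features(v)
  expect_setequal(unique(df$feature),
                  c("intensity", "contrast", "pixel_change",
                    "flow_magnitude", "flow_angle"))
  expect_equal(sum(df$feature == "intensity"), 3L)
  expect_equal(sum(df$feature == "flow_angle"), 2L)
})
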