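test_that("mirror padding flips and prepends the first frames", {
  v <- tiny_video(4, 4, 3, seed = 1)
  p <- mirror_pad(v, 2)
  expect_equal(n_frames(p), 5L)
  expect_equal(get_frame(p, 1), get_frame(v, 2))
  expect_equal(get_frame(p, 2), get_frame(v, 1))
  expect_equal(get_frame(p, 3), get_frame(v, 1))
  expect_equal(get_frame(p, 5), get_frame(v, 3))
  expect_equal(unclass(mirror_pad(v, 0)), unclass(v))
  expect_error(mirror_pad(v, 4), "exceed")
})

test_that("blended initialization mixes the previous frame with noise", {
  g <- array(1, c(64, 64, 3))
  expect_equal(blend_init(g, 1, seed = 1), g)
  b <- blend_init(g, 0.9, seed = 2)
  expect_lt(abs(mean(b) - 0.95), 0.01)
  expect_identical(blend_init(g, 0.5, seed = 3), blend_init(g, 0.5, seed = 3))
  # no predecessor: pure noise with the requested shape
  n <- blend_init(NULL, 0.95, dim = c(5, 6, 3), seed = 4)
  expect_equal(dim(n), c(5, 6, 3))
  expect_true(all(n >= 0 & n <= 1))
})

test_that("gradient normalization divides channels by their spatial sd", {
  g <- withr::with_seed(1, array(rnorm(8 * 8 * 3, sd = c(0.5, 2, 7)),
                                 c(8, 8, 3)))
  n <- normalize_gradient(g, eps = 1e-8)
  for (c in 1:3) {
    s <- stst:::pop_sd(g[, , c])
    expect_equal(n[, , c], g[, , c] / (s + 1e-8), tolerance = 1e-12)
    expect_equal(stst:::pop_sd(n[, , c]), 1, tolerance = 1e-6)
  }
  z <- normalize_gradient(array(0, c(4, 4, 3)))
  expect_equal(z, array(0, c(4, 4, 3)))
})

test_that("zero-iteration schedules return the initialization unchanged", {
  mods <- fixture_models()
  cfg <- synthesis_config(
    loss = fixture_loss_spec(beta = 1, lambda = 0, omega = 0),
    schedule = octave_schedule(octaves = 0L, sigma = 1.5,
                               iterations = 0L, eta = 0.01),
    color_transfer = FALSE, xi = 0L, seed = 1
  )
  g0 <- random_frame(10, 10, seed = 5)
  tgt <- list(spatial_texture = list(current = random_frame(10, 10, seed = 6),
                                     previous = NULL))
  out <- optimize_frame(tgt, g0, NULL, cfg, mods)
  expect_equal(out, g0, ignore_attr = TRUE)
})

test_that("texture optimization monotonically reduces the spatial loss", {
  mods <- fixture_models()
  layers <- c("conv1", "conv2", "conv3")
  x <- get_frame(translating_texture(8, 8, 2, seed = 3), 1)
  cfg <- synthesis_config(
    loss = fixture_loss_spec(beta = 1, lambda = 0, omega = 0),
    schedule = octave_schedule(octaves = 0L, sigma = 1.5,
                               iterations = 100L, eta = 0.02),
    color_transfer = FALSE, xi = 0L, seed = 2
  )
  g0 <- blend_init(NULL, 0, dim = c(8, 8, 3), seed = 7)
  out <- optimize_frame(list(spatial_texture = list(current = x,
                                                    previous = NULL)),
                        g0, NULL, cfg, mods)
  tr <- attr(out, "trace")
  expect_lte(tr$loss[nrow(tr)], 0.5 * tr$loss[1])
  expect_true(all(out >= 0 & out <= 1))
})

test_that("the full loop returns T frames, in range, and deterministic", {
  mods <- fixture_models()
  v <- translating_texture(12, 12, 4, speed = 1, seed = 2)
  cfg <- synthesis_config(
    loss = fixture_loss_spec(beta = 1, lambda = 1, omega = 0.05),
    schedule = octave_schedule(octaves = 0L, sigma = 1.5,
                               iterations = 30L, eta = 0.015),
    phi = 0.95, xi = 1L, seed = 5, color_transfer = FALSE
  )
  out1 <- synthesize_video(v, cfg, mods)
  out2 <- synthesize_video(v, cfg, mods)
  expect_equal(n_frames(out1), 4L)
  expect_identical(dim(out1), dim(v))
  expect_true(all(out1 >= 0 & out1 <= 1))
  expect_identical(unclass(out1), unclass(out2))
  tr <- attr(out1, "loss_trace")
  expect_true(all(c("frame", "octave", "iter", "loss") %in% names(tr)))
  # per-frame loss decreases (non-strict)
  for (f in unique(tr$frame)) {
    l <- tr$loss[tr$frame == f]
    expect_lte(l[length(l)], l[1])
  }
})

test_that("factorization mode accepts distinct spatial and temporal targets", {
  mods <- fixture_models()
  vs <- colored_blobs(12, 12, 4, palette = rbind(c(0.9, 0.1, 0.1),
                                                 c(0.1, 0.1, 0.9)))
  vt <- translating_texture(12, 12, 4, speed = 1, seed = 4)
  spec <- loss_spec(beta = 1, lambda = 1, omega = 0.05,
                    spatial_layers = c("conv1", "conv2", "conv3"),
                    routing = c(spatial_content = "space",
                                spatial_texture = "space",
                                temporal_content = "time",
                                temporal_texture = "time"))
  cfg <- synthesis_config(
    loss = spec,
    schedule = octave_schedule(octaves = 0L, sigma = 1.5,
                               iterations = 20L, eta = 0.03),
    phi = 0.95, xi = 1L, seed = 6, color_transfer = TRUE,
    color_iterations = 5L
  )
  out <- synthesize_video(list(space = vs, time = vt), cfg, mods)
  expect_equal(n_frames(out), 4L)
  expect_true(all(out >= 0 & out <= 1))
  # mismatched shapes are rejected
  bad <- translating_texture(10, 12, 4, speed = 1, seed = 4)
  expect_error(synthesize_video(list(space = vs, time = bad), cfg, mods),
               "share length and shape")
})

test_that("multi-octave schedules resize through the octave geometry", {
  mods <- fixture_models()
  v <- translating_texture(18, 18, 2, speed = 1, seed = 9)
  cfg <- synthesis_config(
    loss = fixture_loss_spec(beta = 1, lambda = 0, omega = c(0.05, 0.1)),
    schedule = octave_schedule(octaves = c(-1L, 0L), sigma = 1.5,
                               iterations = c(10L, 10L), eta = c(0.02, 0.02)),
    phi = 0.9, xi = 0L, seed = 3, color_transfer = FALSE
  )
  out <- synthesize_video(v, cfg, mods)
  tr <- attr(out, "loss_trace")
  expect_setequal(unique(tr$octave), c(-1L, 0L))
  expect_identical(dim(out), dim(v))
})
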