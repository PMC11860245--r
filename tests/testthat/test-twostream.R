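test_that("fixture models are seed-reproducible and validate layer names", {
  m1 <- make_fixture_model(0, 1)
  m2 <- make_fixture_model(0, 1)
  m3 <- make_fixture_model(99, 1)
  x <- random_frame(8, 8, seed = 4)
  a1 <- spatial_forward(m1, x, "conv2")$conv2
  a2 <- spatial_forward(m2, x, "conv2")$conv2
  a3 <- spatial_forward(m3, x, "conv2")$conv2
  expect_identical(a1, a2)
  expect_gt(max(abs(a1 - a3)), 1e-6)
  expect_error(spatial_forward(m1, x, "nope"), "unknown layer")
  expect_error(spatial_forward(make_msoe_model(), x, "concat"), "arity-1")
  # repeated calls are bitwise equal, including on constant input
  z <- array(0, c(8, 8, 3))
  expect_identical(spatial_forward(m1, z, "conv1"),
                   spatial_forward(m1, z, "conv1"))
})

test_that("activation matrices are filters x locations with map dims", {
  m <- make_fixture_model(0, 1)
  a <- spatial_forward(m, random_frame(6, 9, seed = 1), "conv2")$conv2
  expect_equal(nrow(a), 6L) # conv2 has 6 filters
  expect_equal(ncol(a), 6L * 9L)
  expect_equal(attr(a, "map_dims"), c(6L, 9L))
})

test_that("temporal forward checks shapes and arity", {
  mt <- make_fixture_model(1, 2)
  x <- random_frame(8, 8, seed = 2)
  expect_error(temporal_forward(mt, x, random_frame(8, 9, seed = 3), "conv1"),
               "shape mismatch")
  expect_error(temporal_forward(make_fixture_model(0, 1), x, x, "conv1"),
               "arity-2")
  a <- temporal_forward(mt, x, x, "conv3")$conv3
  expect_true(all(is.finite(a)))
})

test_that("analytic gradients match central finite differences", {
  # spatial fixture net through a texture loss
  m <- make_fixture_model(0, 1)
  layers <- c("conv1", "conv3")
  x <- random_frame(8, 8, seed = 11)
  tacts <- spatial_forward(m, random_frame(8, 8, seed = 12), layers)
  Gt <- lapply(tacts, gram)
  lossfun <- function(xx) {
    a <- spatial_forward(m, xx, layers)
    sum(mapply(function(G, A) sum((G - gram(A))^2) / (2 * nrow(A)^2), Gt, a))
  }
  fw <- m$forward(x, NULL, layers, want_grad = TRUE)
  tg <- lapply(layers, function(ly) stst:::texture_loss_grad(Gt[[ly]],
                                                             fw$acts[[ly]]))
  names(tg) <- layers
  ga <- fw$backward(tg)$gx
  h <- 1e-5
  probes <- withr::with_seed(5, cbind(sample(8, 6, TRUE), sample(8, 6, TRUE),
                                      sample(3, 6, TRUE)))
  for (r in seq_len(nrow(probes))) {
    i <- probes[r, 1]; j <- probes[r, 2]; c <- probes[r, 3]
    xp <- x; xp[i, j, c] <- x[i, j, c] + h
    xm <- x; xm[i, j, c] <- x[i, j, c] - h
    fd <- (lossfun(xp) - lossfun(xm)) / (2 * h)
    expect_equal(ga[i, j, c], fd, tolerance = 1e-3)
  }
})

test_that("MSOE gradients match finite differences on the frame pair", {
  mt <- make_msoe_model(msoe_params(scales = 2))
  x0 <- random_frame(12, 12, seed = 21)
  x1 <- random_frame(12, 12, seed = 22)
  ref <- temporal_forward(mt, random_frame(12, 12, seed = 23),
                          random_frame(12, 12, seed = 24), "concat")$concat
  Gt <- gram(ref)
  lossfun <- function(xx) {
    a <- temporal_forward(mt, xx, x0, "concat")$concat
    sum((Gt - gram(a))^2) / (2 * nrow(a)^2)
  }
  fw <- mt$forward(x1, x0, "concat", want_grad = TRUE)
  ga <- fw$backward(list(concat = stst:::texture_loss_grad(Gt,
                                                           fw$acts$concat)))$gx
  h <- 1e-5
  probes <- withr::with_seed(6, cbind(sample(12, 5, TRUE), sample(12, 5, TRUE),
                                      sample(3, 5, TRUE)))
  for (r in seq_len(nrow(probes))) {
    i <- probes[r, 1]; j <- probes[r, 2]; c <- probes[r, 3]
    xp <- x1; xp[i, j, c] <- x1[i, j, c] + h
    xm <- x1; xm[i, j, c] <- x1[i, j, c] - h
    fd <- (lossfun(xp) - lossfun(xm)) / (2 * h)
    expect_equal(ga[i, j, c], fd, tolerance = 1e-3)
  }
})

test_that("MSOE energies are non-negative and static input favors the
           static channel", {
  mt <- make_msoe_model(msoe_params(scales = 2))
  x <- get_frame(drifting_grating(24, 24, 2, spatial_freq = 5), 1)
  a <- temporal_forward(mt, x, x, "scale1")$scale1
  expect_true(all(a >= 0))
  ch_means <- rowMeans(a)
  # channels grouped per orientation as (+phi, -phi, static)
  grp <- matrix(ch_means, nrow = 3)
  for (o in seq_len(ncol(grp))) {
    expect_gte(grp[3, o], grp[1, o])
    expect_gte(grp[3, o], grp[2, o])
  }
})

test_that("MSOE prefers the veridical motion direction", {
  mt <- make_msoe_model(msoe_params(scales = 2))
  v <- drifting_grating(32, 32, 2, spatial_freq = 7, direction = 0, speed = 1)
  a <- temporal_forward(mt, get_frame(v, 2), get_frame(v, 1), "scale1")$scale1
  ch_means <- rowMeans(a)
  moving <- matrix(ch_means, nrow = 3)[1:2, ] # drop static channels
  # rightward channel = orientation 1 (theta = 0), positive phase
  expect_equal(which.max(c(moving)), 1L)
})

test_that("MSOE is invariant to a global luminance offset", {
  mt <- make_msoe_model(msoe_params(scales = 2))
  v <- translating_texture(24, 24, 2, speed = 1, seed = 8)
  x1 <- get_frame(v, 2) * 0.8
  x0 <- get_frame(v, 1) * 0.8
  a <- rowMeans(temporal_forward(mt, x1, x0, "concat")$concat)
  b <- rowMeans(temporal_forward(mt, x1 + 0.1, x0 + 0.1, "concat")$concat)
  expect_true(all(abs(b - a) / (abs(a) + 1e-12) < 0.05))
})

test_that("the VGG-19 architecture exposes the canonical texture layers", {
  m <- make_vgg19_model(seed = 0)
  expect_true(all(c("conv1_1", "conv2_1", "conv3_1", "conv4_1", "conv5_1")
                  %in% m$layer_names))
  a <- spatial_forward(m, random_frame(16, 16, seed = 1),
                       c("conv1_1", "conv2_1"))
  expect_equal(nrow(a$conv1_1), 64L)
  expect_equal(attr(a$conv2_1, "map_dims"), c(8L, 8L)) # after one pool
})
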