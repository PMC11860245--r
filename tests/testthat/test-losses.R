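test_that("content loss matches hand evaluation and scales quadratically", {
  A <- matrix(1)
  expect_equal(content_loss(A, A), 0)
  expect_equal(content_loss(matrix(1), matrix(3)), 2)
  X <- matrix(rnorm(12), 3, 4)
  Y <- matrix(rnorm(12), 3, 4)
  expect_equal(content_loss(3 * X, 3 * Y), 9 * content_loss(X, Y))
  expect_error(content_loss(X, t(Y)), "mismatch")
})

test_that("gram matches a brute-force double loop and is spatially invariant", {
  expect_equal(gram(matrix(0, 3, 5)), matrix(0, 3, 3))
  expect_equal(gram(matrix(c(1, 0, 1, 0), 2, 2)),
               matrix(c(0.5, 0, 0, 0), 2, 2))
  A <- withr::with_seed(7, matrix(rnorm(35), 5, 7))
  G <- gram(A)
  Gb <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    for (k in 1:7) Gb[i, j] <- Gb[i, j] + A[i, k] * A[j, k]
  }
  Gb <- Gb / (5 * 7)
  expect_equal(G, Gb, tolerance = 1e-10)
  expect_equal(gram(A[, sample(7)]), G)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12)) # PSD
})

test_that("texture loss is Gram-invariant and matches hand evaluation", {
  A <- withr::with_seed(1, matrix(rnorm(8), 2, 4))
  expect_equal(texture_loss(A, A), 0)
  expect_equal(texture_loss(A, A[, c(3, 1, 4, 2)]), 0)
  # gram of [[1,1],[0,0]] is [[0.5,0],[0,0]]; vs zero activations
  expect_equal(texture_loss(matrix(c(1, 0, 1, 0), 2, 2), matrix(0, 2, 2)),
               0.03125)
  expect_error(texture_loss(A, matrix(0, 3, 4)), "mismatch")
})

test_that("TV loss: boundary handling, checkerboard value, symmetry", {
  expect_equal(tv_loss(array(0.7, c(4, 5, 3))), 0)
  checker <- array(c(0, 1, 1, 0), c(2, 2, 1))
  expect_equal(tv_loss(checker), 1.0)
  g <- random_frame(6, 5, seed = 9)
  expect_equal(tv_loss(1 - g), tv_loss(g))
  # independent brute-force over explicit index loops
  d <- dim(g)
  tot <- 0
  for (c in 1:3) for (i in 1:6) for (j in 1:5) {
    if (i < 6) tot <- tot + abs(g[i + 1, j, c] - g[i, j, c])
    if (j < 5) tot <- tot + abs(g[i, j + 1, c] - g[i, j, c])
  }
  expect_equal(tv_loss(g), tot / prod(d), tolerance = 1e-12)
})

test_that("total loss is additive over separately computed terms", {
  mods <- fixture_models()
  layers <- c("conv1", "conv2", "conv3")
  x <- random_frame(8, 8, seed = 1)
  g <- random_frame(8, 8, seed = 2)
  spec <- fixture_loss_spec(beta = 1, lambda = 0, omega = 0.3)
  ta <- spatial_forward(mods$spatial, x, layers)
  ga <- spatial_forward(mods$spatial, g, layers)
  lt <- total_loss(spec, list(spatial_texture = ta), list(spatial = ga), g,
                   omega = 0.3)
  manual <- sum(mapply(texture_loss, ta, ga)) + 0.3 * tv_loss(g)
  expect_equal(as.numeric(lt), manual, tolerance = 1e-10)
  # matching activations and omega = 0 give exactly zero
  expect_equal(as.numeric(total_loss(spec, list(spatial_texture = ta),
                                     list(spatial = ta), g, omega = 0)), 0)
  # weight-0 terms are skipped: no target needed
  spec0 <- fixture_loss_spec(beta = 0, lambda = 0, omega = 0.1)
  expect_equal(as.numeric(total_loss(spec0, list(), list(),
                                     array(0.5, c(4, 4, 3)))), 0)
  # active term without routed activations is a config error
  expect_error(total_loss(spec, list(), list(spatial = ga), g),
               "missing routed target")
})

test_that("loss_spec rejects negative weights and unrouted active terms", {
  expect_error(loss_spec(alpha = -1), "non-negative")
  expect_error(loss_spec(beta = 1,
                         routing = c(spatial_content = "a",
                                     spatial_texture = "",
                                     temporal_content = "a",
                                     temporal_texture = "a")),
               "spatial_texture")
})
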