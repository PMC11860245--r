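# Shared helpers: tiny seeded inputs used across the suite.

random_frame <- function(H, W, C = 3L, seed = 1L) {
  withr::with_seed(seed, array(runif(H * W * C), c(H, W, C)))
}

tiny_video <- function(H = 8L, W = 8L, T = 3L, seed = 1L) {
  withr::with_seed(seed, video_tensor(array(runif(H * W * 3 * T),
                                            c(H, W, 3L, T))))
}

fixture_models <- function(seed = 0L) {
  list(spatial = make_fixture_model(seed, 1L),
       temporal = make_msoe_model(msoe_params(scales = 2L)))
}

# Angular difference on the circle, in [0, pi]
ang_diff <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

# Fixture-net loss spec over its three conv layers
fixture_loss_spec <- function(...) {
  loss_spec(spatial_layers = c("conv1", "conv2", "conv3"),
            routing = c(spatial_content = "main", spatial_texture = "main",
                        temporal_content = "main", temporal_texture = "main"),
            ...)
}
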