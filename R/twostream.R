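# Two-stream differentiable feature models.
#
# A stream model is a closure-based object exposing named-layer activations
# (post-nonlinearity feature maps flattened to N x M matrices, filters by
# spatial locations) together with a vector-Jacobian product so the synthesis
# loop can backpropagate losses to the input frame. Three families are
# registered: "fixture" (tiny seeded conv nets for tests), "vgg19" (the
# spatial feature-extractor architecture; weights seeded unless a file is
# supplied) and "msoe" (an analytic multiscale spacetime-oriented energy
# model for motion).

# ---- activation flattening -------------------------------------------------
# A[n, m]: filters major; spatial index m = (row - 1) * W + col (row-major).

#' @keywords internal
flatten_act <- function(x) {
  d <- dim(x)
  A <- matrix(aperm(x, c(3, 2, 1)), nrow = d[3])
  attr(A, "map_dims") <- d[1:2]
  A
}

#' @keywords internal
unflatten_act <- function(A, h, w) {
  N <- nrow(A)
  aperm(array(A, c(N, w, h)), c(3, 2, 1))
}

# ---- generic conv-net engine ----------------------------------------------
# Layers: list(type = "conv", name, w (kh x kw x Cin x Cout), b) with fused
# ReLU, or list(type = "pool") for 2x2 average pooling. Activations are
# tapped after the ReLU, matching the convention that a layer activation is
# the output of convolution followed by the nonlinearity.

#' @keywords internal
convnet_model <- function(name, layers, arity, in_channels) {
  layer_names <- vapply(layers,
                        function(L) if (L$type == "conv") L$name else NA_character_,
                        character(1))
  layer_names <- layer_names[!is.na(layer_names)]

  forward <- function(x, xprev = NULL, taps, want_grad = FALSE) {
    unknown <- setdiff(taps, layer_names)
    if (length(unknown)) {
      stop("unknown layer name(s): ", paste(unknown, collapse = ", "))
    }
    cur <- if (arity == 2L) {
      if (is.null(xprev)) stop("temporal model needs both frames")
      if (!identical(dim(x), dim(xprev))) stop("frame shape mismatch")
      arr <- array(0, c(dim(x)[1:2], dim(x)[3] * 2L))
      arr[, , seq_len(dim(x)[3])] <- x
      arr[, , dim(x)[3] + seq_len(dim(x)[3])] <- xprev
      arr
    } else {
      x
    }
    if (dim(cur)[3] != in_channels) {
      stop("expected ", in_channels / arity, " input channel(s)")
    }
    # index of the deepest layer we must evaluate
    tapped_at <- vapply(layers, function(L) {
      L$type == "conv" && L$name %in% taps
    }, logical(1))
    last <- max(which(tapped_at))
    acts <- list()
    store <- vector("list", last)
    for (li in seq_len(last)) {
      L <- layers[[li]]
      if (L$type == "conv") {
        pre <- conv2d_same(cur, L$w, L$b)
        mask <- pre > 0
        out <- pre * mask
        if (want_grad) store[[li]] <- list(mask = mask, in_dim = dim(cur))
        cur <- out
        if (L$name %in% taps) acts[[L$name]] <- flatten_act(cur)
      } else { # pool
        d <- dim(cur)
        Pr <- pool_matrix(d[1])
        Pc <- pool_matrix(d[2])
        if (want_grad) store[[li]] <- list(Pr = Pr, Pc = Pc)
        cur <- apply_lr(cur, Pr, Pc)
      }
    }
    backward <- NULL
    if (want_grad) {
      out_dims <- lapply(seq_len(last), function(li) NULL)
      backward <- function(tap_grads) {
        g <- NULL
        for (li in rev(seq_len(last))) {
          L <- layers[[li]]
          if (L$type == "conv" && L$name %in% names(tap_grads)) {
            tg <- tap_grads[[L$name]]
            md <- attr(acts[[L$name]], "map_dims")
            tgarr <- unflatten_act(tg, md[1], md[2])
            g <- if (is.null(g)) tgarr else g + tgarr
          }
          if (is.null(g)) next
          if (L$type == "conv") {
            g <- g * store[[li]]$mask
            g <- conv2d_same_input_grad(g, L$w)
          } else {
            g <- apply_lr(g, t(store[[li]]$Pr), t(store[[li]]$Pc))
          }
        }
        if (arity == 2L) {
          C <- dim(g)[3] / 2L
          list(gx = g[, , seq_len(C), drop = FALSE],
               gxprev = g[, , C + seq_len(C), drop = FALSE])
        } else {
          list(gx = g, gxprev = NULL)
        }
      }
    }
    list(acts = acts, backward = backward)
  }

  structure(list(name = name, arity = arity, layer_names = layer_names,
                 forward = forward),
            class = "stream_model")
}

#' @export
print.stream_model <- function(x, ...) {
  cat(sprintf("<stream_model '%s'> arity %d, layers: %s\n", x$name, x$arity,
              paste(x$layer_names, collapse = ", ")))
  invisible(x)
}

#' @keywords internal
he_init_conv <- function(k, cin, cout, gain = 1) {
  w <- array(stats::rnorm(k * k * cin * cout, sd = gain * sqrt(2 / (k * k * cin))),
             c(k, k, cin, cout))
  list(w = w, b = rep(0.1, cout))
}

#' Build a small seeded fixture stream model
#'
#' A three-layer convolutional network (4, 6 and 8 filters of size 3x3 with
#' ReLU) with seed-reproducible random weights. Fixture models make every
#' stage of the synthesis and loss machinery testable at desk scale without
#' any pretrained weights. `arity = 2` builds a temporal variant that takes
#' the current and previous frame (channel-concatenated).
#'
#' @param seed integer seed for the weight draw.
#' @param arity 1 (spatial; input is one frame) or 2 (temporal; frame pair).
#' @return A `stream_model` with layers `conv1`, `conv2`, `conv3`.
#' @export
make_fixture_model <- function(seed = 0L, arity = 1L) {
  stopifnot(arity %in% c(1L, 2L))
  cin <- 3L * arity
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  layers <- list(
    c(list(type = "conv", name = "conv1"), he_init_conv(3L, cin, 4L)),
    c(list(type = "conv", name = "conv2"), he_init_conv(3L, 4L, 6L)),
    c(list(type = "conv", name = "conv3"), he_init_conv(3L, 6L, 8L))
  )
  convnet_model(paste0("fixture", arity), layers, arity, cin)
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build the VGG-19 architecture spatial stream
#'
#' The 16-convolution feature extractor of VGG-19 with average pooling
#' between blocks (average pooling gives smoother synthesis gradients than
#' max pooling and is the customary choice for texture matching). The
#' canonical texture layers are `conv1_1`, `conv2_1`, `conv3_1`, `conv4_1`
#' and `conv5_1`. Without a weights file the filters are He-initialized from
#' `seed`; supply `weights` (an `.rds` file holding a named list with `w`
#' and `b` entries per conv layer) to use pretrained filters.
#'
#' @param seed seed for random initialization when no weights are given.
#' @param weights optional path to an `.rds` weights file.
#' @return A `stream_model` of arity 1.
#' @export
make_vgg19_model <- function(seed = 0L, weights = NULL) {
  blocks <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                 c(512, 512, 512, 512), c(512, 512, 512, 512))
  wlist <- if (!is.null(weights)) readRDS(weights) else NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  layers <- list()
  cin <- 3L
  for (b in seq_along(blocks)) {
    for (u in seq_along(blocks[[b]])) {
      nm <- sprintf("conv%d_%d", b, u)
      cout <- blocks[[b]][u]
      par <- if (!is.null(wlist)) wlist[[nm]] else he_init_conv(3L, cin, cout)
      layers[[length(layers) + 1L]] <-
        list(type = "conv", name = nm, w = par$w, b = par$b)
      cin <- cout
    }
    layers[[length(layers) + 1L]] <- list(type = "pool")
  }
  convnet_model("vgg19", layers, 1L, 3L)
}

# ---- analytic MSOE temporal stream ----------------------------------------

#' @keywords internal
gabor_pair <- function(theta, f0, sigma, radius) {
  s <- seq(-radius, radius)
  X <- outer(rep(1, length(s)), s)   # column coordinate
  Y <- outer(s, rep(1, length(s)))   # row coordinate
  u <- X * cos(theta) + Y * sin(theta)
  env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * f0 * u)
  odd <- env * sin(2 * pi * f0 * u)
  even <- even - mean(even) # zero DC response: luminance invariance
  odd <- odd - mean(odd)
  nrm <- sqrt(sum(even^2))
  list(even = even / nrm, odd = odd / nrm)
}

#' MSOE parameter set
#'
#' Tunable parameters of the analytic multiscale spacetime-oriented energy
#' model: `scales` pyramid levels (downsampled by 2 with a Gaussian
#' prefilter), quadrature Gabor pairs at `orientations` (radians), spatial
#' passband `f0` (cycles/pixel), Gaussian envelope `sigma` (pixels), kernel
#' `radius` (pixels), preferred `speed` (pixels/frame) of the moving
#' channels, and the divisive-normalization constant `norm_const`.
#'
#' @param scales number of pyramid levels (>= 1).
#' @param orientations Gabor orientations in radians.
#' @param f0 spatial frequency of the Gabor carrier, cycles/pixel.
#' @param sigma Gaussian envelope width, pixels.
#' @param radius kernel radius, pixels (kernel is `2*radius + 1` square).
#' @param speed preferred speed of the moving channels, pixels/frame.
#' @param norm_const additive constant of the divisive normalization.
#' @param gain output scale of the normalized energies; the default makes
#'   temporal-stream Gram losses commensurate with spatial-stream losses
#'   (see the methods vignette).
#' @export
msoe_params <- function(scales = 3L,
                        orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                        f0 = 0.25, sigma = 2, radius = 4, speed = 1,
                        norm_const = 0.01, gain = 3) {
  list(scales = as.integer(scales), orientations = orientations, f0 = f0,
       sigma = sigma, radius = radius, speed = speed,
       norm_const = norm_const, gain = gain)
}

#' Build the analytic MSOE temporal stream
#'
#' A motion-energy model over consecutive frame pairs: both frames are
#' grayscaled, a Gaussian pyramid is built, quadrature pairs of oriented
#' Gabor filters are applied to the two-frame stack with a temporal phase
#' offset `2*pi*f0*speed` per motion direction (two opposite directions per
#' orientation plus one static channel per orientation), quadrature outputs
#' are squared and summed, energies are divisively normalized across
#' channels, and all scales are bilinearly upsampled and concatenated into
#' the `concat` layer. The model is differentiable, orientation-selective,
#' multiscale and — because the filters have zero DC response — invariant
#' to global luminance offsets.
#'
#' @param params an [msoe_params()] list.
#' @return A `stream_model` of arity 2 with layers `concat`,
#'   `scale1` ... `scaleS`.
#' @export
make_msoe_model <- function(params = msoe_params()) {
  p <- params
  pairs <- lapply(p$orientations, gabor_pair,
                  f0 = p$f0, sigma = p$sigma, radius = p$radius)
  phi <- 2 * pi * p$f0 * p$speed
  # per orientation: phases (+phi, -phi, 0) -> two opposite directions + static
  phases <- c(phi, -phi, 0)
  n_or <- length(p$orientations)
  n_ch <- n_or * length(phases)
  layer_names <- c("concat", paste0("scale", seq_len(p$scales)))
  blur_k <- gaussian_kernel_1d(1, radius = 2L)

  # circular boundary: exact zero response to constants everywhere, so the
  # model is exactly invariant to global luminance offsets
  conv1 <- function(m, k) {
    conv2d_same(array(m, c(dim(m), 1L)),
                array(k, c(dim(k), 1L, 1L)), border = "wrap")[, , 1]
  }

  forward <- function(x, xprev = NULL, taps, want_grad = FALSE) {
    unknown <- setdiff(taps, layer_names)
    if (length(unknown)) {
      stop("unknown layer name(s): ", paste(unknown, collapse = ", "))
    }
    if (is.null(xprev)) stop("temporal model needs both frames")
    if (!identical(dim(x), dim(xprev))) stop("frame shape mismatch")
    C <- dim(x)[3]
    g1 <- if (C == 3L) to_grayscale(x)[, , 1] else x[, , 1]
    g0 <- if (C == 3L) to_grayscale(xprev)[, , 1] else xprev[, , 1]
    H <- nrow(g1); W <- ncol(g1)
    kmin <- 2L * p$radius + 3L
    n_scales <- p$scales
    while (n_scales > 1L && min(H, W) / 2^(n_scales - 1L) < kmin) {
      n_scales <- n_scales - 1L
    }
    # combined full-res -> scale operators (blur then decimate, repeated)
    Ls <- vector("list", n_scales); Rs <- vector("list", n_scales)
    Ls[[1]] <- diag(H); Rs[[1]] <- diag(W)
    for (s in seq_len(n_scales - 1L)) {
      hs <- nrow(Ls[[s]]); ws <- nrow(Rs[[s]])
      Dr <- pool_matrix(hs) %*% filter_matrix(hs, blur_k, "replicate")
      Dc <- pool_matrix(ws) %*% filter_matrix(ws, blur_k, "replicate")
      Ls[[s + 1L]] <- Dr %*% Ls[[s]]
      Rs[[s + 1L]] <- Dc %*% Rs[[s]]
    }
    scale_store <- vector("list", n_scales)
    concat_maps <- vector("list", n_scales)
    acts <- list()
    for (s in seq_len(n_scales)) {
      i1 <- Ls[[s]] %*% g1 %*% t(Rs[[s]])
      i0 <- Ls[[s]] %*% g0 %*% t(Rs[[s]])
      hs <- nrow(i1); ws <- ncol(i1)
      base <- vector("list", n_or)
      E <- array(0, c(hs, ws, n_ch))
      AB <- vector("list", n_ch)
      ch <- 0L
      for (o in seq_len(n_or)) {
        ke <- pairs[[o]]$even; ko <- pairs[[o]]$odd
        b <- list(ce1 = conv1(i1, ke), co1 = conv1(i1, ko),
                  ce0 = conv1(i0, ke), co0 = conv1(i0, ko))
        base[[o]] <- b
        for (ph in phases) {
          ch <- ch + 1L
          A <- b$ce1 + cos(ph) * b$ce0 - sin(ph) * b$co0
          B <- b$co1 + sin(ph) * b$ce0 + cos(ph) * b$co0
          E[, , ch] <- A^2 + B^2
          if (want_grad) AB[[ch]] <- list(A = A, B = B)
        }
      }
      S <- apply(E, c(1, 2), sum)
      Y <- p$gain * E / array(rep(S + p$norm_const, n_ch), dim(E))
      nm <- paste0("scale", s)
      if (nm %in% taps) acts[[nm]] <- flatten_act(Y)
      up <- apply_lr(Y, resize_matrix(H, hs), resize_matrix(W, ws))
      concat_maps[[s]] <- up
      if (want_grad) {
        scale_store[[s]] <- list(E = E, S = S, AB = AB, hs = hs, ws = ws,
                                 Ur = resize_matrix(H, hs),
                                 Uc = resize_matrix(W, ws))
      }
    }
    if ("concat" %in% taps) {
      full <- array(0, c(H, W, n_ch * n_scales))
      for (s in seq_len(n_scales)) {
        full[, , (s - 1L) * n_ch + seq_len(n_ch)] <- concat_maps[[s]]
      }
      acts[["concat"]] <- flatten_act(full)
    }
    backward <- NULL
    if (want_grad) {
      backward <- function(tap_grads) {
        gg1 <- matrix(0, H, W)
        gg0 <- matrix(0, H, W)
        gcat <- NULL
        if ("concat" %in% names(tap_grads)) {
          gcat <- unflatten_act(tap_grads[["concat"]], H, W)
        }
        for (s in seq_len(n_scales)) {
          st <- scale_store[[s]]
          gY <- array(0, c(st$hs, st$ws, n_ch))
          nm <- paste0("scale", s)
          if (nm %in% names(tap_grads)) {
            gY <- gY + unflatten_act(tap_grads[[nm]], st$hs, st$ws)
          }
          if (!is.null(gcat)) {
            gup <- gcat[, , (s - 1L) * n_ch + seq_len(n_ch), drop = FALSE]
            gY <- gY + apply_lr(gup, t(st$Ur), t(st$Uc))
          }
          # divisive normalization vjp
          denom <- st$S + p$norm_const
          wsum <- matrix(0, st$hs, st$ws)
          for (ch in seq_len(n_ch)) wsum <- wsum + gY[, , ch] * st$E[, , ch]
          gi1 <- matrix(0, st$hs, st$ws)
          gi0 <- matrix(0, st$hs, st$ws)
          ch <- 0L
          for (o in seq_len(n_or)) {
            ke <- pairs[[o]]$even; ko <- pairs[[o]]$odd
            g_ce1 <- 0; g_co1 <- 0; g_ce0 <- 0; g_co0 <- 0
            for (ph in phases) {
              ch <- ch + 1L
              gE <- p$gain * (gY[, , ch] / denom - wsum / denom^2)
              gA <- 2 * scale_store[[s]]$AB[[ch]]$A * gE
              gB <- 2 * scale_store[[s]]$AB[[ch]]$B * gE
              g_ce1 <- g_ce1 + gA
              g_co1 <- g_co1 + gB
              g_ce0 <- g_ce0 + cos(ph) * gA + sin(ph) * gB
              g_co0 <- g_co0 - sin(ph) * gA + cos(ph) * gB
            }
            rot <- function(k) k[nrow(k):1, ncol(k):1]
            gi1 <- gi1 + conv1(g_ce1, rot(ke)) + conv1(g_co1, rot(ko))
            gi0 <- gi0 + conv1(g_ce0, rot(ke)) + conv1(g_co0, rot(ko))
          }
          gg1 <- gg1 + t(Ls[[s]]) %*% gi1 %*% Rs[[s]]
          gg0 <- gg0 + t(Ls[[s]]) %*% gi0 %*% Rs[[s]]
        }
        expand <- function(gg) {
          if (C == 3L) {
            out <- array(0, c(H, W, 3L))
            out[, , 1] <- 0.299 * gg
            out[, , 2] <- 0.587 * gg
            out[, , 3] <- 0.114 * gg
            out
          } else {
            array(gg, c(H, W, 1L))
          }
        }
        list(gx = expand(gg1), gxprev = expand(gg0))
      }
    }
    list(acts = acts, backward = backward)
  }

  structure(list(name = "msoe", arity = 2L, layer_names = layer_names,
                 forward = forward, params = p,
                 channel_info = list(per_scale = n_ch, phases = phases,
                                     orientations = p$orientations)),
            class = "stream_model")
}

#' Stream-model registry
#'
#' @param name one of `"fixture"`, `"vgg19"`, `"msoe"`.
#' @param seed seed for random weight initialization where applicable.
#' @param arity input arity for fixture models (1 or 2).
#' @param weights optional weights file for `"vgg19"`.
#' @param params optional [msoe_params()] for `"msoe"`.
#' @return A `stream_model`.
#' @export
make_stream_model <- function(name = c("fixture", "vgg19", "msoe"),
                              seed = 0L, arity = 1L, weights = NULL,
                              params = NULL) {
  name <- match.arg(name)
  switch(name,
         fixture = make_fixture_model(seed, arity),
         vgg19 = make_vgg19_model(seed, weights),
         msoe = make_msoe_model(if (is.null(params)) msoe_params() else params))
}

#' Layer activations of the spatial stream
#'
#' Runs the spatial module on one frame and returns the requested layer
#' activations flattened to `N x M` matrices (filters by spatial locations;
#' spatial index is row-major). Activations are taken after the
#' nonlinearity.
#'
#' @param model a `stream_model` with arity 1.
#' @param x an `H x W x C` frame.
#' @param layers character vector of layer names.
#' @return Named list of activation matrices with a `map_dims` attribute.
#' @export
spatial_forward <- function(model, x, layers) {
  if (model$arity != 1L) stop("spatial_forward needs an arity-1 model")
  model$forward(x, NULL, layers)$acts
}

#' Layer activations of the temporal stream
#'
#' Runs the temporal module on a consecutive frame pair. For the MSOE model
#' the `concat` layer holds the multiscale concatenation of the normalized
#' orientation-energy maps.
#'
#' @param model a `stream_model` with arity 2.
#' @param x_t,x_tm1 current and previous frame (same shape).
#' @param layers character vector of layer names.
#' @return Named list of activation matrices.
#' @export
temporal_forward <- function(model, x_t, x_tm1, layers) {
  if (model$arity != 2L) stop("temporal_forward needs an arity-2 model")
  model$forward(x_t, x_tm1, layers)$acts
}
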