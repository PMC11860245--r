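# Frame-by-frame metamer synthesis: multiscale (octave) normalized gradient
# descent on each generated frame, preconditioned by frame blending, mirror
# padding and per-frame color transfer.

#' Octave schedule
#'
#' Coarse-to-fine resolution schedule of the per-frame optimization. Octave
#' exponents are listed coarse to fine with the final entry 0 (original
#' resolution); each octave runs its own iteration count and learning rate.
#' Defaults are the reference setting: octaves (-2, -1, 0) at scale 1.5 with
#' 250/750/1000 iterations and learning rates 0.001/0.003/0.005.
#'
#' @param octaves integer exponents, coarse to fine, last = 0.
#' @param sigma octave scale (> 1).
#' @param iterations per-octave iteration counts (>= 0).
#' @param eta per-octave learning rates (> 0).
#' @export
octave_schedule <- function(octaves = c(-2L, -1L, 0L), sigma = 1.5,
                            iterations = c(250L, 750L, 1000L),
                            eta = c(0.001, 0.003, 0.005)) {
  n <- length(octaves)
  if (length(iterations) != n || length(eta) != n) {
    stop("octaves, iterations and eta must have equal length")
  }
  if (any(iterations < 0) || any(eta <= 0)) {
    stop("iterations must be >= 0 and eta > 0")
  }
  if (utils::tail(octaves, 1) != 0L) stop("the last octave must be 0")
  list(octaves = as.integer(octaves), sigma = sigma,
       iterations = as.integer(iterations), eta = eta)
}

#' Synthesis configuration
#'
#' Bundles the loss specification, octave schedule and the perceptual
#' stabilization hyperparameters: blending ratio `phi` (fraction of the
#' previous post-processed frame in each frame's initialization, the rest
#' uniform noise), mirror padding length `xi` (time-reversed first frames
#' prepended and later discarded), color-transfer switches, and the epsilon
#' guard of the gradient standard-deviation normalization.
#'
#' @param loss a [loss_spec()].
#' @param schedule an [octave_schedule()].
#' @param phi blending ratio in `[0, 1]` (default 0.95).
#' @param xi number of mirror-padding frames (default 5).
#' @param seed integer seed; all stochastic steps derive from it.
#' @param color_transfer apply per-frame 3D color-distribution transfer?
#' @param regrain apply gradient-preserving regraining after the transfer?
#' @param color_iterations distribution-transfer iterations per frame.
#' @param color_reference target id used as color reference; default is the
#'   spatial-texture routed target (the spatial stream owns appearance).
#' @param grad_norm_epsilon epsilon of the gradient normalization.
#' @export
synthesis_config <- function(loss = loss_spec(), schedule = octave_schedule(),
                             phi = 0.95, xi = 5L, seed = 1L,
                             color_transfer = TRUE, regrain = TRUE,
                             color_iterations = 20L, color_reference = NULL,
                             grad_norm_epsilon = 1e-8) {
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  if (xi < 0) stop("xi must be >= 0")
  list(loss = loss, schedule = schedule, phi = phi, xi = as.integer(xi),
       seed = as.integer(seed), color_transfer = color_transfer,
       regrain = regrain, color_iterations = as.integer(color_iterations),
       color_reference = color_reference,
       grad_norm_epsilon = grad_norm_epsilon)
}

#' Mirror-pad a video in time
#'
#' Prepends the first `xi` frames in reversed order, so frames
#' `[a, b, c]` with `xi = 2` become `[b, a, a, b, c]`. Used so the earliest
#' synthesized frames reach stationary statistics before the unpadded
#' portion begins; the padded outputs are discarded afterwards.
#'
#' @param v a video.
#' @param xi number of frames to mirror (0 <= `xi` <= `n_frames(v)`).
#' @return A video of length `n_frames(v) + xi`.
#' @export
mirror_pad <- function(v, xi) {
  T <- n_frames(v)
  if (xi > T) stop("xi cannot exceed the number of frames")
  if (xi == 0L) return(v)
  d <- dim(v)
  out <- array(0, c(d[1:3], T + xi))
  for (k in seq_len(xi)) out[, , , k] <- v[, , , xi - k + 1L]
  out[, , , xi + seq_len(T)] <- v
  video_tensor(out, fps = attr(v, "fps"), check = FALSE)
}

#' Blended frame initialization
#'
#' `g_t <- phi * g_{t-1} + (1 - phi) * mu` with `mu ~ U(0, 1)` elementwise:
#' each frame's optimization starts from a mix of the previous
#' post-processed frame and fresh uniform noise. With no predecessor
#' (`g_prev = NULL`) the initialization is pure noise.
#'
#' @param g_prev previous post-processed frame, or `NULL`.
#' @param phi blending ratio in `[0, 1]`.
#' @param dim frame dimensions `c(H, W, C)` (required when `g_prev` is NULL).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (the synthesis loop seeds once globally).
#' @return An `H x W x C` frame.
#' @export
blend_init <- function(g_prev, phi, dim = base::dim(g_prev), seed = NULL) {
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  mu <- array(stats::runif(prod(dim)), dim)
  if (is.null(g_prev)) mu else phi * g_prev + (1 - phi) * mu
}

#' Per-channel gradient normalization
#'
#' Divides each channel of a gradient array by its standard deviation over
#' the height and width dimensions (plus `eps`), so update magnitudes are
#' comparable across octaves and loss configurations.
#'
#' @param grad frame-shaped array.
#' @param eps small positive guard (zero gradients map to zero).
#' @return Array of the same shape.
#' @export
normalize_gradient <- function(grad, eps = 1e-8) {
  for (c in seq_len(dim(grad)[3])) {
    grad[, , c] <- grad[, , c] / (pop_sd(grad[, , c]) + eps)
  }
  grad
}

# Routed target frames at one time step: per active term, the current (and
# for temporal terms previous) frame of the routed target video.
#' @keywords internal
route_targets <- function(spec, padded, t) {
  w <- c(spatial_content = spec$alpha, spatial_texture = spec$beta,
         temporal_content = spec$theta, temporal_texture = spec$lambda)
  out <- list()
  for (term in names(w)[w > 0]) {
    id <- spec$routing[[term]]
    if (is.null(padded[[id]])) {
      stop("loss term '", term, "' routes to unknown target '", id, "'")
    }
    v <- padded[[id]]
    out[[term]] <- list(
      current = get_frame(v, t),
      previous = if (t > 1L) get_frame(v, t - 1L) else NULL
    )
  }
  out
}

#' Optimize one generated frame
#'
#' Runs the multiscale optimization of a single frame: for each octave
#' (coarse to fine) the routed target frames, the current estimate and the
#' previous generated frame are resized to the octave resolution, target
#' activations (and Gram matrices) are computed once, and the scheduled
#' number of normalized-gradient-descent steps is applied to the estimate
#' only, clamping to `[0, 1]` after every step. Between octaves the
#' estimate is bilinearly upsampled. Temporal loss terms are skipped when no
#' previous generated frame exists (the mirror padding in
#' [synthesize_video()] makes this affect only discarded frames).
#'
#' @param targets named list: per active loss term, a list with `current`
#'   and (for temporal terms) `previous` target frames at full resolution.
#' @param g_init initial frame estimate (full resolution).
#' @param g_prev_generated previous generated frame, or `NULL`.
#' @param cfg a [synthesis_config()].
#' @param models list with `spatial` and `temporal` stream models.
#' @return The optimized frame, with attribute `trace` (a data frame of
#'   per-octave, per-iteration loss values).
#' @export
optimize_frame <- function(targets, g_init, g_prev_generated, cfg, models) {
  spec <- cfg$loss
  sch <- cfg$schedule
  d <- dim(g_init)
  H <- d[1]; W <- d[2]
  n_oct <- length(sch$octaves)
  omega <- rep_len(spec$omega, n_oct)
  use_sp <- (spec$alpha > 0 || spec$beta > 0)
  use_tp <- (spec$theta > 0 || spec$lambda > 0) && !is.null(g_prev_generated)
  g <- g_init
  trace <- list()
  for (k in seq_len(n_oct)) {
    os <- octave_size(H, W, sch$sigma, sch$octaves[k])
    g <- resize_bilinear(g, os[1], os[2])
    rsz <- function(f) if (is.null(f)) NULL else resize_bilinear(f, os[1], os[2])
    tgt <- lapply(targets, function(p) list(current = rsz(p$current),
                                            previous = rsz(p$previous)))
    gp <- rsz(g_prev_generated)
    # target activations / Grams, once per octave
    tacts <- list()
    if (spec$alpha > 0) {
      tacts$spatial_content <- spatial_forward(models$spatial,
                                               tgt$spatial_content$current,
                                               spec$spatial_layers)
    }
    if (spec$beta > 0) {
      A <- spatial_forward(models$spatial, tgt$spatial_texture$current,
                           spec$spatial_layers)
      tacts$spatial_texture_gram <- lapply(A, gram)
    }
    if (use_tp && spec$theta > 0) {
      p <- tgt$temporal_content
      if (is.null(p$previous)) stop("temporal content term lacks a previous target frame")
      tacts$temporal_content <- temporal_forward(models$temporal, p$current,
                                                 p$previous, spec$temporal_layers)
    }
    if (use_tp && spec$lambda > 0) {
      p <- tgt$temporal_texture
      if (is.null(p$previous)) stop("temporal texture term lacks a previous target frame")
      A <- temporal_forward(models$temporal, p$current, p$previous,
                            spec$temporal_layers)
      tacts$temporal_texture_gram <- lapply(A, gram)
    }
    iters <- sch$iterations[k]
    losses <- numeric(iters)
    for (it in seq_len(iters)) {
      grad <- array(0, dim(g))
      lval <- 0
      if (use_sp) {
        fw <- models$spatial$forward(g, NULL, spec$spatial_layers,
                                     want_grad = TRUE)
        tg <- list()
        for (ly in spec$spatial_layers) {
          Ahat <- fw$acts[[ly]]
          gl <- matrix(0, nrow(Ahat), ncol(Ahat))
          if (spec$alpha > 0) {
            A <- tacts$spatial_content[[ly]]
            lval <- lval + spec$alpha * content_loss(A, Ahat)
            gl <- gl + spec$alpha * content_loss_grad(A, Ahat)
          }
          if (spec$beta > 0) {
            G <- tacts$spatial_texture_gram[[ly]]
            Ghat <- gram(Ahat)
            lval <- lval + spec$beta * sum((G - Ghat)^2) / (2 * nrow(Ahat)^2)
            gl <- gl + spec$beta * texture_loss_grad(G, Ahat)
          }
          tg[[ly]] <- gl
        }
        grad <- grad + fw$backward(tg)$gx
      }
      if (use_tp) {
        fw <- models$temporal$forward(g, gp, spec$temporal_layers,
                                      want_grad = TRUE)
        tg <- list()
        for (ly in spec$temporal_layers) {
          Ahat <- fw$acts[[ly]]
          gl <- matrix(0, nrow(Ahat), ncol(Ahat))
          if (spec$theta > 0) {
            A <- tacts$temporal_content[[ly]]
            lval <- lval + spec$theta * content_loss(A, Ahat)
            gl <- gl + spec$theta * content_loss_grad(A, Ahat)
          }
          if (spec$lambda > 0) {
            G <- tacts$temporal_texture_gram[[ly]]
            Ghat <- gram(Ahat)
            lval <- lval + spec$lambda * sum((G - Ghat)^2) / (2 * nrow(Ahat)^2)
            gl <- gl + spec$lambda * texture_loss_grad(G, Ahat)
          }
          tg[[ly]] <- gl
        }
        grad <- grad + fw$backward(tg)$gx
      }
      if (omega[k] > 0) {
        lval <- lval + omega[k] * tv_loss(g)
        grad <- grad + omega[k] * tv_loss_grad(g)
      }
      losses[it] <- lval
      grad <- normalize_gradient(grad, cfg$grad_norm_epsilon)
      g <- clamp01(g - sch$eta[k] * grad)
    }
    if (iters > 0) {
      trace[[k]] <- data.frame(octave = sch$octaves[k],
                               iter = seq_len(iters), loss = losses)
    }
  }
  g <- resize_bilinear(g, H, W)
  attr(g, "trace") <- if (length(trace)) do.call(rbind, trace) else
    data.frame(octave = integer(), iter = integer(), loss = numeric())
  g
}

#' Synthesize a metamer video
#'
#' The full generation loop. All routed targets are mirror-padded by
#' `cfg$xi` frames; then for each frame the estimate is initialized by
#' [blend_init()] from the previous post-processed frame, optimized with
#' [optimize_frame()], and post-processed by 3D color-distribution transfer
#' toward the color-reference target's current frame (with optional
#' regraining). The first `xi` outputs are discarded. The temporal stream's
#' generated-side input at time `t` is the previous post-processed generated
#' frame.
#'
#' Pass a single video to match one target, or a named list of videos with
#' `cfg$loss$routing` pointing each loss term at a target id (for example
#' spatial texture from one video and temporal texture from another:
#' spatiotemporal factorization).
#'
#' @param targets a video or a named list of videos of equal length/shape.
#' @param cfg a [synthesis_config()].
#' @param models list with `spatial` and `temporal` stream models.
#' @return A video of the target length, with attribute `loss_trace`.
#' @export
synthesize_video <- function(targets, cfg, models) {
  if (inherits(targets, "stst_video")) {
    ids <- unique(cfg$loss$routing)
    targets <- stats::setNames(rep(list(targets), length(ids)), ids)
  }
  d <- dim(targets[[1]])
  for (v in targets) {
    if (!identical(dim(v), d)) stop("all targets must share length and shape")
  }
  spec <- cfg$loss
  if (d[3] == 1L) cfg$color_transfer <- FALSE # transfer is defined on RGB
  color_id <- cfg$color_reference
  if (is.null(color_id)) {
    color_id <- if (spec$beta > 0) spec$routing[["spatial_texture"]] else
      names(targets)[1]
  }
  if (is.null(targets[[color_id]])) {
    stop("color reference '", color_id, "' is not a target id")
  }
  padded <- lapply(targets, mirror_pad, xi = cfg$xi)
  Tp <- d[4] + cfg$xi
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  out <- array(0, c(d[1:3], Tp))
  g_prev <- NULL
  traces <- vector("list", Tp)
  for (t in seq_len(Tp)) {
    g0 <- blend_init(g_prev, cfg$phi, dim = d[1:3])
    tgt <- route_targets(spec, padded, t)
    g <- optimize_frame(tgt, g0, g_prev, cfg, models)
    tr <- attr(g, "trace")
    attr(g, "trace") <- NULL
    if (cfg$color_transfer) {
      ref <- get_frame(padded[[color_id]], t)
      # one fixed rotation sequence for every frame: a per-frame redraw
      # would inject spurious frame-to-frame color changes (flicker)
      gc <- pdf_transfer(g, ref, iterations = cfg$color_iterations,
                         seed = cfg$seed + 1009L)
      if (cfg$regrain) gc <- regrain(gc, g)
      g <- clamp01(gc)
    }
    out[, , , t] <- g
    if (nrow(tr)) traces[[t]] <- cbind(frame = t - cfg$xi, tr)
    g_prev <- g
  }
  res <- video_tensor(array(out[, , , cfg$xi + seq_len(d[4])], d),
                      fps = attr(targets[[1]], "fps"))
  attr(res, "loss_trace") <- do.call(rbind, traces[!vapply(traces, is.null,
                                                           logical(1))])
  res
}
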