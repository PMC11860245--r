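# Seeded synthetic stimuli with analytically known motion, used as ground
# truth throughout the test suite. Translation is toroidal (implemented as
# a Fourier-domain phase shift), so global statistics are exactly
# stationary and conservation assertions hold to machine precision.
# Velocity convention matches the flow module: angle 0 is rightward
# (columns), angles increase toward downward (rows).

# Exact periodic subpixel translation of a matrix by (dx, dy).
#' @keywords internal
shift_periodic <- function(m, dx, dy) {
  H <- nrow(m); W <- ncol(m)
  ky <- c(0:floor(H / 2), -(ceiling(H / 2) - 1):-1)[1:H]
  kx <- c(0:floor(W / 2), -(ceiling(W / 2) - 1):-1)[1:W]
  phase <- exp(-2i * pi * (outer(ky, rep(1, W)) * dy / H +
                             outer(rep(1, H), kx) * dx / W))
  Re(stats::fft(stats::fft(m) * phase, inverse = TRUE)) / (H * W)
}

#' Drifting sinusoidal grating
#'
#' A luminance grating with `spatial_freq` cycles per frame width, oriented
#' so that it drifts along `direction` at `speed` pixels/frame. Ground
#' truth velocity is stored in the `flow` attribute as per-pair `(dx, dy)`.
#' `direction` and `speed` may be vectors of length `T - 1` (per frame
#' pair).
#'
#' @param H,W,T frame size and frame count.
#' @param spatial_freq grating frequency, cycles per frame width.
#' @param direction drift direction, radians (0 = rightward).
#' @param speed drift speed, pixels/frame.
#' @param contrast peak-to-mean amplitude in `[0, 1]` (default 0.45).
#' @param seed unused (the grating is deterministic); kept so all fixture
#'   generators share one signature.
#' @return An RGB video with attribute `flow`.
#' @export
drifting_grating <- function(H, W, T, spatial_freq = 4, direction = 0,
                             speed = 1, contrast = 0.45, seed = 1L) {
  dirs <- rep_len(direction, max(T - 1L, 1L))
  spds <- rep_len(speed, max(T - 1L, 1L))
  f <- spatial_freq / W # cycles per pixel
  x <- outer(rep(1, H), seq_len(W) - 1)
  y <- outer(seq_len(H) - 1, rep(1, W))
  out <- array(0, c(H, W, 3L, T))
  offx <- 0
  offy <- 0
  flow <- matrix(0, max(T - 1L, 0L), 2)
  for (t in seq_len(T)) {
    if (t > 1L) {
      dx <- spds[t - 1L] * cos(dirs[t - 1L])
      dy <- spds[t - 1L] * sin(dirs[t - 1L])
      offx <- offx + dx
      offy <- offy + dy
      flow[t - 1L, ] <- c(dx, dy)
    }
    th <- if (t > 1L) dirs[t - 1L] else dirs[1L]
    u <- (x - offx) * cos(th) + (y - offy) * sin(th)
    g <- 0.5 + contrast * sin(2 * pi * f * u)
    for (c in 1:3) out[, , c, t] <- g
  }
  v <- video_tensor(clamp01(out))
  attr(v, "flow") <- flow
  v
}

#' Rigidly translating smooth noise texture
#'
#' A seeded band-limited RGB noise patch translating with toroidal
#' wraparound at `speed` pixels/frame along `direction` (either may be a
#' length `T - 1` vector for time-varying motion). Because translation is
#' periodic and exact, the per-frame intensity is constant to machine
#' precision and the true flow field is spatially uniform.
#'
#' @param H,W,T frame size and frame count.
#' @param speed pixels/frame.
#' @param direction radians (0 = rightward).
#' @param smoothness Gaussian blur sd (pixels) applied to the white noise.
#' @param seed integer seed.
#' @return An RGB video with attribute `flow` (per-pair `(dx, dy)` rows).
#' @export
translating_texture <- function(H, W, T, speed = 2, direction = 0,
                                smoothness = 1.5, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dirs <- rep_len(direction, max(T - 1L, 1L))
  spds <- rep_len(speed, max(T - 1L, 1L))
  k <- gaussian_kernel_1d(smoothness)
  base <- array(0, c(H, W, 3L))
  lum <- matrix(stats::runif(H * W), H, W)
  tint <- matrix(stats::runif(H * W), H, W)
  smooth_periodic <- function(m) {
    # circular Gaussian blur keeps the texture toroidally stationary
    r <- (length(k) - 1L) / 2L
    for (o in seq(-r, r)) {
      if (o == -r) acc <- k[o + r + 1L] * m[((seq_len(H) - 1 + o) %% H) + 1, ]
      else acc <- acc + k[o + r + 1L] * m[((seq_len(H) - 1 + o) %% H) + 1, ]
    }
    m <- acc
    for (o in seq(-r, r)) {
      if (o == -r) acc <- k[o + r + 1L] * m[, ((seq_len(W) - 1 + o) %% W) + 1]
      else acc <- acc + k[o + r + 1L] * m[, ((seq_len(W) - 1 + o) %% W) + 1]
    }
    acc
  }
  lum <- smooth_periodic(lum)
  tint <- smooth_periodic(tint)
  rescale <- function(m) {
    rg <- range(m)
    if (diff(rg) < 1e-12) return(m * 0 + 0.5)
    0.15 + 0.7 * (m - rg[1]) / diff(rg)
  }
  lum <- rescale(lum)
  tint <- rescale(tint)
  # channels stay well inside [0, 1] so the spectral shift never clips and
  # conservation of global statistics is exact
  base[, , 1] <- lum * (0.55 + 0.35 * tint)
  base[, , 2] <- lum
  base[, , 3] <- lum * (0.9 - 0.35 * tint)
  out <- array(0, c(H, W, 3L, T))
  out[, , , 1] <- base
  offx <- 0
  offy <- 0
  flow <- matrix(0, max(T - 1L, 0L), 2)
  for (t in seq_len(T - 1L)) {
    dx <- spds[t] * cos(dirs[t])
    dy <- spds[t] * sin(dirs[t])
    offx <- offx + dx
    offy <- offy + dy
    flow[t, ] <- c(dx, dy)
    for (c in 1:3) out[, , c, t + 1L] <- shift_periodic(base[, , c], offx, offy)
  }
  v <- video_tensor(clamp01(out))
  attr(v, "flow") <- flow
  v
}

#' Static video tiled from a fixed color palette
#'
#' Frames are vertical color bands drawn from `palette` in the given
#' proportions; the video is static. Useful for palette-recovery and
#' color-distribution tests with exactly known ground truth.
#'
#' @param H,W,T frame size and frame count.
#' @param palette `k x 3` matrix of RGB colors in `[0, 1]`.
#' @param proportions band widths as fractions summing to 1 (default
#'   equal).
#' @param seed unused; shared fixture signature.
#' @return An RGB video.
#' @export
colored_blobs <- function(H, W, T, palette, proportions = NULL, seed = 1L) {
  palette <- as.matrix(palette)
  k <- nrow(palette)
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  stopifnot(length(proportions) == k, abs(sum(proportions) - 1) < 1e-9)
  edges <- round(cumsum(c(0, proportions)) * W)
  frame <- array(0, c(H, W, 3L))
  for (i in seq_len(k)) {
    cols <- (edges[i] + 1L):max(edges[i + 1L], edges[i] + 1L)
    cols <- cols[cols <= W]
    for (c in 1:3) frame[, cols, c] <- palette[i, c]
  }
  out <- array(0, c(H, W, 3L, T))
  for (t in seq_len(T)) out[, , , t] <- frame
  video_tensor(out)
}
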