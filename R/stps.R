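# Spatiotemporal phase scrambling (STPS): the baseline generation method.
# Phase randomization preserves amplitude spectra exactly; realness of the
# output is guaranteed by drawing the random phase field as the phase of
# the Fourier transform of a real random field (Hermitian symmetry for
# free), with the DC phase reset to zero so means are untouched.

#' @keywords internal
hermitian_phase <- function(dims) {
  r <- array(stats::runif(prod(dims)) - 0.5, dims)
  ph <- Arg(stats::fft(r))
  ph[1] <- 0 # DC bin (first element in every layout)
  ph
}

#' 2D phase scrambling
#'
#' Adds one random Hermitian-symmetric phase field per channel to the 2D
#' Fourier spectrum of every frame (the same field across all frames, so
#' residual temporal structure is untouched). Amplitude spectra and
#' per-frame channel means are preserved; uniform random phases in
#' `[-pi, pi]` arise from the phase of a white-noise field. Values are
#' returned unclipped by default so the spectral invariants hold exactly;
#' [stps_generate()] clips before color transfer.
#'
#' @param v a video.
#' @param seed integer seed.
#' @param clip clip the output to `[0, 1]`?
#' @return A video (possibly with values outside `[0, 1]` when
#'   `clip = FALSE`).
#' @export
phase_scramble_2d <- function(v, seed = 1L, clip = FALSE) {
  d <- dim(v)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- array(0, d)
  n <- d[1] * d[2]
  for (c in seq_len(d[3])) {
    mult <- exp(1i * hermitian_phase(d[1:2]))
    for (t in seq_len(d[4])) {
      F <- stats::fft(v[, , c, t])
      out[, , c, t] <- Re(stats::fft(F * mult, inverse = TRUE)) / n
    }
  }
  if (clip) out <- clamp01(out)
  video_tensor(out, fps = attr(v, "fps"), check = FALSE)
}

#' 3D phase scrambling
#'
#' Adds a random Hermitian-symmetric phase field to the full spatiotemporal
#' (3D) Fourier spectrum, per channel. The 3D amplitude spectrum and the
#' global per-channel mean are preserved.
#'
#' @inheritParams phase_scramble_2d
#' @export
phase_scramble_3d <- function(v, seed = 1L, clip = FALSE) {
  d <- dim(v)
  if (d[4] < 2L) stop("3D scrambling needs at least 2 frames")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- array(0, d)
  n <- d[1] * d[2] * d[4]
  for (c in seq_len(d[3])) {
    cube <- array(v[, , c, ], c(d[1], d[2], d[4]))
    mult <- exp(1i * hermitian_phase(dim(cube)))
    F <- stats::fft(cube)
    out[, , c, ] <- Re(stats::fft(F * mult, inverse = TRUE)) / n
  }
  if (clip) out <- clamp01(out)
  video_tensor(out, fps = attr(v, "fps"), check = FALSE)
}

#' Generate a phase-scrambled control video
#'
#' The three-step baseline: 2D phase scrambling of every frame, 3D phase
#' scrambling of the full spatiotemporal volume, then per-frame 3D
#' color-distribution transfer with the original frame `t` as reference
#' (plus regraining). Values are clipped to `[0, 1]` after the inverse
#' transforms, before the color transfer.
#'
#' @param v a video (RGB for the color-transfer step; grayscale videos skip
#'   it).
#' @param seed integer seed.
#' @param color_iterations distribution-transfer iterations per frame.
#' @param regrain apply gradient-preserving regraining?
#' @return A video of the same shape as `v` with values in `[0, 1]`.
#' @export
stps_generate <- function(v, seed = 1L, color_iterations = 20L,
                          regrain = TRUE) {
  d <- dim(v)
  s2 <- phase_scramble_2d(v, seed = seed)
  s3 <- phase_scramble_3d(s2, seed = seed + 1L)
  out <- array(clamp01(unclass(s3)), d)
  if (d[3] == 3L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed + 2L)
    for (t in seq_len(d[4])) {
      src <- array(out[, , , t], d[1:3])
      ref <- get_frame(v, t)
      g <- pdf_transfer(src, ref, iterations = color_iterations)
      if (regrain) g <- regrain(g, src)
      out[, , , t] <- g
    }
  }
  video_tensor(out, fps = attr(v, "fps"))
}
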