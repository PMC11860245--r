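#' Video tensors
#'
#' A video is stored as a 4-D numeric array with dimensions
#' `H x W x C x T` (rows, columns, channels, frames) and class
#' `"stst_video"`. Pixel intensities live in `[0, 1]`; quantization to 8 bit
#' happens only when frames are written to disk. Frames are indexed 1-based
#' in time, matching the `t`, `t - 1` notation used throughout the package.
#'
#' @param frames either a 4-D array `H x W x C x T`, or a list of
#'   `H x W x C` frame arrays sharing one shape.
#' @param fps frames per second (metadata only; not used in computation).
#' @param check validate the pixel range (values in `[0, 1]`)? Operations
#'   that legitimately produce out-of-range values (e.g. phase scrambling
#'   before clipping) set this to `FALSE`.
#' @return An object of class `"stst_video"`.
#' @examples
#' v <- video_tensor(array(0.5, c(4, 4, 3, 2)))
#' n_frames(v)
#' @export
video_tensor <- function(frames, fps = 30, check = TRUE) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    stopifnot(length(d) == 3)
    arr <- array(0, c(d, length(frames)))
    for (t in seq_along(frames)) {
      if (!identical(dim(frames[[t]]), d)) {
        stop("all frames must share the same H x W x C shape")
      }
      arr[, , , t] <- frames[[t]]
    }
    frames <- arr
  }
  if (length(dim(frames)) != 4) stop("expected an H x W x C x T array")
  d <- dim(frames)
  if (!d[3] %in% c(1L, 3L)) stop("channel count must be 1 or 3")
  if (d[4] < 1L) stop("a video needs at least one frame")
  if (check && (min(frames) < -1e-9 || max(frames) > 1 + 1e-9)) {
    stop("pixel values must lie in [0, 1]")
  }
  structure(frames, fps = fps, class = "stst_video")
}

#' @rdname video_tensor
#' @param v a video.
#' @export
n_frames <- function(v) dim(v)[4]

#' @rdname video_tensor
#' @param t frame index (1-based).
#' @export
get_frame <- function(v, t) {
  d <- dim(v)
  array(v[, , , t], d[1:3])
}

#' @rdname video_tensor
#' @param frame replacement `H x W x C` array.
#' @export
set_frame <- function(v, t, frame) {
  v[, , , t] <- frame
  v
}

#' @export
print.stst_video <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<stst_video> %d x %d px, %d channel(s), %d frames @ %g fps\n",
              d[1], d[2], d[3], d[4], attr(x, "fps")))
  invisible(x)
}

#' Read a video from a directory of PNG frames
#'
#' Frames are read in lexical filename order, which must equal temporal
#' order (use zero-padded frame numbers). Pixel values are returned in
#' `[0, 1]`. Container formats (MP4 etc.) are not supported: no video codec
#' library is bundled, and the lossless PNG-directory representation is the
#' canonical on-disk format of this package.
#'
#' @param path directory containing `.png` frames.
#' @param fps frame rate to record as metadata.
#' @return An [video_tensor()] object.
#' @export
read_video <- function(path, fps = 30) {
  if (!dir.exists(path)) {
    if (file.exists(path)) {
      stop("'", path, "' is a file; only PNG frame directories are supported")
    }
    stop("no such directory: ", path)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 2L) stop("need at least 2 frames, found ", length(files))
  frames <- lapply(files, function(f) {
    px <- png::readPNG(f)
    if (length(dim(px)) == 2L) dim(px) <- c(dim(px), 1L)
    if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE] # drop alpha
    px
  })
  video_tensor(frames, fps = fps)
}

#' Write a video as a directory of PNG frames
#'
#' Values are quantized to 8 bit at write time, so a read/write round trip
#' is exact to within 1/255 per pixel. `lossless = FALSE` is accepted for
#' interface compatibility but also writes PNG (no lossy codec is bundled).
#'
#' @param v a video.
#' @param path output directory (created if missing).
#' @param lossless ignored; PNG frames are always lossless.
#' @return `path`, invisibly.
#' @export
write_video <- function(v, path, lossless = TRUE) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", path)
  }
  T <- n_frames(v)
  width <- max(5L, nchar(as.character(T)))
  for (t in seq_len(T)) {
    f <- clamp01(get_frame(v, t))
    if (dim(f)[3] == 1L) dim(f) <- dim(f)[1:2]
    png::writePNG(f, file.path(path, sprintf(paste0("%0", width, "d.png"), t)))
  }
  invisible(path)
}

#' Convert an RGB frame to grayscale
#'
#' Luminance is the dot product of the channel values with
#' `(0.299, 0.587, 0.114)` (ITU-R BT.601 weights).
#'
#' @param f an `H x W x 3` frame.
#' @return An `H x W x 1` frame.
#' @examples
#' f <- array(c(1, 0, 0), c(1, 1, 3))
#' to_grayscale(f)[1, 1, 1] # 0.299
#' @export
to_grayscale <- function(f) {
  if (length(dim(f)) != 3 || dim(f)[3] != 3L) {
    stop("to_grayscale expects an H x W x 3 frame")
  }
  g <- 0.299 * f[, , 1] + 0.587 * f[, , 2] + 0.114 * f[, , 3]
  array(g, c(dim(f)[1:2], 1L))
}

#' Bilinear frame resize
#'
#' Bilinear interpolation with half-pixel centre alignment; interpolation
#' weights sum to one, so constant frames stay constant and the output is
#' clamped to `[0, 1]`. No antialias prefilter is applied when downscaling
#' (see the methods vignette for the rationale).
#'
#' @param f an `H x W x C` frame.
#' @param H,W target size in pixels (both >= 1).
#' @return The resized `H x W x C` frame.
#' @export
resize_bilinear <- function(f, H, W) {
  d <- dim(f)
  if (H < 1 || W < 1) stop("target size must be positive")
  if (H == d[1] && W == d[2]) return(f)
  Rr <- resize_matrix(H, d[1])
  Rc <- resize_matrix(W, d[2])
  clamp01(apply_lr(f, Rr, Rc))
}

#' @keywords internal
resize_video <- function(v, H, W) {
  d <- dim(v)
  out <- array(0, c(H, W, d[3], d[4]))
  for (t in seq_len(d[4])) out[, , , t] <- resize_bilinear(get_frame(v, t), H, W)
  video_tensor(out, fps = attr(v, "fps"), check = FALSE)
}

#' Octave geometry
#'
#' Frame size at octave `o` for octave scale `sigma`:
#' `H_o = trunc(H * sigma^o)`, `W_o = trunc(W * sigma^o)`. Truncation toward
#' zero is used for the integer conversion; with `sigma = 1.5` this maps a
#' 360 x 640 frame to 240 x 426 (`o = -1`) and 160 x 284 (`o = -2`).
#'
#' @param H,W original frame size in pixels.
#' @param sigma octave scale (> 1).
#' @param o octave exponent (integer <= 0; `o = 0` is the original size).
#' @return Integer vector `c(H_o, W_o)`.
#' @examples
#' octave_size(360, 640, 1.5, -2) # 160 284
#' @export
octave_size <- function(H, W, sigma, o) {
  if (sigma <= 1) stop("octave scale sigma must exceed 1")
  if (o > 0) stop("octave exponent must be <= 0")
  Ho <- trunc(H * sigma^o)
  Wo <- trunc(W * sigma^o)
  if (Ho < 1 || Wo < 1) stop("octave size collapses below one pixel")
  c(as.integer(Ho), as.integer(Wo))
}
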