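# Internal linear-operator helpers. Filtering, pooling and resizing are
# expressed as left/right matrix products on H x W channel slices so that
# their adjoints (needed for backpropagation) are plain transposes.

#' @keywords internal
gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Correlation matrix for a 1-D kernel indexed -r..r: out[i] = sum_o k[o] f[i+o].
# border: "zero" drops out-of-range taps, "replicate" clamps the index.
#' @keywords internal
filter_matrix <- function(n, kern, border = c("zero", "replicate")) {
  border <- match.arg(border)
  r <- (length(kern) - 1L) / 2L
  M <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    w <- kern[o + r + 1L]
    if (w == 0) next
    for (i in seq_len(n)) {
      j <- i + o
      if (j < 1L || j > n) {
        if (border == "zero") next
        j <- min(max(j, 1L), n)
      }
      M[i, j] <- M[i, j] + w
    }
  }
  M
}

# Bilinear resampling matrix mapping n_in samples onto n_out (half-pixel
# centre alignment; rows sum to 1 so constants are preserved exactly).
#' @keywords internal
resize_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    M[, 1L] <- 1
    return(M)
  }
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5
    src <- min(max(src, 1), n_in)
    lo <- floor(src)
    hi <- min(lo + 1, n_in)
    f <- src - lo
    M[i, lo] <- M[i, lo] + (1 - f)
    M[i, hi] <- M[i, hi] + f
  }
  M
}

# 2x2 average-pooling matrix (stride 2, trailing odd sample dropped).
#' @keywords internal
pool_matrix <- function(n_in) {
  n_out <- n_in %/% 2L
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) M[i, c(2L * i - 1L, 2L * i)] <- 0.5
  M
}

# Apply left/right operator pair to every channel of an H x W x C array.
#' @keywords internal
apply_lr <- function(x, L, R) {
  C <- dim(x)[3]
  out <- array(0, c(nrow(L), nrow(R), C))
  for (c in seq_len(C)) out[, , c] <- L %*% x[, , c] %*% t(R)
  out
}

# -- dense 2-D cross-correlation ("conv" in CNN parlance), 'same' zero pad --
#
# Implemented by im2col + one matrix product; the gather-index matrix is
# cached per (H, W, kh, kw, Cin) signature since synthesis calls the same
# shapes thousands of times.

.conv_cache <- new.env(parent = emptyenv())

#' @keywords internal
im2col_index <- function(H, W, kh, kw, Cin) {
  key <- paste(H, W, kh, kw, Cin, sep = "_")
  idx <- .conv_cache[[key]]
  if (!is.null(idx)) return(idx)
  ph <- (kh - 1L) / 2L
  pw <- (kw - 1L) / 2L
  PH <- H + 2L * ph
  PW <- W + 2L * pw
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  base <- (j - 1L) * PH + i # padded linear index of the top-left tap, chan 1
  offs <- integer(kh * kw * Cin)
  q <- 1L
  for (ci in 0:(Cin - 1L)) {
    for (dj in 0:(kw - 1L)) {
      for (di in 0:(kh - 1L)) {
        offs[q] <- ci * PH * PW + dj * PH + di
        q <- q + 1L
      }
    }
  }
  idx <- outer(base, offs, `+`)
  .conv_cache[[key]] <- idx
  idx
}

# x: H x W x Cin, w: kh x kw x Cin x Cout (odd kernel sizes). Optional bias.
# border "zero" pads with zeros; "wrap" is circular (toroidal) convolution,
# whose adjoint is circular correlation with the rotated kernel.
#' @keywords internal
conv2d_same <- function(x, w, bias = NULL, border = "zero") {
  d <- dim(x)
  H <- d[1]; W <- d[2]; Cin <- d[3]
  kd <- dim(w)
  kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  stopifnot(kd[3] == Cin, kh %% 2L == 1L, kw %% 2L == 1L)
  ph <- (kh - 1L) / 2L
  pw <- (kw - 1L) / 2L
  if (border == "wrap") {
    ri <- ((seq(1L - ph, H + ph) - 1L) %% H) + 1L
    ci <- ((seq(1L - pw, W + pw) - 1L) %% W) + 1L
    xp <- x[ri, ci, , drop = FALSE]
  } else {
    xp <- array(0, c(H + 2L * ph, W + 2L * pw, Cin))
    xp[ph + seq_len(H), pw + seq_len(W), ] <- x
  }
  idx <- im2col_index(H, W, kh, kw, Cin)
  Xcol <- matrix(xp[idx], nrow = H * W)
  y <- Xcol %*% matrix(w, ncol = Cout)
  if (!is.null(bias)) y <- sweep(y, 2L, bias, `+`)
  array(y, c(H, W, Cout))
}

# Gradient of conv2d_same w.r.t. its input: correlate the upstream gradient
# with the spatially flipped, channel-transposed kernel.
#' @keywords internal
conv2d_same_input_grad <- function(gy, w, border = "zero") {
  kd <- dim(w)
  wr <- aperm(w[kd[1]:1, kd[2]:1, , , drop = FALSE], c(1, 2, 4, 3))
  conv2d_same(gy, wr, border = border)
}

#' @keywords internal
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Population (biased) standard deviation.
#' @keywords internal
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
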