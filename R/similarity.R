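# Representation- and prediction-similarity metrics: linear centered kernel
# alignment (CKA), the structural similarity index (SSIM) and its dynamic
# conditional variant (cSSIM), plus a sliding-window CKA over aligned
# activation sequences.

#' Linear centered kernel alignment
#'
#' For column-centered matrices `Xc`, `Yc` (samples by features):
#' `CKA = ||Yc' Xc||_F^2 / (||Xc' Xc||_F * ||Yc' Yc||_F)`.
#' Equals 1 for representations identical up to orthogonal rotation and
#' isotropic scaling; equivalent to the centered-Gram HSIC formulation.
#'
#' @param X,Y matrices with the same number of rows (samples >= 2).
#' @return Scalar in `[0, 1]`; `NA` (with a warning) if either input has no
#'   variance after centering.
#' @export
linear_cka <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("sample counts differ")
  if (nrow(X) < 2L) stop("need at least 2 samples")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  nx <- sqrt(sum(crossprod(Xc)^2))
  ny <- sqrt(sum(crossprod(Yc)^2))
  if (nx == 0 || ny == 0) {
    warning("zero-variance input: CKA undefined")
    return(NA_real_)
  }
  sum(crossprod(Yc, Xc)^2) / (nx * ny)
}

#' @keywords internal
valid_filter_matrix <- function(n, kern) {
  len <- length(kern)
  n_out <- n - len + 1L
  if (n_out < 1L) stop("window larger than image")
  M <- matrix(0, n_out, n)
  for (i in seq_len(n_out)) M[i, i:(i + len - 1L)] <- kern
  M
}

#' Structural similarity index
#'
#' Standard SSIM with an 11x11 Gaussian window (sd 1.5), `K1 = 0.01`,
#' `K2 = 0.03` and dynamic range 1, averaged over all fully valid window
#' positions. RGB inputs are grayscaled first.
#'
#' @param a,b frames of identical shape (`H x W x C` arrays or matrices).
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b) {
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  if (is.matrix(b)) b <- array(b, c(dim(b), 1L))
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  x <- if (dim(a)[3] == 3L) to_grayscale(a)[, , 1] else a[, , 1]
  y <- if (dim(b)[3] == 3L) to_grayscale(b)[, , 1] else b[, , 1]
  s <- seq(-5, 5)
  k <- exp(-s^2 / (2 * 1.5^2))
  k <- k / sum(k)
  Fr <- valid_filter_matrix(nrow(x), k)
  Fc <- t(valid_filter_matrix(ncol(x), k))
  f <- function(m) Fr %*% m %*% Fc
  mx <- f(x); my <- f(y)
  vx <- f(x^2) - mx^2
  vy <- f(y^2) - my^2
  cxy <- f(x * y) - mx * my
  C1 <- 0.01^2
  C2 <- 0.03^2
  S <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(S)
}

#' Conditional SSIM for next-frame predictions
#'
#' `cSSIM(f_t, f_{t-1}, fhat_t) = (1 - SSIM(f_{t-1}, fhat_t)) *
#' SSIM(f_t, fhat_t)`: the prediction's similarity to the true current
#' frame, discounted by how much the prediction merely copies the previous
#' frame (a perfect copy scores 0).
#'
#' @param f_t current ground-truth frame.
#' @param f_tm1 previous frame.
#' @param f_hat predicted current frame.
#' @return Scalar.
#' @export
cssim <- function(f_t, f_tm1, f_hat) {
  (1 - ssim(f_tm1, f_hat)) * ssim(f_t, f_hat)
}

#' Sliding-window CKA over activation sequences
#'
#' Splits two aligned per-frame activation sequences into windows of
#' `window` consecutive frames advanced by `step`, stacks each window's
#' activations row-wise (frames x features) and returns one linear-CKA
#' value per window position.
#'
#' @param acts_a,acts_b lists of per-frame activation row-vectors or
#'   matrices (equal length; element `t` has the same row count in both).
#' @param window window length in frames (default 5).
#' @param step hop size in frames (default 1).
#' @return Numeric vector of length `floor((T - window)/step) + 1`.
#' @export
sliding_cka <- function(acts_a, acts_b, window = 5L, step = 1L) {
  T <- length(acts_a)
  if (length(acts_b) != T) stop("sequence length mismatch")
  if (window > T) stop("window exceeds sequence length")
  starts <- seq(1L, T - window + 1L, by = step)
  vapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    Xa <- do.call(rbind, lapply(acts_a[idx], function(m) {
      if (is.null(dim(m))) matrix(m, nrow = 1) else m
    }))
    Xb <- do.call(rbind, lapply(acts_b[idx], function(m) {
      if (is.null(dim(m))) matrix(m, nrow = 1) else m
    }))
    linear_cka(Xa, Xb)
  }, numeric(1))
}
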