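# Dense two-frame optical flow via Farneback polynomial expansion: each
# image neighborhood is approximated by a quadratic polynomial under a
# Gaussian applicability (weight) window; the displacement field follows
# from how the polynomial coefficients shift between frames, solved over an
# averaging window and refined iteratively over a coarse-to-fine pyramid.

#' Optical-flow parameters
#'
#' Defaults follow the customary dense Farneback setting for feature
#' analysis: pyramid scale 0.5 with five levels, averaging window 13,
#' ten iterations per level, polynomial neighborhood 5 and Gaussian
#' smoothing 1.1 for the expansion basis.
#'
#' @param pyr_scale pyramid decimation factor (only 0.5 is supported).
#' @param levels number of pyramid levels (capped by image size).
#' @param winsize side of the box averaging window, pixels.
#' @param iterations displacement refinement iterations per level.
#' @param poly_n pixel neighborhood radius of the polynomial expansion.
#' @param poly_sigma Gaussian applicability sd of the expansion, pixels.
#' @export
flow_params <- function(pyr_scale = 0.5, levels = 5L, winsize = 13L,
                        iterations = 10L, poly_n = 5L, poly_sigma = 1.1) {
  if (pyr_scale != 0.5) stop("only pyr_scale = 0.5 is supported")
  list(pyr_scale = pyr_scale, levels = as.integer(levels),
       winsize = as.integer(winsize), iterations = as.integer(iterations),
       poly_n = as.integer(poly_n), poly_sigma = poly_sigma)
}

# Quadratic polynomial expansion f(x) ~ x'Ax + b'x + c of a grayscale
# image under a Gaussian applicability of radius n, sd sigma. Returns the
# per-pixel fields a11 (x^2), a22 (y^2), a12 (xy/2), b1 (x), b2 (y).
#' @keywords internal
poly_expansion <- function(f, n, sigma) {
  H <- nrow(f); W <- ncol(f)
  s <- seq(-n, n)
  a <- exp(-s^2 / (2 * sigma^2))
  k0 <- a
  k1 <- a * s
  k2 <- a * s^2
  My0 <- filter_matrix(H, k0, "replicate")
  My1 <- filter_matrix(H, k1, "replicate")
  My2 <- filter_matrix(H, k2, "replicate")
  Mx0 <- t(filter_matrix(W, k0, "replicate"))
  Mx1 <- t(filter_matrix(W, k1, "replicate"))
  Mx2 <- t(filter_matrix(W, k2, "replicate"))
  m00 <- My0 %*% f %*% Mx0
  m10 <- My0 %*% f %*% Mx1
  m01 <- My1 %*% f %*% Mx0
  m20 <- My0 %*% f %*% Mx2
  m02 <- My2 %*% f %*% Mx0
  m11 <- My1 %*% f %*% Mx1
  # normal-equation matrix of the basis (1, x, y, x^2, y^2, xy) under a x a
  X <- outer(rep(1, length(s)), s)
  Y <- outer(s, rep(1, length(s)))
  Wt <- outer(a, a)
  B <- cbind(1, c(X), c(Y), c(X)^2, c(Y)^2, c(X) * c(Y))
  G <- t(B * c(Wt)) %*% B
  Ginv <- solve(G)
  M <- rbind(c(m00), c(m10), c(m01), c(m20), c(m02), c(m11))
  Cc <- Ginv %*% M
  shape <- function(v) matrix(v, H, W)
  list(a11 = shape(Cc[4, ]), a22 = shape(Cc[5, ]), a12 = shape(Cc[6, ] / 2),
       b1 = shape(Cc[2, ]), b2 = shape(Cc[3, ]))
}

#' @keywords internal
bilerp_mat <- function(m, yy, xx) {
  H <- nrow(m); W <- ncol(m)
  yy <- pmin(pmax(yy, 1), H)
  xx <- pmin(pmax(xx, 1), W)
  y0 <- pmin(floor(yy), H - 1L)
  x0 <- pmin(floor(xx), W - 1L)
  fy <- yy - y0
  fx <- xx - x0
  id <- function(y, x) (x - 1) * H + y
  m[id(y0, x0)] * (1 - fy) * (1 - fx) + m[id(y0 + 1, x0)] * fy * (1 - fx) +
    m[id(y0, x0 + 1)] * (1 - fy) * fx + m[id(y0 + 1, x0 + 1)] * fy * fx
}

# One pyramid level of displacement refinement.
#' @keywords internal
flow_level <- function(P1, P2, dx, dy, winsize, iterations) {
  H <- nrow(dx); W <- ncol(dx)
  box <- rep(1 / winsize, winsize)
  Br <- filter_matrix(H, box, "replicate")
  Bc <- t(filter_matrix(W, box, "replicate"))
  blur <- function(m) Br %*% m %*% Bc
  yy0 <- matrix(seq_len(H), H, W)
  xx0 <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (it in seq_len(iterations)) {
    yy <- yy0 + dy
    xx <- xx0 + dx
    w <- lapply(P2, function(m) matrix(bilerp_mat(m, yy, xx), H, W))
    a11 <- (P1$a11 + w$a11) / 2
    a12 <- (P1$a12 + w$a12) / 2
    a22 <- (P1$a22 + w$a22) / 2
    db1 <- -0.5 * (w$b1 - P1$b1) + a11 * dx + a12 * dy
    db2 <- -0.5 * (w$b2 - P1$b2) + a12 * dx + a22 * dy
    G11 <- blur(a11^2 + a12^2)
    G12 <- blur(a12 * (a11 + a22))
    G22 <- blur(a12^2 + a22^2)
    h1 <- blur(a11 * db1 + a12 * db2)
    h2 <- blur(a12 * db1 + a22 * db2)
    # relative ridge keeps the solve well-posed under the aperture problem
    # (pure 1-D structure): degenerate directions fall back to normal flow
    reg <- 1e-6 * (G11 + G22) + 1e-12
    G11 <- G11 + reg
    G22 <- G22 + reg
    det <- G11 * G22 - G12^2
    dx <- (G22 * h1 - G12 * h2) / det
    dy <- (G11 * h2 - G12 * h1) / det
  }
  list(dx = dx, dy = dy)
}

#' Dense optical flow between two grayscale frames
#'
#' Estimates the displacement field `d` such that frame 1 at pixel `p`
#' appears near `p + d` in frame 2. Units are pixels/frame; `dx` is
#' rightward (columns), `dy` downward (rows).
#'
#' @param f1,f2 grayscale matrices (or `H x W x 1` arrays) of equal size.
#' @param params a [flow_params()] list.
#' @return List with `dx` and `dy` matrices.
#' @export
optical_flow <- function(f1, f2, params = flow_params()) {
  if (length(dim(f1)) == 3L) f1 <- f1[, , 1]
  if (length(dim(f2)) == 3L) f2 <- f2[, , 1]
  if (!identical(dim(f1), dim(f2))) stop("frame size mismatch")
  p <- params
  min_side <- 2L * p$poly_n + 3L
  pyr1 <- list(f1)
  pyr2 <- list(f2)
  blur_k <- gaussian_kernel_1d(1, radius = 2L)
  lev <- 1L
  while (lev < p$levels &&
         min(dim(pyr1[[lev]])) >= 2L * min_side) {
    down <- function(m) {
      Dr <- pool_matrix(nrow(m)) %*% filter_matrix(nrow(m), blur_k, "replicate")
      Dc <- pool_matrix(ncol(m)) %*% filter_matrix(ncol(m), blur_k, "replicate")
      Dr %*% m %*% t(Dc)
    }
    pyr1[[lev + 1L]] <- down(pyr1[[lev]])
    pyr2[[lev + 1L]] <- down(pyr2[[lev]])
    lev <- lev + 1L
  }
  dx <- matrix(0, nrow(pyr1[[lev]]), ncol(pyr1[[lev]]))
  dy <- dx
  for (l in rev(seq_len(lev))) {
    if (l < lev) {
      H <- nrow(pyr1[[l]]); W <- ncol(pyr1[[l]])
      Rr <- resize_matrix(H, nrow(dx))
      Rc <- resize_matrix(W, ncol(dx))
      dx <- 2 * (Rr %*% dx %*% t(Rc))
      dy <- 2 * (Rr %*% dy %*% t(Rc))
    }
    P1 <- poly_expansion(pyr1[[l]], p$poly_n, p$poly_sigma)
    P2 <- poly_expansion(pyr2[[l]], p$poly_n, p$poly_sigma)
    res <- flow_level(P1, P2, dx, dy, p$winsize, p$iterations)
    dx <- res$dx
    dy <- res$dy
  }
  list(dx = dx, dy = dy)
}
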