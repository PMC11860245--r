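# Loss components of the style-transfer objective: content (activation
# matching), texture (Gram-matrix matching), anisotropic total variation,
# and their combination with per-term weights and target routing. Gradient
# helpers return dL/dActivation so the synthesis loop can chain them through
# a stream model's vector-Jacobian product.

#' Content loss between two layer activations
#'
#' `L = 1 / (2 N M) * sum_ij (A_ij - Ahat_ij)^2` for `N x M` activation
#' matrices. Preserves the retinotopic (spatial) arrangement of features.
#'
#' @param A,Ahat activation matrices of identical shape (target, generated).
#' @return Non-negative scalar.
#' @export
content_loss <- function(A, Ahat) {
  if (!identical(dim(A), dim(Ahat))) stop("activation shape mismatch")
  sum((A - Ahat)^2) / (2 * nrow(A) * ncol(A))
}

#' @keywords internal
content_loss_grad <- function(A, Ahat) {
  (Ahat - A) / (nrow(A) * ncol(A))
}

#' Gram matrix of a layer activation
#'
#' `G_ij = 1/(N M) * sum_k A_ik A_jk`: the normalized filter-response
#' correlation matrix, the stationary texture statistic. Symmetric and
#' positive semidefinite; invariant to any permutation of spatial locations.
#'
#' @param A an `N x M` activation matrix.
#' @return An `N x N` matrix.
#' @export
gram <- function(A) {
  tcrossprod(A) / (nrow(A) * ncol(A))
}

#' Texture loss between two layer activations
#'
#' `L = 1/(2 N^2) * sum_ij (G_ij - Ghat_ij)^2` on the Gram matrices of the
#' two activations. Because the Gram normalizes by the number of spatial
#' locations, the two activations may have different spatial sizes (as
#' happens across octaves) but must share the filter count `N`.
#'
#' @param A,Ahat activation matrices with equal row (filter) counts.
#' @return Non-negative scalar.
#' @export
texture_loss <- function(A, Ahat) {
  if (nrow(A) != nrow(Ahat)) stop("filter count mismatch")
  G <- gram(A)
  Ghat <- gram(Ahat)
  sum((G - Ghat)^2) / (2 * nrow(A)^2)
}

# dL/dAhat for the texture loss (G of the target precomputed upstream).
#' @keywords internal
texture_loss_grad <- function(G, Ahat) {
  Ghat <- gram(Ahat)
  D <- (Ghat - G) / nrow(Ahat)^2
  (2 / (nrow(Ahat) * ncol(Ahat))) * (D %*% Ahat)
}

#' Anisotropic total variation of a frame
#'
#' `1/(H W C)` times the sum over channels of absolute vertical and
#' horizontal neighbor differences (pairs whose neighbor falls outside the
#' frame are omitted). Penalizes high-frequency pixel noise while tolerating
#' edges.
#'
#' @param g an `H x W x C` frame array.
#' @return Non-negative scalar.
#' @examples
#' tv_loss(array(c(0, 1, 1, 0), c(2, 2, 1))) # checkerboard: 1
#' @export
tv_loss <- function(g) {
  d <- dim(g)
  tot <- 0
  for (c in seq_len(d[3])) {
    m <- g[, , c]
    if (d[1] > 1L) tot <- tot + sum(abs(m[-1, , drop = FALSE] - m[-d[1], , drop = FALSE]))
    if (d[2] > 1L) tot <- tot + sum(abs(m[, -1, drop = FALSE] - m[, -d[2], drop = FALSE]))
  }
  tot / prod(d)
}

#' @keywords internal
tv_loss_grad <- function(g) {
  d <- dim(g)
  out <- array(0, d)
  nrm <- 1 / prod(d)
  for (c in seq_len(d[3])) {
    m <- g[, , c]
    gm <- matrix(0, d[1], d[2])
    if (d[1] > 1L) {
      s <- sign(m[-1, , drop = FALSE] - m[-d[1], , drop = FALSE])
      gm[-1, ] <- gm[-1, ] + s
      gm[-d[1], ] <- gm[-d[1], ] - s
    }
    if (d[2] > 1L) {
      s <- sign(m[, -1, drop = FALSE] - m[, -d[2], drop = FALSE])
      gm[, -1] <- gm[, -1] + s
      gm[, -d[2]] <- gm[, -d[2]] - s
    }
    out[, , c] <- gm * nrm
  }
  out
}

#' Loss specification
#'
#' Weights and layer selections for the four style-transfer loss terms plus
#' total variation. `alpha`/`beta` weight spatial content/texture over the
#' spatial layers, `theta`/`lambda` weight temporal content/texture over the
#' temporal layers, and `omega` weights the TV term (a vector gives one
#' value per octave, coarse to fine). A zero weight disables its term
#' entirely. `routing` maps each loss term to the name of a target video,
#' enabling spatiotemporal factorization (one target for space, another for
#' time).
#'
#' @param alpha,beta spatial content / texture weights (>= 0).
#' @param theta,lambda temporal content / texture weights (>= 0).
#' @param omega total-variation weight, scalar or per-octave vector.
#' @param spatial_layers,temporal_layers layer-name character vectors.
#' @param routing named character vector with entries `spatial_content`,
#'   `spatial_texture`, `temporal_content`, `temporal_texture` naming target
#'   identifiers.
#' @return A `loss_spec` list.
#' @export
loss_spec <- function(alpha = 0, beta = 1, theta = 0, lambda = 1,
                      omega = c(0.05, 0.1, 0.5),
                      spatial_layers = c("conv1_1", "conv2_1", "conv3_1",
                                         "conv4_1", "conv5_1"),
                      temporal_layers = "concat",
                      routing = c(spatial_content = "spatial",
                                  spatial_texture = "spatial",
                                  temporal_content = "temporal",
                                  temporal_texture = "temporal")) {
  if (any(c(alpha, beta, theta, lambda) < 0) || any(omega < 0)) {
    stop("loss weights must be non-negative")
  }
  need <- c("spatial_content", "spatial_texture",
            "temporal_content", "temporal_texture")
  w <- c(spatial_content = alpha, spatial_texture = beta,
         temporal_content = theta, temporal_texture = lambda)
  for (term in need[w > 0]) {
    if (is.na(routing[term]) || !nzchar(routing[term])) {
      stop("no routed target for active loss term '", term, "'")
    }
  }
  structure(list(alpha = alpha, beta = beta, theta = theta, lambda = lambda,
                 omega = omega, spatial_layers = spatial_layers,
                 temporal_layers = temporal_layers, routing = routing),
            class = "loss_spec")
}

#' Combined style-transfer loss
#'
#' `L = sum_{l in L_s}(alpha * L_content + beta * L_texture) +
#'      sum_{l in L_t}(theta * L_content + lambda * L_texture) +
#'      omega * L_TV(g)`.
#' Terms with zero weight are not computed. `targets` and `generated` hold
#' per-stream named activation lists, as produced by [spatial_forward()] /
#' [temporal_forward()]; routing has already selected which target video
#' each term's activations come from.
#'
#' @param spec a [loss_spec()].
#' @param targets list with (as needed) `spatial_content`, `spatial_texture`,
#'   `temporal_content`, `temporal_texture`: each a named list of target
#'   activation matrices over that stream's layers.
#' @param generated list with `spatial` and/or `temporal` activation lists
#'   of the generated frame.
#' @param g the generated frame array (needed when any `omega > 0`).
#' @param omega TV weight to use (defaults to the first entry of
#'   `spec$omega`).
#' @return Scalar total loss with attribute `terms` (per-term breakdown).
#' @export
total_loss <- function(spec, targets, generated, g = NULL,
                       omega = spec$omega[1]) {
  terms <- c(spatial_content = 0, spatial_texture = 0,
             temporal_content = 0, temporal_texture = 0, tv = 0)
  pull <- function(term, stream) {
    tl <- targets[[term]]
    if (is.null(tl)) stop("missing routed target activations for '", term, "'")
    gl <- generated[[stream]]
    if (is.null(gl)) stop("missing generated activations for stream '", stream, "'")
    list(tl = tl, gl = gl)
  }
  acc <- function(term, stream, layers, w, fun) {
    if (w == 0) return(0)
    p <- pull(term, stream)
    s <- 0
    for (ly in layers) s <- s + fun(p$tl[[ly]], p$gl[[ly]])
    w * s
  }
  terms["spatial_content"] <- acc("spatial_content", "spatial",
                                  spec$spatial_layers, spec$alpha, content_loss)
  terms["spatial_texture"] <- acc("spatial_texture", "spatial",
                                  spec$spatial_layers, spec$beta, texture_loss)
  terms["temporal_content"] <- acc("temporal_content", "temporal",
                                   spec$temporal_layers, spec$theta, content_loss)
  terms["temporal_texture"] <- acc("temporal_texture", "temporal",
                                   spec$temporal_layers, spec$lambda, texture_loss)
  if (omega > 0) {
    if (is.null(g)) stop("g frame required for the TV term")
    terms["tv"] <- omega * tv_loss(g)
  }
  structure(sum(terms), terms = terms)
}
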