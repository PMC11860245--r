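# Low-level spatiotemporal feature time series and comparison statistics:
# per-frame intensity and contrast (spatial), per-frame-pair pixel change
# and dense optical-flow summaries (temporal), plus Pearson/Euclidean
# series comparison, 3D color-histogram KL divergence and k-means palettes.

#' @keywords internal
feature_series <- function(name, values) {
  structure(values, name = name, class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series '%s'> length %d\n", attr(x, "name"), length(x)))
  print(as.numeric(x))
  invisible(x)
}

#' Per-frame mean pixel intensity
#'
#' The average pixel value over height, width and channels, per frame.
#'
#' @param v a video.
#' @return A length-`T` feature series.
#' @export
pixel_intensity <- function(v) {
  feature_series("intensity",
                 vapply(seq_len(n_frames(v)),
                        function(t) mean(get_frame(v, t)), numeric(1)))
}

#' Per-frame luminance contrast
#'
#' The population standard deviation over height and width of each frame
#' after grayscale conversion (BT.601 weights).
#'
#' @param v an RGB video.
#' @return A length-`T` feature series.
#' @export
contrast <- function(v) {
  feature_series("contrast",
                 vapply(seq_len(n_frames(v)), function(t) {
                   pop_sd(to_grayscale(get_frame(v, t)))
                 }, numeric(1)))
}

#' Per-pair mean absolute pixel change
#'
#' The mean over height, width and channels of the absolute difference
#' between consecutive frames.
#'
#' @param v a video with at least 2 frames.
#' @return A length-`T - 1` feature series.
#' @export
pixel_change <- function(v) {
  T <- n_frames(v)
  if (T < 2L) stop("pixel_change needs at least 2 frames")
  feature_series("pixel_change",
                 vapply(seq_len(T - 1L), function(t) {
                   mean(abs(get_frame(v, t + 1L) - get_frame(v, t)))
                 }, numeric(1)))
}

#' Optical-flow magnitude and angle series
#'
#' Dense optical flow between consecutive grayscaled frames, summarized per
#' frame pair by the arithmetic mean flow magnitude (pixels/frame) and mean
#' flow angle (radians in `[0, 2*pi)`; angle 0 is rightward motion, angles
#' increase toward downward motion). `circular_mean = TRUE` switches the
#' angle summary to the circular mean of the per-pixel angles.
#'
#' @param v a video with at least 2 frames.
#' @param params a [flow_params()] list.
#' @param circular_mean use the circular rather than arithmetic mean angle?
#' @return List with `magnitude` and `angle` feature series (length
#'   `T - 1`).
#' @export
optical_flow_stats <- function(v, params = flow_params(),
                               circular_mean = FALSE) {
  T <- n_frames(v)
  if (T < 2L) stop("optical flow needs at least 2 frames")
  C <- dim(v)[3]
  gray <- lapply(seq_len(T), function(t) {
    f <- get_frame(v, t)
    if (C == 3L) to_grayscale(f)[, , 1] else f[, , 1]
  })
  mags <- numeric(T - 1L)
  angs <- numeric(T - 1L)
  for (t in seq_len(T - 1L)) {
    fl <- optical_flow(gray[[t]], gray[[t + 1L]], params)
    mags[t] <- mean(sqrt(fl$dx^2 + fl$dy^2))
    a <- atan2(fl$dy, fl$dx) %% (2 * pi)
    angs[t] <- if (circular_mean) {
      atan2(mean(sin(a)), mean(cos(a))) %% (2 * pi)
    } else {
      mean(a)
    }
  }
  list(magnitude = feature_series("flow_magnitude", mags),
       angle = feature_series("flow_angle", angs))
}

#' Compare two feature series
#'
#' Pearson correlation coefficient and Euclidean distance between two
#' equal-length series. The PCC of a zero-variance series is undefined and
#' returned as `NA` with a warning.
#'
#' @param a,b numeric series of equal length (`>= 3` for the PCC).
#' @return List with `pcc` and `ed`.
#' @export
series_similarity <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("series length mismatch")
  ed <- sqrt(sum((a - b)^2))
  pcc <- NA_real_
  if (length(a) >= 3L) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance series: PCC undefined")
    } else {
      pcc <- stats::cor(a, b)
    }
  }
  list(pcc = pcc, ed = ed)
}

#' @keywords internal
color_histogram <- function(v, bins) {
  px <- matrix(aperm(unclass(v), c(1, 2, 4, 3)), ncol = 3)
  idx <- pmin(floor(px * bins), bins - 1L)
  lin <- 1L + idx[, 1] + bins * idx[, 2] + bins^2 * idx[, 3]
  tabulate(lin, nbins = bins^3)
}

#' KL divergence between the color distributions of two videos
#'
#' Pools all pixels of each RGB video into a `bins^3` joint color histogram
#' (additive smoothing `1e-9` before normalization) and returns
#' `KL(P_a || P_b)`.
#'
#' @param a,b RGB videos.
#' @param bins histogram bins per channel (default 16).
#' @return Non-negative scalar (nats).
#' @export
color_distribution_distance <- function(a, b, bins = 16L) {
  if (dim(a)[3] != 3L || dim(b)[3] != 3L) stop("RGB videos required")
  ha <- color_histogram(a, bins) + 1e-9
  hb <- color_histogram(b, bins) + 1e-9
  p <- ha / sum(ha)
  q <- hb / sum(hb)
  sum(p * log(p / q))
}

#' Color palette of a video
#'
#' The `k` dominant colors, computed by k-means clustering of all pooled
#' RGB pixels. With fewer distinct colors than `k` the missing centroids
#' are filled by duplicating existing ones.
#'
#' @param v an RGB video.
#' @param k number of palette colors (default 5).
#' @param seed integer seed for the k-means initialization.
#' @return A `k x 3` matrix of RGB centroids.
#' @export
video_palette <- function(v, k = 5L, seed = 1L) {
  px <- matrix(aperm(unclass(v), c(1, 2, 4, 3)), ncol = 3)
  ux <- unique(px)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (nrow(ux) <= k) {
    centers <- ux[rep_len(seq_len(nrow(ux)), k), , drop = FALSE]
    rownames(centers) <- NULL
    colnames(centers) <- c("R", "G", "B")
    return(centers)
  }
  km <- stats::kmeans(px, centers = k, nstart = 3L, iter.max = 50L)
  centers <- km$centers
  rownames(centers) <- NULL
  colnames(centers) <- c("R", "G", "B")
  centers
}

#' All low-level features of a video as a data frame
#'
#' Convenience wrapper computing intensity, contrast, pixel change and
#' optical-flow magnitude/angle; returns tidy columns `frame`, `feature`,
#' `value` (temporal features are indexed by the pair's second frame).
#'
#' @param v an RGB video.
#' @param params a [flow_params()] list.
#' @return A data frame.
#' @export
video_features <- function(v, params = flow_params()) {
  fl <- optical_flow_stats(v, params)
  T <- n_frames(v)
  rbind(
    data.frame(frame = seq_len(T), feature = "intensity",
               value = as.numeric(pixel_intensity(v))),
    data.frame(frame = seq_len(T), feature = "contrast",
               value = as.numeric(contrast(v))),
    data.frame(frame = 1L + seq_len(T - 1L), feature = "pixel_change",
               value = as.numeric(pixel_change(v))),
    data.frame(frame = 1L + seq_len(T - 1L), feature = "flow_magnitude",
               value = as.numeric(fl$magnitude)),
    data.frame(frame = 1L + seq_len(T - 1L), feature = "flow_angle",
               value = as.numeric(fl$angle))
  )
}
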