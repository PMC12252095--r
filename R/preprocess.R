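## Noise and background removal plus density reduction. These are the three
## standard cleaning steps applied to raw canopy scans before any geometry:
## a statistical distance filter for sensor noise, an axis interval filter
## for background, and voxel-grid downsampling for density.

#' Statistical outlier removal
#'
#' For each point the mean distance to its `k` nearest neighbours is
#' computed; points whose statistic exceeds the global mean plus
#' `std_ratio` standard deviations are removed. Output is a subset of the
#' input, in input order.
#'
#' @param cloud A point cloud.
#' @param k Neighbourhood size (excluding the point itself); must be < N.
#' @param std_ratio Spread multiplier of the rejection threshold.
#' @return Filtered point cloud.
#' @examples
#' pc <- point_cloud(matrix(runif(300), ncol = 3))
#' statistical_outlier_removal(pc, k = 10, std_ratio = 2)
#' @export
statistical_outlier_removal <- function(cloud, k = 20, std_ratio = 2) {
  cloud <- as_point_cloud(cloud)
  m <- as_xyz(cloud)
  n <- nrow(m)
  if (n <= k) stop("statistical_outlier_removal needs N > k (N = ", n,
                   ", k = ", k, ")", call. = FALSE)
  stopifnot(k >= 3, std_ratio > 0)
  nn <- RANN::nn2(m, m, k = k + 1L)
  mean_d <- rowMeans(nn$nn.dists[, -1L, drop = FALSE])
  thr <- mean(mean_d) + std_ratio * stats::sd(mean_d)
  keep <- which(mean_d <= thr)
  rebuild_cloud(m[keep, , drop = FALSE], cloud, keep)
}

#' Pass-through (axis interval) filter
#'
#' Keeps points whose coordinate on `axis` lies in the closed interval
#' `[min, max]`, preserving order. Used to crop away background behind the
#' plants.
#'
#' @param cloud A point cloud.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param min,max Interval bounds in mm, `min < max`.
#' @return Filtered point cloud.
#' @export
passthrough_filter <- function(cloud, axis = c("x", "y", "z"), min, max) {
  axis <- match.arg(axis)
  if (!(is.finite(min) && is.finite(max)) || min >= max) {
    stop("passthrough interval requires min < max", call. = FALSE)
  }
  cloud <- as_point_cloud(cloud)
  v <- cloud[[axis]]
  keep <- which(v >= min & v <= max)
  rebuild_cloud(as_xyz(cloud)[keep, , drop = FALSE], cloud, keep)
}

## Integer voxel keys on the origin-aligned lattice. Anchoring the grid on
## multiples of the voxel size (rather than the cloud's minimum corner) makes
## the filter exactly idempotent: centroids stay inside their cell, so a
## second pass reproduces the first.
voxel_keys <- function(m, voxel) {
  k <- floor(m / voxel)
  paste(k[, 1], k[, 2], k[, 3])
}

#' Voxel-grid downsampling
#'
#' Replaces all points falling in each occupied cell of an axis-aligned
#' cubic grid by their centroid. At most one output point per occupied
#' voxel; every output point lies within `voxel * sqrt(3) / 2` of an input
#' point.
#'
#' @param cloud A point cloud.
#' @param voxel Cell edge length (mm), > 0.
#' @return Downsampled point cloud (centroids, grouped in first-occurrence
#'   order of their voxel).
#' @export
voxel_downsample <- function(cloud, voxel = 1) {
  if (!is.numeric(voxel) || voxel <= 0) stop("voxel size must be > 0", call. = FALSE)
  cloud <- as_point_cloud(cloud)
  m <- as_xyz(cloud)
  if (nrow(m) == 0) return(cloud)
  key <- voxel_keys(m, voxel)
  fk <- factor(key, levels = unique(key))
  cnt <- as.vector(table(fk))
  cent <- rowsum(m, fk, reorder = FALSE) / cnt
  out <- rebuild_cloud(cent)
  if ("provenance" %in% names(cloud)) {
    ## a voxel is "observed" if it holds any observed point, else it keeps
    ## the smallest contributing mirror label
    out$provenance <- as.integer(tapply(cloud$provenance, fk, min))
  }
  out
}
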