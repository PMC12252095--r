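## Fruit isolation from mixed plant clouds: Euclidean clustering into
## connected components, PCA surface statistics (normals and curvature), and
## curvature-seeded region growing.

#' Euclidean clustering
#'
#' Connected components of the graph linking points closer than
#' `tolerance`. Components smaller than `min_size` are discarded; the rest
#' are returned as integer index vectors sorted by size, largest first.
#'
#' Neighbour search is kd-tree based; each point is linked to at most
#' `max_neighbours` neighbours within the tolerance, which gives the exact
#' component structure whenever local point counts within one tolerance
#' radius stay below that cap (transitivity supplies the rest).
#'
#' @param cloud A point cloud.
#' @param tolerance Link distance (mm), > 0.
#' @param min_size Minimum cluster size to report.
#' @param max_neighbours Per-point neighbour cap for the radius search.
#' @return List of integer vectors (row indices into `cloud`).
#' @export
euclidean_cluster <- function(cloud, tolerance, min_size = 1, max_neighbours = 64) {
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("tolerance must be > 0", call. = FALSE)
  }
  m <- as_xyz(cloud)
  n <- nrow(m)
  if (n == 0) return(list())
  k <- min(n, max_neighbours)
  nn <- RANN::nn2(m, m, k = k, searchtype = "radius", radius = tolerance)
  i <- rep(seq_len(n), k)
  j <- as.vector(nn$nn.idx)
  ## rows whose neighbour list saturated the cap may be missing links within
  ## the tolerance; re-query those exactly so components are always correct
  sat <- which(nn$nn.idx[, k] > 0L)
  if (length(sat) && k < n) {
    nn2_full <- RANN::nn2(m, m[sat, , drop = FALSE], k = n,
                          searchtype = "radius", radius = tolerance)
    i <- c(i, rep(sat, n))
    j <- c(j, as.vector(nn2_full$nn.idx))
  }
  ok <- j > 0 & j != i
  g <- igraph::graph_from_edgelist(cbind(i[ok], j[ok]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  idx <- split(seq_len(n), comp$membership)
  idx <- idx[order(lengths(idx), decreasing = TRUE)]
  unname(idx[lengths(idx) >= min_size])
}

#' Per-point surface statistics from PCA of local neighbourhoods
#'
#' For every point the covariance of its `k` nearest neighbours (plus
#' itself) is eigendecomposed. The normal is the eigenvector of the
#' smallest eigenvalue; the curvature is the surface-variation measure
#' `lambda_min / (lambda_1 + lambda_2 + lambda_3)`, which is 0 on a plane
#' and at most 1/3. Degenerate neighbourhoods (all points coincident) get
#' curvature 0 and are flagged unreliable.
#'
#' @param cloud A point cloud.
#' @param k Neighbourhood size, `3 <= k < N`.
#' @return A `surface_stats` tibble with columns `nx`, `ny`, `nz`,
#'   `curvature`, `reliable`; attribute `k`.
#' @export
estimate_surface_stats <- function(cloud, k = 20) {
  m <- as_xyz(cloud)
  n <- nrow(m)
  if (n <= k) stop("estimate_surface_stats needs N > k", call. = FALSE)
  stopifnot(k >= 3)
  nn <- RANN::nn2(m, m, k = k + 1L)
  normals <- matrix(0, n, 3)
  curv <- numeric(n)
  reliable <- rep(TRUE, n)
  for (i in seq_len(n)) {
    nb <- m[nn$nn.idx[i, ], , drop = FALSE]
    C <- stats::cov(nb)
    if (!all(is.finite(C)) || sum(diag(C)) < 1e-18) {
      normals[i, ] <- c(0, 0, 1)
      reliable[i] <- FALSE
      next
    }
    e <- eigen(C, symmetric = TRUE)
    normals[i, ] <- e$vectors[, 3]
    curv[i] <- max(0, e$values[3]) / sum(pmax(e$values, 0))
  }
  out <- tibble::tibble(nx = normals[, 1], ny = normals[, 2], nz = normals[, 3],
                        curvature = curv, reliable = reliable)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("surface_stats", class(out))
  out
}

#' Region growing from high-curvature seeds
#'
#' Seeds are the points above the `curvature_seed_quantile` of the
#' curvature distribution, visited in decreasing curvature order. A region
#' grows through the k-nearest-neighbour graph: an unassigned neighbour
#' joins when the angle between its normal and the current point's normal
#' is at most `smoothness_deg` and its curvature is within `curvature_tol`
#' of the region's originating seed. If the largest region ends up covering
#' less than `min_region_frac` of the non-planar points, both thresholds
#' are relaxed once by `relax_factor` and the growth is repeated.
#'
#' @param cloud A point cloud.
#' @param stats A [estimate_surface_stats()] result computed on `cloud`.
#' @param curvature_seed_quantile Seed quantile in (0, 1).
#' @param smoothness_deg Normal-angle threshold (degrees).
#' @param curvature_tol Curvature window around the region seed.
#' @param k Growth-graph neighbourhood (defaults to the stats neighbourhood).
#' @param min_region_frac,relax_factor Single-relaxation trigger and factor.
#' @return List of integer index vectors (disjoint regions, largest first).
#' @export
region_grow_fruit <- function(cloud, stats,
                              curvature_seed_quantile = 0.7,
                              smoothness_deg = 20,
                              curvature_tol = 0.08,
                              k = NULL,
                              min_region_frac = 0.3,
                              relax_factor = 1.5) {
  m <- as_xyz(cloud)
  n <- nrow(m)
  if (!inherits(stats, "surface_stats") || nrow(stats) != n) {
    stop("stats must be surface stats computed on the same cloud", call. = FALSE)
  }
  k <- k %||% attr(stats, "k")
  normals <- cbind(stats$nx, stats$ny, stats$nz)
  curv <- stats$curvature
  seeds <- which(curv >= stats::quantile(curv, curvature_seed_quantile))
  if (!length(seeds)) stop("empty seed set", call. = FALSE)
  nn_idx <- RANN::nn2(m, m, k = min(n, k + 1L))$nn.idx[, -1L, drop = FALSE]
  nonplanar <- sum(curv > 1e-3)

  grow <- function(smooth_deg, ctol) {
    cos_thr <- cos(smooth_deg * pi / 180)
    assigned <- rep(0L, n)
    regions <- list()
    ## start from the most typical of the high-curvature seeds: a window
    ## anchored at an extreme-curvature seed would exclude ordinary surface
    for (s in seeds[order(curv[seeds])]) {
      if (assigned[s]) next
      rid <- length(regions) + 1L
      seed_curv <- curv[s]
      queue <- s
      assigned[s] <- rid
      members <- s
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (q in nn_idx[p, ]) {
          if (assigned[q]) next
          if (abs(sum(normals[p, ] * normals[q, ])) < cos_thr) next
          if (abs(curv[q] - seed_curv) > ctol) next
          assigned[q] <- rid
          members <- c(members, q)
          queue <- c(queue, q)
        }
      }
      regions[[rid]] <- members
    }
    regions[order(lengths(regions), decreasing = TRUE)]
  }

  regions <- grow(smoothness_deg, curvature_tol)
  if (length(regions) && nonplanar > 0 &&
      length(regions[[1]]) < min_region_frac * nonplanar) {
    regions <- grow(smoothness_deg * relax_factor, curvature_tol * relax_factor)
  }
  regions
}
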