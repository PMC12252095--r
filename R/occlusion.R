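## Occlusion quantification: how much fruit surface is missing, and in
## which severity class. The rate is 1 - A_observed / A_complete, the
## missing fraction of surface area; classes follow the field convention of
## Low (<= 30%), Middle (30-50%] and High (50-70%].

#' Estimate the surface area of a point-sampled surface
#'
#' Local tangent-plane tessellation: each point's `k`-neighbourhood is
#' projected onto its PCA-fitted tangent plane and the point is credited
#' the area of its local Voronoi cell there (the cell of an interior point
#' is fully determined by its natural neighbours, so local cells tile the
#' sampled surface and their sum estimates the total area without a global
#' watertight mesh). Boundary points -- recognised by a large angular gap
#' among their projected neighbours, as in [extract_edge_contour()] -- have
#' unbounded Voronoi cells, and are credited one third of their incident
#' Delaunay-triangle area instead, so partial (occluded) surfaces are
#' handled naturally.
#'
#' @param cloud A point cloud with N >= 10, not all collinear.
#' @param k Local neighbourhood size.
#' @param boundary_gap_deg Angular gap (degrees) above which a point is
#'   treated as a surface-boundary point.
#' @return Estimated area in mm^2.
#' @examples
#' sph <- generate_fruit(fruit_spec(semi_axes = c(10, 10, 10), n_points = 2000))
#' estimate_surface_area(sph$cloud) # ~ 4 * pi * 100
#' @export
estimate_surface_area <- function(cloud, k = 15, boundary_gap_deg = 120) {
  m <- as_xyz(cloud)
  n <- nrow(m)
  if (n < 3) stop("estimate_surface_area needs at least 3 points", call. = FALSE)
  if (n == 3) return(triangle_area(m[1, ], m[2, ], m[3, ]))
  if (n < 10) stop("estimate_surface_area needs N >= 10 (or exactly 3)", call. = FALSE)
  sv <- svd(sweep(m, 2, colMeans(m)), nu = 0)
  if (sv$d[2] < 1e-9 * sv$d[1]) stop("degenerate geometry: points are collinear",
                                     call. = FALSE)
  k <- min(k, n - 1L)
  nn <- RANN::nn2(m, m, k = k + 1L)
  gap_thr <- boundary_gap_deg * pi / 180
  total <- 0
  for (i in seq_len(n)) {
    nb <- m[nn$nn.idx[i, ], , drop = FALSE]
    ctr <- colMeans(nb)
    rel <- sweep(nb, 2, ctr)
    ev <- eigen(crossprod(rel) / nrow(rel), symmetric = TRUE)
    uv <- rel %*% ev$vectors[, 1:2]
    du <- uv[-1, 1] - uv[1, 1]
    dv <- uv[-1, 2] - uv[1, 2]
    ang <- sort(atan2(dv, du))
    boundary <- max(diff(c(ang, ang[1] + 2 * pi))) >= gap_thr
    tm <- tryCatch(
      suppressWarnings(interp::tri.mesh(uv[, 1], uv[, 2], duplicate = "remove")),
      error = function(e) NULL)
    if (is.null(tm)) next
    tr <- interp::triangles(tm)[, 1:3, drop = FALSE]
    inc <- tr[rowSums(tr == 1L) > 0, , drop = FALSE]  # row 1 is point i
    if (!nrow(inc)) next
    if (!boundary) {
      ## interior point: its Voronoi cell is the polygon of circumcenters of
      ## its incident Delaunay triangles, ordered around the point
      cc <- vapply(seq_len(nrow(inc)), function(t) {
        circumcenter2(uv[inc[t, 1], ], uv[inc[t, 2], ], uv[inc[t, 3], ])
      }, numeric(2))
      if (!anyNA(cc)) {
        o <- order(atan2(cc[2, ] - uv[1, 2], cc[1, ] - uv[1, 1]))
        xs <- cc[1, o]; ys <- cc[2, o]
        total <- total + abs(sum(xs * c(ys[-1], ys[1]) -
                                   c(xs[-1], xs[1]) * ys)) / 2
        next
      }
    }
    ## boundary point (or degenerate circumcenter): a third of the incident
    ## Delaunay-triangle area
    a <- 0
    for (t in seq_len(nrow(inc))) {
      a <- a + triangle_area(nb[inc[t, 1], ], nb[inc[t, 2], ], nb[inc[t, 3], ])
    }
    total <- total + a / 3
  }
  total
}

## Circumcenter of a 2-D triangle; NA on degeneracy.
circumcenter2 <- function(A, B, C) {
  d <- 2 * (A[1] * (B[2] - C[2]) + B[1] * (C[2] - A[2]) + C[1] * (A[2] - B[2]))
  if (abs(d) < 1e-12) return(c(NA_real_, NA_real_))
  a2 <- sum(A^2); b2 <- sum(B^2); c2 <- sum(C^2)
  c((a2 * (B[2] - C[2]) + b2 * (C[2] - A[2]) + c2 * (A[2] - B[2])) / d,
    (a2 * (C[1] - B[1]) + b2 * (A[1] - C[1]) + c2 * (B[1] - A[1])) / d)
}

triangle_area <- function(p1, p2, p3) {
  0.5 * sqrt(sum(cross3(p2 - p1, p3 - p1)^2))
}

#' Occlusion rate from observed and complete surface areas
#'
#' `1 - a_observed / a_complete`, clamped into \[0, 1\]. An observed area
#' exceeding the complete area (possible with meshing jitter) is clamped to
#' rate 0 with a warning rather than treated as an error.
#'
#' @param a_observed Observed (partial) surface area, mm^2, >= 0.
#' @param a_complete Complete surface area, mm^2, > 0.
#' @return Occlusion rate in \[0, 1\].
#' @examples
#' occlusion_rate(30, 100) # 0.7
#' @export
occlusion_rate <- function(a_observed, a_complete) {
  if (!is.numeric(a_complete) || a_complete <= 0) {
    stop("a_complete must be > 0", call. = FALSE)
  }
  if (!is.numeric(a_observed) || a_observed < 0) {
    stop("a_observed must be >= 0", call. = FALSE)
  }
  if (a_observed > a_complete) {
    warning("observed area exceeds complete area; clamping occlusion rate to 0",
            call. = FALSE)
  }
  min(1, max(0, 1 - a_observed / a_complete))
}

#' Classify an occlusion rate into severity levels
#'
#' `rate <= 0.30` is Low, `0.30 < rate <= 0.50` Middle, `0.50 < rate <=
#' 0.70` High. Rates above 70% fall outside the calibrated range and are
#' labelled `"OutOfRange"`.
#'
#' @param rate Occlusion rate in \[0, 1\].
#' @return One of `"Low"`, `"Middle"`, `"High"`, `"OutOfRange"`.
#' @export
classify_occlusion <- function(rate) {
  if (!is.numeric(rate) || is.na(rate) || rate < 0 || rate > 1) {
    stop("rate must lie in [0, 1]", call. = FALSE)
  }
  if (rate <= 0.30) "Low"
  else if (rate <= 0.50) "Middle"
  else if (rate <= 0.70) "High"
  else "OutOfRange"
}

#' Occlusion report for an observed cloud against a complete reference
#'
#' @param observed,complete Point clouds (partial scan and complete
#'   reference).
#' @param k Neighbourhood size for [estimate_surface_area()].
#' @return A one-row tibble: `a_observed`, `a_complete`, `rate`, `level`.
#' @export
occlusion_report <- function(observed, complete, k = 15) {
  a_obs <- estimate_surface_area(observed, k = k)
  a_full <- estimate_surface_area(complete, k = k)
  rate <- occlusion_rate(a_obs, a_full)
  tibble::tibble(a_observed = a_obs, a_complete = a_full,
                 rate = rate, level = classify_occlusion(rate))
}
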