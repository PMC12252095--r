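## The symmetry core: locate the fruit's geometric centre by RANSAC
## ellipsoid fitting, initialise a candidate mirror plane from the principal
## axis of the cloud, and refine the plane until the cloud and its mirror
## image coincide. The refinement couples ICP alignment of the reflected
## cloud with a capped mirror-distance objective that accepts or rejects
## each proposed adjustment.

## ---- algebraic quadric / ellipsoid machinery -------------------------------

## Least-squares quadric through rows of m: coefficients q of
## a x^2 + b y^2 + c z^2 + d xy + e xz + f yz + g x + h y + i z + j = 0,
## ||q|| = 1 (smallest right singular vector of the design matrix).
quadric_fit <- function(m) {
  x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
  A <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z, 1)
  ## smallest right singular vector via the normal matrix: also yields the
  ## null-space solution for the minimal 9-point system
  eigen(crossprod(A), symmetric = TRUE)$vectors[, 10]
}

## Decode a quadric into ellipsoid parameters, or NULL when the quadric is
## not an ellipsoid (3x3 block not definite, or no real positive semi-axes).
quadric_to_ellipsoid <- function(q) {
  Q3 <- matrix(c(q[1], q[4] / 2, q[5] / 2,
                 q[4] / 2, q[2], q[6] / 2,
                 q[5] / 2, q[6] / 2, q[3]), 3, 3)
  ev <- eigen(Q3, symmetric = TRUE)
  if (all(ev$values < 0)) { ev$values <- -ev$values; q <- -q; Q3 <- -Q3 }
  if (any(ev$values <= 1e-12)) return(NULL)
  center <- tryCatch(as.vector(solve(Q3, -q[7:9] / 2)), error = function(e) NULL)
  if (is.null(center) || !all(is.finite(center))) return(NULL)
  rhs <- as.numeric(t(center) %*% Q3 %*% center) - q[10]
  if (rhs <= 0) return(NULL)
  semi <- sqrt(rhs / ev$values)
  ord <- order(semi, decreasing = TRUE)
  axes <- ev$vectors[, ord, drop = FALSE]
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  list(center = center, semi_axes = semi[ord], orientation = axes, q = q)
}

## First-order geometric distance |F(p)| / ||grad F(p)|| for quadric q.
quadric_distance <- function(q, m) {
  x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
  F <- q[1] * x^2 + q[2] * y^2 + q[3] * z^2 + q[4] * x * y + q[5] * x * z +
    q[6] * y * z + q[7] * x + q[8] * y + q[9] * z + q[10]
  gx <- 2 * q[1] * x + q[4] * y + q[5] * z + q[7]
  gy <- 2 * q[2] * y + q[4] * x + q[6] * z + q[8]
  gz <- 2 * q[3] * z + q[5] * x + q[6] * y + q[9]
  g <- sqrt(gx^2 + gy^2 + gz^2)
  abs(F) / pmax(g, 1e-12)
}

#' RANSAC ellipsoid fit
#'
#' Repeatedly fits the algebraic quadric through a minimal sample of 9
#' points, rejects non-ellipsoid quadrics, and counts inliers by a
#' first-order geometric distance gate. The final model is a least-squares
#' quadric refit on the best consensus set. Deterministic for a given
#' `seed`.
#'
#' @param cloud A point cloud with N >= 30.
#' @param iters Number of RANSAC hypotheses.
#' @param inlier_tol Inlier gate (mm) on the normalised algebraic distance.
#' @param seed Integer seed.
#' @return An `ellipsoid_model`: `center` (mm), `semi_axes` (mm, decreasing),
#'   `orientation` (columns = principal axes, det +1), `inlier_fraction`.
#' @export
fit_ellipsoid_ransac <- function(cloud, iters = 200, inlier_tol = 1.5, seed = 1L) {
  m <- as_xyz(cloud)
  n <- nrow(m)
  if (n < 30) stop("fit_ellipsoid_ransac needs N >= 30", call. = FALSE)
  stopifnot(iters >= 1, inlier_tol > 0)
  ## A quadric interpolating exactly 9 noisy surface points is rarely an
  ## ellipsoid itself, so hypotheses are scored by consensus regardless of
  ## type; ellipsoid validity is enforced on the consensus refit. The best
  ## ellipsoid-typed hypothesis is kept as a fallback consensus.
  best_any <- NULL; best_any_n <- -1L
  best_ell <- NULL; best_ell_n <- -1L
  with_seed(seed, {
    for (it in seq_len(iters)) {
      sub <- m[sample.int(n, 9L), , drop = FALSE]
      q <- tryCatch(quadric_fit(sub), error = function(e) NULL)
      if (is.null(q)) next
      ## local optimisation: an interpolating quadric through 9 noisy points
      ## is wild, so refit once on a wide-gate consensus before scoring
      wide <- quadric_distance(q, m) <= 3 * inlier_tol
      if (sum(wide) >= 20L) {
        q2 <- tryCatch(quadric_fit(m[wide, , drop = FALSE]),
                       error = function(e) NULL)
        if (!is.null(q2)) q <- q2
      }
      d <- quadric_distance(q, m)
      inl <- d <= inlier_tol
      ninl <- sum(inl)
      if (ninl > best_any_n) { best_any_n <- ninl; best_any <- inl }
      if (ninl > best_ell_n && !is.null(quadric_to_ellipsoid(q))) {
        best_ell_n <- ninl; best_ell <- inl
      }
    }
  })
  ## full-data fit as an additional hypothesis; keeps the noise-free case at
  ## the global least-squares optimum
  q_all <- quadric_fit(m)
  inl_all <- quadric_distance(q_all, m) <= inlier_tol
  candidates <- list(best_any, best_ell, inl_all)
  counts <- c(best_any_n, best_ell_n, sum(inl_all))
  fit <- NULL; used <- NA_integer_
  for (ci in order(counts, decreasing = TRUE)) {
    inl <- candidates[[ci]]
    if (is.null(inl) || counts[ci] < 9L) next
    f <- quadric_to_ellipsoid(quadric_fit(m[inl, , drop = FALSE]))
    if (!is.null(f)) { fit <- f; used <- ci; break }
  }
  if (is.null(fit)) {
    stop(sprintf(
      "no ellipsoidal consensus found after %d iterations (best inlier fraction %.2f)",
      iters, max(0, best_any_n) / n), call. = FALSE)
  }
  structure(list(center = fit$center,
                 semi_axes = fit$semi_axes,
                 orientation = fit$orientation,
                 inlier_fraction = counts[used] / n),
            class = "ellipsoid_model")
}

#' @export
print.ellipsoid_model <- function(x, ...) {
  cat(sprintf(
    "Ellipsoid: center (%.2f, %.2f, %.2f) mm, semi-axes %.2f/%.2f/%.2f mm, %.0f%% inliers\n",
    x$center[1], x$center[2], x$center[3],
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], 100 * x$inlier_fraction))
  invisible(x)
}

## ---- plane initialisation and elementary operations ------------------------

#' Initial symmetry plane from the principal axis
#'
#' Centres the cloud, eigendecomposes its covariance and takes the
#' eigenvector of the largest eigenvalue as the plane normal, anchored at
#' the supplied centre. Near-spherical clouds (eigenvalue ratio
#' `lambda1 / lambda2 < 1.05`) trigger a degeneracy warning because the
#' direction is then unstable -- though for a true sphere any plane through
#' the centre is a valid symmetry plane.
#'
#' @param cloud A point cloud with N >= 3, not all collinear.
#' @param center Anchor point (mm), typically the fitted ellipsoid centre.
#' @return A [plane()].
#' @export
initial_symmetry_plane <- function(cloud, center) {
  m <- as_xyz(cloud)
  if (nrow(m) < 3) stop("initial_symmetry_plane needs N >= 3", call. = FALSE)
  C <- stats::cov(m)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[2] < 1e-12 * e$values[1]) {
    stop("rank-deficient covariance: points are collinear", call. = FALSE)
  }
  if (e$values[1] / e$values[2] < 1.05) {
    warning("near-spherical cloud: principal direction is unstable",
            call. = FALSE)
  }
  plane(e$vectors[, 1], center)
}

#' Signed projection of points onto a plane normal
#'
#' `D = (p - anchor) . normal`: positive in the half-space the normal
#' points into, negative on the other side.
#'
#' @param points A point cloud, data frame, 3-column matrix, or single
#'   length-3 point.
#' @param plane A [plane()].
#' @return Numeric vector of signed distances (mm).
#' @export
signed_projection <- function(points, plane) {
  stopifnot(inherits(plane, "symmetry_plane"))
  if (is.numeric(points) && length(points) == 3L) points <- matrix(points, 1)
  m <- as_xyz(points)
  as.vector(sweep(m, 2, plane$anchor) %*% plane$normal)
}

#' Count points per half-space of a plane
#'
#' Points with `|D| <= eps` are counted as on-plane; the rest split into
#' the positive and negative half-spaces by the sign of their projection.
#' Counts always sum to N.
#'
#' @param cloud A point cloud.
#' @param plane A [plane()].
#' @param eps On-plane slab half-width (mm), >= 0.
#' @return A one-row tibble: `n_positive`, `n_negative`, `on_plane`.
#' @export
halfspace_split <- function(cloud, plane, eps = 0) {
  stopifnot(eps >= 0)
  d <- signed_projection(cloud, plane)
  on <- abs(d) <= eps
  tibble::tibble(n_positive = sum(d > 0 & !on),
                 n_negative = sum(d < 0 & !on),
                 on_plane = sum(on))
}

#' Reflect points across a plane
#'
#' `p -> p - 2 ((p - anchor) . n) n`: an isometric involution. Order is
#' preserved; normals, if present, are reflected too.
#'
#' @param cloud A point cloud.
#' @param plane A [plane()].
#' @return The mirrored point cloud.
#' @export
reflect_points <- function(cloud, plane) {
  m <- as_xyz(cloud)
  d <- signed_projection(m, plane)
  out_m <- m - 2 * outer(d, plane$normal)
  if (is.matrix(cloud)) return(out_m)
  out <- as_point_cloud(cloud)
  out$x <- out_m[, 1]; out$y <- out_m[, 2]; out$z <- out_m[, 3]
  if (has_normals(out)) {
    nm <- cbind(out$nx, out$ny, out$nz)
    nm <- nm - 2 * outer(as.vector(nm %*% plane$normal), plane$normal)
    out$nx <- nm[, 1]; out$ny <- nm[, 2]; out$nz <- nm[, 3]
  }
  out
}

#' Extract the edge contour of a partial surface
#'
#' For each point, its `k` neighbours are projected onto the local
#' least-squares tangent plane and sorted by polar angle around the point;
#' the point is an edge (boundary) point when the largest angular gap
#' between consecutive neighbours reaches `gap_angle_deg`. Interior points
#' of a well-sampled surface have gaps near `360 / k` degrees; points on a
#' hole boundary see an empty angular sector.
#'
#' @param cloud A point cloud with N > k.
#' @param k Neighbourhood size, >= 5.
#' @param gap_angle_deg Boundary gap threshold (degrees).
#' @param role Contour role tag, `"unmirrored"` or `"mirrored"`.
#' @return An integer vector of edge-point indices with class `contour` and
#'   attribute `role`.
#' @export
extract_edge_contour <- function(cloud, k = 20, gap_angle_deg = 120,
                                 role = c("unmirrored", "mirrored")) {
  role <- match.arg(role)
  m <- as_xyz(cloud)
  n <- nrow(m)
  if (n <= k) stop("extract_edge_contour needs N > k", call. = FALSE)
  stopifnot(k >= 5)
  nn_idx <- RANN::nn2(m, m, k = k + 1L)$nn.idx[, -1L, drop = FALSE]
  thr <- gap_angle_deg * pi / 180
  edge <- logical(n)
  for (i in seq_len(n)) {
    nb <- m[nn_idx[i, ], , drop = FALSE]
    rel_nb <- sweep(nb, 2, colMeans(nb))
    ev <- eigen(crossprod(rel_nb), symmetric = TRUE)
    u <- ev$vectors[, 1]; v <- ev$vectors[, 2]
    rel <- sweep(nb, 2, m[i, ])
    ang <- sort(atan2(rel %*% v, rel %*% u))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    edge[i] <- max(gaps) >= thr
  }
  structure(which(edge), class = "contour", role = role)
}

#' Point-to-point ICP with an annealed correspondence gate
#'
#' Classic iterative closest point: nearest-neighbour correspondences,
#' distance-gated by a declining schedule, followed by the closed-form SVD
#' rigid estimate each iteration. Iterations are split evenly over the
#' schedule entries so the gate tightens as the alignment improves; the
#' loop stops early when the gated RMS changes by less than `tol`.
#'
#' @param source,target Point clouds (non-empty).
#' @param max_iters Iteration cap.
#' @param tol Convergence tolerance on the RMS change (mm).
#' @param corr_schedule Declining correspondence gates (mm).
#' @return A [rigid_transform()] mapping `source` onto `target`, with
#'   attributes `iterations` and `rms`.
#' @export
icp_align <- function(source, target, max_iters = 80, tol = 1e-8,
                      corr_schedule = c(15, 8, 4, 2, 1)) {
  S <- as_xyz(source)
  T <- as_xyz(target)
  if (nrow(S) == 0 || nrow(T) == 0) stop("ICP inputs must be non-empty", call. = FALSE)
  stopifnot(max_iters >= 1, tol > 0, all(corr_schedule > 0))
  R <- diag(3); tt <- c(0, 0, 0)
  Sc <- S
  per <- ceiling(max_iters / length(corr_schedule))
  prev_rms <- Inf
  matched <- FALSE
  it <- 0L
  for (it in seq_len(max_iters)) {
    gate <- corr_schedule[min(length(corr_schedule), ceiling(it / per))]
    nn <- RANN::nn2(T, Sc, k = 1L)
    keep <- nn$nn.dists[, 1] <= gate
    if (sum(keep) < 3L) next
    matched <- TRUE
    est <- kabsch(Sc[keep, , drop = FALSE], T[nn$nn.idx[keep, 1], , drop = FALSE])
    Sc <- sweep(Sc %*% t(est$R), 2, est$t, `+`)
    R <- est$R %*% R
    tt <- as.vector(est$R %*% tt) + est$t
    rms <- sqrt(mean(nn$nn.dists[keep, 1]^2))
    if (abs(prev_rms - rms) < tol) { prev_rms <- rms; break }
    prev_rms <- rms
  }
  if (!matched) {
    stop("no ICP correspondences under the widest gate (",
         max(corr_schedule), " mm)", call. = FALSE)
  }
  out <- rigid_transform(R, tt)
  attr(out, "iterations") <- it
  attr(out, "rms") <- prev_rms
  out
}

#' Rotate a symmetry plane by an alignment result
#'
#' The refined normal is the ICP rotation applied to the initial normal,
#' renormalised; the anchor (the fitted centre) is unchanged.
#'
#' @param initial A [plane()].
#' @param transform A [rigid_transform()] from contour/mirror alignment.
#' @return The rotated [plane()].
#' @export
refine_plane <- function(initial, transform) {
  stopifnot(inherits(initial, "symmetry_plane"),
            inherits(transform, "rigid_transform"))
  plane(as.vector(transform$rotation %*% initial$normal), initial$anchor)
}

#' Angular error between two planes (or normals)
#'
#' `acos(|n_a . n_b|)` in degrees: sign-invariant, in \[0, 90\].
#'
#' @param a,b [plane()] objects or length-3 normals.
#' @return Angle in degrees.
#' @export
angular_error <- function(a, b) {
  na <- if (inherits(a, "symmetry_plane")) a$normal else unit3(as.numeric(a))
  nb <- if (inherits(b, "symmetry_plane")) b$normal else unit3(as.numeric(b))
  acos(min(1, abs(sum(na * nb)))) * 180 / pi
}

## ---- the adaptive self-matching loop ---------------------------------------

## Capped mirror-distance objective: RMS of nearest-neighbour distances
## between the cloud and its reflection, with each distance capped at a
## fixed multiple of the cloud's sampling spacing. Reflected points that
## fall into occlusion holes pay a constant penalty, so the objective
## rewards both matching more of the surface and matching it closely; a
## fixed (rather than quantile-adaptive) cap is essential because an
## adaptive one lets a badly oriented plane look good by re-weighting which
## points it must fit.
mirror_objective <- function(m, center, cap = NULL, max_query = 3000L) {
  force(m); force(center)
  qi <- stride_sample(nrow(m), max_query)   # query side subsampled for speed
  mq <- m[qi, , drop = FALSE]
  if (is.null(cap)) {
    spacing <- stats::median(RANN::nn2(m, mq, k = 2L)$nn.dists[, 2])
    cap <- max(3 * spacing, 2)
  }
  function(normal) {
    normal <- as.vector(normal)
    d0 <- as.vector(sweep(mq, 2, center) %*% normal)
    refl <- mq - 2 * outer(d0, normal)
    d <- RANN::nn2(m, refl, k = 1L)$nn.dists[, 1]
    sqrt(mean(pmin(d, cap)^2))
  }
}

## 2-D Nelder-Mead polish of a plane normal on the mirror objective,
## parameterised in the normal's tangent plane.
polish_normal <- function(Jfun, normal, maxit = 60) {
  B <- tangent_basis(normal)
  f <- function(ab) Jfun(unit3(as.vector(normal + B %*% ab)))
  o <- stats::optim(c(0, 0), f, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-4,
                                   parscale = c(0.03, 0.03)))
  list(normal = unit3(as.vector(normal + B %*% o$par)), value = o$value)
}

#' Find a fruit's symmetry plane by adaptive self-matching
#'
#' The full plane-detection pipeline: RANSAC ellipsoid fitting supplies the
#' geometric centre; PCA of the cloud supplies the initial normal; the
#' self-matching loop then mirrors the cloud across the candidate plane,
#' aligns the reflection back onto the original with gated ICP, and rotates
#' the plane by half of the recovered rotation (the composition of the true
#' and candidate reflections is a rotation by twice the plane error). Each
#' proposed adjustment is accepted only if a capped mirror-distance
#' objective improves, halving the step when it does not; the loop stops
#' when the incremental rotation falls below `loop_tol_deg` or after
#' `loop_max` iterations, and a final simplex polish of the normal runs on
#' the same objective. The polished PCA plane competes against the polished
#' ellipsoid major axis and the better mirror objective wins.
#'
#' Edge points (occlusion-hole boundaries, detected with
#' [extract_edge_contour()]) are excluded from the ICP source because their
#' reflections have no matching counterpart.
#'
#' @param cloud A fruit-level point cloud, N >= 50.
#' @param config A [pipeline_config()].
#' @return A [plane()] with attributes: `iterations`, `objective`,
#'   `ellipsoid` (the fitted model), `split` (final half-space counts),
#'   `warnings` (character).
#' @export
assm_find_plane <- function(cloud, config = pipeline_config()) {
  m <- as_xyz(cloud)
  if (nrow(m) < 50) stop("assm_find_plane needs N >= 50", call. = FALSE)
  warn <- character()
  ell <- fit_ellipsoid_ransac(cloud, iters = config$ransac_iters,
                              inlier_tol = config$ransac_inlier_tol,
                              seed = stage_seed(config$seed, "ransac-ellipsoid"))
  center <- ell$center
  p0 <- withCallingHandlers(
    initial_symmetry_plane(cloud, center),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  Jfun <- mirror_objective(m, center)
  n <- p0$normal
  Jcur <- Jfun(n)
  ## edge points excluded from the alignment source; a closed fruit surface
  ## has almost none, an occluded one has its hole boundaries flagged
  edges <- tryCatch(
    extract_edge_contour(cloud, k = config$contour_k,
                         gap_angle_deg = config$contour_gap_deg),
    error = function(e) integer())
  keep <- setdiff(seq_len(nrow(m)), as.integer(edges))
  src_idx <- keep[stride_sample(length(keep), 1500L)]
  iterations <- 0L
  for (it in seq_len(config$loop_max)) {
    iterations <- it
    pl <- plane(n, center)
    split <- halfspace_split(cloud, pl)
    src <- reflect_points(m[src_idx, , drop = FALSE], pl)
    est <- tryCatch(
      icp_align(src, m, max_iters = config$icp_max_iters, tol = config$icp_tol,
                corr_schedule = config$icp_corr_schedule),
      error = function(e) NULL)
    if (is.null(est)) {
      warn <- c(warn, sprintf("self-matching iteration %d: ICP found no correspondences", it))
      break
    }
    aa <- rotation_axis_angle(est$rotation)
    accepted <- FALSE
    for (frac in c(0.5, 0.25)) {
      cand <- unit3(as.vector(rotation_about(aa$axis, aa$angle * frac) %*% n))
      Jc <- Jfun(cand)
      if (Jc < Jcur) {
        n <- cand; Jcur <- Jc; accepted <- TRUE
        break
      }
    }
    if (!accepted) break
    if (aa$angle * 180 / pi < config$loop_tol_deg) break
  }
  po <- polish_normal(Jfun, n)
  ## alternative initialisation: the ellipsoid's major axis, same polish
  pe <- polish_normal(Jfun, ell$orientation[, 1])
  cands <- list(po, pe)
  ## For a clearly anisotropic fruit every principal plane is a mirror plane,
  ## so the objective alone cannot distinguish the fruit's symmetry axis from
  ## a perpendicular one; the fitted ellipsoid's major axis (robust to
  ## occlusion) anchors the choice. Near-spherical fits fall back to the
  ## objective alone.
  if (ell$semi_axes[1] / ell$semi_axes[2] >= 1.08) {
    aligned <- vapply(cands, function(cc) {
      angular_error(cc$normal, ell$orientation[, 1]) <= 45
    }, logical(1))
    if (any(aligned)) cands <- cands[aligned]
  }
  best <- cands[[which.min(vapply(cands, function(cc) cc$value, numeric(1)))]]
  n <- best$normal; Jcur <- best$value
  out <- plane(n, center)
  attr(out, "iterations") <- iterations
  attr(out, "objective") <- Jcur
  attr(out, "ellipsoid") <- ell
  attr(out, "split") <- halfspace_split(cloud, out)
  attr(out, "warnings") <- warn
  out
}
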