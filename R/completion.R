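## Triple-orthogonal symmetry system and multi-directional mirror
## completion: reflect the cloud across each plane of the system in turn,
## keep only reflected points that land in holes, seat each patch with a
## small ICP refinement, and fuse the result on a voxel grid.

#' Construct a symmetry system of three mutually orthogonal planes
#'
#' The second plane's normal is the direction of maximum variance of the
#' cloud projected into the primary plane; the third is the cross product
#' of the first two. All three share the primary plane's anchor (the fruit
#' centre), and the triad is right-handed.
#'
#' @param primary The refined primary [plane()].
#' @param cloud The fruit point cloud.
#' @return A `symmetry_system`: list of three [plane()]s plus the shared
#'   `anchor`.
#' @export
build_orthogonal_planes <- function(primary, cloud) {
  stopifnot(inherits(primary, "symmetry_plane"))
  m <- as_xyz(cloud)
  n1 <- primary$normal
  rel <- sweep(m, 2, primary$anchor)
  proj <- rel - outer(as.vector(rel %*% n1), n1)
  C <- stats::cov(proj)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[1] < 1e-12) {
    stop("projected cloud is rank-deficient; cannot build orthogonal planes",
         call. = FALSE)
  }
  n2 <- e$vectors[, 1]
  n2 <- unit3(n2 - sum(n2 * n1) * n1)   # exact orthogonality
  n3 <- unit3(cross3(n1, n2))
  symmetry_system(n1, n2, n3, primary$anchor)
}

symmetry_system <- function(n1, n2, n3, anchor) {
  structure(list(planes = list(plane(n1, anchor), plane(n2, anchor),
                               plane(n3, anchor)),
                 anchor = as.numeric(anchor)),
            class = "symmetry_system")
}

system_normals <- function(system) {
  vapply(system$planes, function(p) p$normal, numeric(3))
}

#' @export
print.symmetry_system <- function(x, ...) {
  N <- system_normals(x)
  cat("Triple-orthogonal symmetry system, anchor (",
      paste(sprintf("%.2f", x$anchor), collapse = ", "), ") mm\n", sep = "")
  for (i in 1:3) {
    cat(sprintf("  n%d = (%.4f, %.4f, %.4f)\n", i, N[1, i], N[2, i], N[3, i]))
  }
  invisible(x)
}

## Summed capped mirror objective over the three planes of a system.
system_objective <- function(m, center, cap = NULL) {
  Js <- mirror_objective(m, center, cap)
  function(B) Js(B[, 1]) + Js(B[, 2]) + Js(B[, 3])
}

#' Jointly refine a symmetry system over rigid rotations
#'
#' Rotates the whole orthogonal triad (three rotational degrees of freedom,
#' Nelder-Mead) to minimise the sum of the per-plane capped
#' mirror-distance objectives. Multiple starting triads can be supplied --
#' by default the input system and, when an ellipsoid model is given, the
#' ellipsoid's principal axes -- and the best final objective wins.
#' Orthogonality is preserved exactly because only rigid rotations of the
#' triad are searched.
#'
#' @param cloud The fruit point cloud.
#' @param system A [build_orthogonal_planes()] result.
#' @param ellipsoid Optional `ellipsoid_model` whose axes seed a second
#'   start.
#' @param cap Distance cap of the robust objective (mm); defaults to three
#'   median nearest-neighbour spacings.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return The refined `symmetry_system`, with attribute `objective`.
#' @export
refine_symmetry_system <- function(cloud, system, ellipsoid = NULL,
                                   cap = NULL, maxit = 200) {
  stopifnot(inherits(system, "symmetry_system"))
  m <- as_xyz(cloud)
  center0 <- system$anchor
  starts <- list(system_normals(system))
  if (!is.null(ellipsoid)) starts <- c(starts, list(ellipsoid$orientation))
  rot_of <- function(phi) {
    a <- sqrt(sum(phi^2))
    if (a < 1e-12) diag(3) else rotation_about(phi / a, a)
  }
  Jf <- system_objective(m, center0, cap)
  best <- NULL
  for (B0 in starts) {
    f <- function(phi) Jf(rot_of(phi) %*% B0)
    o <- stats::optim(c(0, 0, 0), f, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-5,
                                     parscale = rep(0.05, 3)))
    if (is.null(best) || o$value < best$value) {
      best <- list(B = rot_of(o$par) %*% B0, value = o$value)
    }
  }
  out <- symmetry_system(best$B[, 1], best$B[, 2], best$B[, 3], center0)
  attr(out, "objective") <- best$value
  out
}

#' Mirror-complete missing regions across a symmetry system
#'
#' For each plane in order, the current cloud is reflected; reflected
#' points whose nearest existing point is farther than `gap_threshold` are
#' hole fillers and are kept, the rest are redundant copies of observed
#' surface. Each kept patch is rigidly seated against the original points
#' within `3 * gap_threshold` of the patch by a small gated ICP (the seat
#' is rejected if it asks for an implausibly large correction). Later
#' planes see earlier fills, so multi-directional gaps close sequentially.
#' Original points are never moved or deleted; every appended point carries
#' its source plane (1-3) in the `provenance` column.
#'
#' @param cloud The occluded fruit cloud, N >= 50.
#' @param system A `symmetry_system`.
#' @param gap_threshold Hole-detection gate (mm); default 2 mm (= 2 x the
#'   default fusion voxel). Raised automatically to 1.5 times the
#'   cloud's 95th-percentile nearest-neighbour spacing when that is larger,
#'   so sparse but observed surface is never mistaken for a hole.
#' @param icp_opts Optional list overriding the patch-ICP controls
#'   (`max_iters`, `tol`, `corr_schedule`).
#' @return A point cloud with a `provenance` column (0 = original);
#'   attribute `already_complete` is `TRUE` when no plane contributed.
#' @export
mirror_complete <- function(cloud, system, gap_threshold = 2, icp_opts = list()) {
  stopifnot(inherits(system, "symmetry_system"), gap_threshold > 0)
  cloud <- as_point_cloud(cloud)
  m <- as_xyz(cloud)
  if (nrow(m) < 50) stop("mirror_complete needs N >= 50", call. = FALSE)
  ## hole detection must sit above the cloud's own sampling scale, or sparse
  ## but observed regions would be mistaken for holes
  spacing <- stats::quantile(RANN::nn2(m, m, k = 2L)$nn.dists[, 2], 0.95)
  gap_threshold <- max(gap_threshold, 1.5 * spacing)
  opts <- utils::modifyList(
    list(max_iters = 30, tol = 1e-8,
         corr_schedule = c(2 * gap_threshold, gap_threshold, gap_threshold / 2)),
    icp_opts)
  cur <- m
  prov <- rep(0L, nrow(m))
  ## two sweeps over the planes: the first fills the main holes; the second,
  ## with a reduced gate, closes the gate-wide erosion bands left along hole
  ## rims and regions whose mirror partner was itself filled late in the
  ## first sweep (compositions of the three mirrors)
  gates <- c(gap_threshold, max(gap_threshold / 2, 1.5 * stats::median(
    RANN::nn2(m, m, k = 2L)$nn.dists[, 2])))
  for (sweep_i in seq_along(gates)) {
    gate <- gates[sweep_i]
    for (pi in 1:3) {
      pl <- system$planes[[pi]]
      refl <- reflect_points(cur, pl)
      d <- RANN::nn2(cur, refl, k = 1L)$nn.dists[, 1]
      keep <- d > gate
      if (sweep_i > 1L) {
        ## the reduced gate only closes rims around first-sweep fills; on
        ## intact (merely sparse) surface it must not fire
        fills <- cur[prov > 0L, , drop = FALSE]
        if (nrow(fills) == 0L) break
        near_fill <- RANN::nn2(fills, refl, k = 1L)$nn.dists[, 1] <=
          3 * gap_threshold
        keep <- keep & near_fill
      }
      add <- refl[keep, , drop = FALSE]
      if (nrow(add) < 10L) next
      if (sweep_i == 1L) {
        ## seat the patch against the original boundary neighbourhood; the
        ## second sweep adds thin slivers for which a rigid fit is unstable
        near <- RANN::nn2(add, cur, k = 1L)$nn.dists[, 1] <= 3 * gap_threshold
        tgt <- cur[near, , drop = FALSE]
        if (nrow(tgt) >= 30L) {
          est <- tryCatch(
            icp_align(add, tgt, max_iters = opts$max_iters, tol = opts$tol,
                      corr_schedule = opts$corr_schedule),
            error = function(e) NULL)
          if (!is.null(est)) {
            ang <- rotation_axis_angle(est$rotation)$angle * 180 / pi
            shift <- sqrt(sum(est$translation^2))
            if (ang < 10 && shift < 2 * gap_threshold) {
              add <- apply_transform(est, add)
            }
          }
        }
      }
      cur <- rbind(cur, add)
      prov <- c(prov, rep.int(pi, nrow(add)))
    }
  }
  out <- rebuild_cloud(cur)
  out$provenance <- prov
  attr(out, "already_complete") <- all(prov == 0L)
  out
}

#' Fuse overlapping completed regions on a voxel grid
#'
#' Voxel-centroid fusion (the [voxel_downsample()] semantics) applied to
#' the union of original and mirrored points, deduplicating the overlapped
#' regions. A fused point is labelled as observed (provenance 0) whenever
#' any observed point contributed to its voxel.
#'
#' @param cloud A point cloud (typically a [mirror_complete()] result).
#' @param voxel Fusion cell edge (mm), > 0.
#' @return The fused point cloud.
#' @export
fuse_and_filter <- function(cloud, voxel = 1) {
  voxel_downsample(cloud, voxel)
}

#' Complete an occluded fruit cloud end to end
#'
#' Orchestrates [assm_find_plane()], [build_orthogonal_planes()],
#' [refine_symmetry_system()], [mirror_complete()] and [fuse_and_filter()].
#' Deterministic for a fixed `config$seed`.
#'
#' @param cloud The occluded fruit cloud.
#' @param config A [pipeline_config()].
#' @param report Also estimate surface areas of input and completed cloud
#'   and derive an occlusion report (costs one surface-area estimate per
#'   cloud; disable for large batch runs that only need geometry).
#' @return An `assm_completion` list: `cloud` (fused, with provenance),
#'   `system`, `plane`, `ellipsoid`, `n_input`, `n_added`, and `report`
#'   (one-row tibble, or `NULL`).
#' @export
assm_complete <- function(cloud, config = pipeline_config(), report = TRUE) {
  cloud <- as_point_cloud(cloud)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  pl <- stage("symmetry", assm_find_plane(cloud, config))
  ell <- attr(pl, "ellipsoid")
  sys0 <- stage("completion", build_orthogonal_planes(pl, cloud))
  sys <- stage("completion", refine_symmetry_system(cloud, sys0, ellipsoid = ell))
  filled <- stage("completion",
                  mirror_complete(cloud, sys, gap_threshold = config$gap_threshold))
  fused <- stage("completion", fuse_and_filter(filled, voxel = config$voxel))
  rep_tbl <- NULL
  if (report) {
    rep_tbl <- stage("evaluation", {
      a_obs <- estimate_surface_area(cloud)
      a_full <- estimate_surface_area(fused)
      rate <- suppressWarnings(occlusion_rate(a_obs, a_full))
      tibble::tibble(a_observed = a_obs, a_complete = a_full,
                     rate = rate, level = classify_occlusion(rate))
    })
  }
  structure(list(cloud = fused, system = sys, plane = pl, ellipsoid = ell,
                 n_input = nrow(cloud),
                 n_added = sum(filled$provenance > 0L),
                 report = rep_tbl),
            class = "assm_completion")
}

#' @export
print.assm_completion <- function(x, ...) {
  cat(sprintf(
    "ASSM completion: %d input points, %d mirrored fills, %d fused points\n",
    x$n_input, x$n_added, nrow(x$cloud)))
  if (!is.null(x$report)) {
    cat(sprintf("  estimated occlusion of input: %.1f%% (%s)\n",
                100 * x$report$rate, x$report$level))
  }
  invisible(x)
}
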