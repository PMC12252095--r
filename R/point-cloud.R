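#' Construct a point cloud
#'
#' A point cloud is a tibble with coordinate columns `x`, `y`, `z` in
#' millimetres, optionally per-point unit normals (`nx`, `ny`, `nz`), a
#' PCA surface-variation curvature column (`curvature`, dimensionless in
#' \[0, 1/3\]) and an integer `provenance` column written by the completion
#' stage (0 = observed point, 1-3 = filled by mirroring across the first,
#' second or third symmetry plane). All pipeline functions accept and return
#' this shape, so results compose with dplyr verbs and the pipe.
#'
#' @param x A matrix with 3 columns, or a data frame with at least `x`, `y`,
#'   `z` columns. Extra recognised columns (`nx`, `ny`, `nz`, `curvature`,
#'   `provenance`) are kept; anything else is dropped.
#' @param normals Optional N x 3 matrix of unit normals.
#' @param validate Check invariants (finite coordinates, unit normals).
#' @return A `point_cloud` tibble.
#' @examples
#' point_cloud(matrix(rnorm(30), ncol = 3))
#' @export
point_cloud <- function(x, normals = NULL, validate = TRUE) {
  if (is.data.frame(x)) {
    keep <- intersect(c("x", "y", "z", "nx", "ny", "nz", "curvature", "provenance"),
                      names(x))
    if (!all(c("x", "y", "z") %in% keep)) {
      stop("data frame must have columns x, y, z", call. = FALSE)
    }
    out <- tibble::as_tibble(x[keep])
  } else {
    m <- as_xyz(x)
    out <- tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  }
  if (!is.null(normals)) {
    normals <- as_xyz(normals)
    if (nrow(normals) != nrow(out)) stop("normals must match point count", call. = FALSE)
    out$nx <- normals[, 1]; out$ny <- normals[, 2]; out$nz <- normals[, 3]
  }
  out <- new_point_cloud(out)
  if (validate) validate_point_cloud(out)
  out
}

new_point_cloud <- function(df) {
  class(df) <- unique(c("point_cloud", class(tibble::as_tibble(df))))
  df
}

validate_point_cloud <- function(cloud) {
  m <- as_xyz(cloud)
  if (nrow(m) > 0 && !all(is.finite(m))) {
    stop("point cloud contains non-finite coordinates", call. = FALSE)
  }
  if (all(c("nx", "ny", "nz") %in% names(cloud)) && nrow(cloud) > 0) {
    nn <- sqrt(cloud$nx^2 + cloud$ny^2 + cloud$nz^2)
    if (any(abs(nn - 1) > 1e-6)) {
      stop("point normals must have unit length (within 1e-6)", call. = FALSE)
    }
  }
  invisible(cloud)
}

#' @rdname point_cloud
#' @export
as_point_cloud <- function(x) {
  if (inherits(x, "point_cloud")) return(x)
  point_cloud(x)
}

#' @rdname point_cloud
#' @param cloud A point cloud.
#' @export
cloud_matrix <- function(cloud) as_xyz(cloud)

## Rebuild a cloud tibble from a coordinate matrix, carrying over any
## per-point columns for the surviving row indices.
rebuild_cloud <- function(m, template = NULL, idx = NULL) {
  out <- tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  if (!is.null(template) && !is.null(idx)) {
    for (col in intersect(c("nx", "ny", "nz", "curvature", "provenance"),
                          names(template))) {
      out[[col]] <- template[[col]][idx]
    }
  }
  new_point_cloud(out)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("# Point cloud:", nrow(x), "points",
      if (all(c("nx", "ny", "nz") %in% names(x))) "(with normals)" else "",
      "\n")
  NextMethod()
}

#' Oriented plane (unit normal plus anchor point)
#'
#' `plane(n, c)` and `plane(-n, c)` denote the same geometric plane; every
#' consumer in the package is sign-invariant except [halfspace_split()],
#' which explicitly uses the orientation.
#'
#' @param normal Length-3 numeric, normalised internally; must be non-zero.
#' @param anchor Length-3 numeric point on the plane (mm).
#' @return A `symmetry_plane` object.
#' @examples
#' plane(c(0, 0, 2), c(0, 0, 0))
#' @export
plane <- function(normal, anchor = c(0, 0, 0)) {
  stopifnot(length(normal) == 3, length(anchor) == 3,
            all(is.finite(normal)), all(is.finite(anchor)))
  structure(list(normal = unit3(as.numeric(normal)),
                 anchor = as.numeric(anchor)),
            class = "symmetry_plane")
}

#' @export
print.symmetry_plane <- function(x, ...) {
  cat(sprintf("Symmetry plane: normal (%.4f, %.4f, %.4f), anchor (%.2f, %.2f, %.2f) mm\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$anchor[1], x$anchor[2], x$anchor[3]))
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1 within 1e-8).
#' @param translation Length-3 numeric (mm).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = unname(rotation),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a cloud or coordinate matrix
#'
#' @param transform A [rigid_transform()].
#' @param cloud A point cloud (normals, if present, are rotated too).
#' @return Transformed object of the same type.
#' @export
apply_transform <- function(transform, cloud) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- as_xyz(cloud)
  out <- sweep(m %*% t(transform$rotation), 2, transform$translation, `+`)
  if (is.matrix(cloud)) return(out)
  res <- as_point_cloud(cloud)
  res$x <- out[, 1]; res$y <- out[, 2]; res$z <- out[, 3]
  if (all(c("nx", "ny", "nz") %in% names(res))) {
    nm <- cbind(res$nx, res$ny, res$nz) %*% t(transform$rotation)
    res$nx <- nm[, 1]; res$ny <- nm[, 2]; res$nz <- nm[, 3]
  }
  res
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_axis_angle(x$rotation)
  cat(sprintf("Rigid transform: rotation %.3f deg, translation %.3f mm\n",
              aa$angle * 180 / pi, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of all stages. Every length is in
#' millimetres. The single `seed` drives all stochastic stages through
#' [stage_seed()].
#'
#' @param voxel Voxel edge for downsampling and fusion (mm).
#' @param sor_k,sor_std_ratio Statistical outlier removal neighbourhood and
#'   spread multiplier.
#' @param ransac_iters,ransac_inlier_tol RANSAC ellipsoid fitting controls
#'   (iterations; inlier gate on first-order geometric distance, mm).
#' @param contour_k,contour_gap_deg Edge-contour neighbourhood size and
#'   boundary angular-gap threshold (degrees).
#' @param icp_max_iters,icp_tol,icp_corr_schedule ICP iteration cap,
#'   convergence tolerance on the RMS change, and the declining
#'   correspondence-distance gates (mm).
#' @param loop_max,loop_tol_deg Self-matching outer-loop cap and convergence
#'   threshold on the incremental rotation (degrees).
#' @param gap_threshold Mirror-fill gate: reflected points closer than this
#'   to the existing surface are redundant (mm). Default 2 x voxel.
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config(seed = 7)
#' @export
pipeline_config <- function(voxel = 1,
                            sor_k = 20, sor_std_ratio = 2,
                            ransac_iters = 200, ransac_inlier_tol = 1.5,
                            contour_k = 20, contour_gap_deg = 120,
                            icp_max_iters = 80, icp_tol = 1e-8,
                            icp_corr_schedule = c(15, 8, 4, 2, 1),
                            loop_max = 10, loop_tol_deg = 0.5,
                            gap_threshold = 2 * voxel,
                            seed = 1L) {
  stopifnot(voxel > 0, sor_k >= 3, sor_std_ratio > 0,
            ransac_iters >= 1, ransac_inlier_tol > 0,
            contour_k >= 5, contour_gap_deg > 0,
            icp_max_iters >= 1, icp_tol > 0, all(icp_corr_schedule > 0),
            loop_max >= 1, loop_tol_deg > 0, gap_threshold > 0,
            is.numeric(seed), length(seed) == 1, seed == round(seed))
  structure(list(voxel = voxel, sor_k = as.integer(sor_k),
                 sor_std_ratio = sor_std_ratio,
                 ransac_iters = as.integer(ransac_iters),
                 ransac_inlier_tol = ransac_inlier_tol,
                 contour_k = as.integer(contour_k),
                 contour_gap_deg = contour_gap_deg,
                 icp_max_iters = as.integer(icp_max_iters),
                 icp_tol = icp_tol,
                 icp_corr_schedule = as.numeric(icp_corr_schedule),
                 loop_max = as.integer(loop_max),
                 loop_tol_deg = loop_tol_deg,
                 gap_threshold = gap_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}
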