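## Internal geometry and RNG helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Coerce a cloud-like object to a bare coordinate matrix
#'
#' Accepts a `point_cloud`, any data frame with `x`, `y`, `z` columns, or a
#' numeric matrix with three columns. Used at the top of every geometric
#' operation so the public API stays data-frame-first while the numerics run
#' on matrices.
#' @noRd
as_xyz <- function(cloud) {
  if (is.matrix(cloud)) {
    if (ncol(cloud) != 3L) stop("coordinate matrix must have 3 columns", call. = FALSE)
    storage.mode(cloud) <- "double"
    return(unname(cloud))
  }
  if (is.data.frame(cloud)) {
    if (!all(c("x", "y", "z") %in% names(cloud))) {
      stop("cloud data frame must have columns x, y, z", call. = FALSE)
    }
    return(unname(cbind(cloud$x, cloud$y, cloud$z)))
  }
  stop("cannot interpret object of class ", paste(class(cloud), collapse = "/"),
       " as a point cloud", call. = FALSE)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a near-zero vector", call. = FALSE)
  v / n
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Rodrigues rotation about a unit axis.
rotation_about <- function(axis, angle) {
  axis <- unit3(axis)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Axis/angle decomposition of a rotation matrix. For angles near 0 the axis
## is arbitrary and reported as +x.
rotation_axis_angle <- function(R) {
  tr <- (sum(diag(R)) - 1) / 2
  angle <- acos(max(-1, min(1, tr)))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- sqrt(sum(ax^2))
  list(axis = if (s > 1e-12) ax / s else c(1, 0, 0), angle = angle)
}

## Partial rotation: same axis, `frac` times the angle.
rotation_fraction <- function(R, frac) {
  aa <- rotation_axis_angle(R)
  if (aa$angle < 1e-12) return(diag(3))
  rotation_about(aa$axis, aa$angle * frac)
}

## Closed-form least-squares rigid alignment (Kabsch/Umeyama without scale):
## returns R, t with R %*% s + t ~ t for paired rows of S and T.
kabsch <- function(S, T) {
  cs <- colMeans(S)
  ct <- colMeans(T)
  H <- crossprod(sweep(S, 2, cs), sweep(T, 2, ct))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = ct - as.vector(R %*% cs))
}

## Orthonormal basis of the tangent plane of a unit vector.
tangent_basis <- function(n) {
  u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- unit3(u - sum(u * n) * n)
  cbind(t1, cross3(n, t1))
}

#' Derive a deterministic child seed for a named pipeline stage
#'
#' Every stochastic stage draws its randomness from a child seed computed
#' from the master seed and the stage name, so stages can be re-run in
#' isolation and still reproduce the full-pipeline result.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer in `[0, 2^31 - 2]`.
#' @examples
#' stage_seed(1, "ransac")
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483647), expr)
}

## Uniformly strided subsample of row indices (deterministic, order-stable).
stride_sample <- function(n, size) {
  if (n <= size) return(seq_len(n))
  unique(round(seq(1, n, length.out = size)))
}
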