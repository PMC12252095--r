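## Shared fixtures, all generated in code.

## Uniform samples on a sphere of radius r centred at `center`.
h_sphere_cloud <- function(n, r = 10, center = c(0, 0, 0), seed = 1, sigma = 0) {
  withr::with_seed(seed, {
    g <- matrix(stats::rnorm(3 * n), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    rad <- r + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
    point_cloud(sweep(g * rad, 2, center, `+`))
  })
}

## Regular planar grid in the z = z0 plane.
h_grid_cloud <- function(nx = 20, ny = 20, spacing = 1, z0 = 0) {
  g <- expand.grid(x = seq_len(nx) * spacing, y = seq_len(ny) * spacing)
  point_cloud(cbind(g$x, g$y, rep(z0, nrow(g))))
}

## Uniform samples of a full axis-aligned ellipsoid surface (area-exact via
## the generator).
h_ellipsoid_fruit <- function(semi = c(30, 25, 20), n = 3000, sigma = 0,
                              seed = 1, pose = rigid_transform()) {
  generate_fruit(fruit_spec(semi_axes = semi, eps = c(1, 1), pose = pose,
                            sigma = sigma, n_points = n, seed = seed))
}

## A quick standard occluded tomato-like fruit for pipeline-level tests.
h_occluded_fruit <- function(seed = 3, rate = 0.4, sigma = 0.3, n = 3500,
                             kind = "multi_patch") {
  fr <- generate_fruit(fruit_spec(semi_axes = c(35, 28, 25), sigma = sigma,
                                  n_points = n, seed = seed,
                                  pose = random_pose(seed)))
  occ <- apply_occlusion(fr$cloud, fr$truth,
                         occlusion_pattern(kind, rate, seed = seed + 100))
  list(cloud = occ$cloud, truth = fr$truth, achieved = occ$achieved_rate)
}

## Independent least-squares quadric -> ellipsoid oracle (no package code).
h_ellipsoid_oracle <- function(m) {
  x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
  A <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z, 1)
  q <- svd(A, nu = 0)$v[, 10]
  Q3 <- matrix(c(q[1], q[4] / 2, q[5] / 2,
                 q[4] / 2, q[2], q[6] / 2,
                 q[5] / 2, q[6] / 2, q[3]), 3, 3)
  ev <- eigen(Q3, symmetric = TRUE)
  if (all(ev$values < 0)) { ev$values <- -ev$values; q <- -q; Q3 <- -Q3 }
  center <- as.vector(solve(Q3, -q[7:9] / 2))
  k <- as.numeric(t(center) %*% Q3 %*% center) - q[10]
  semi <- sqrt(k / ev$values)
  ord <- order(semi, decreasing = TRUE)
  list(center = center, semi_axes = semi[ord])
}

## Exact two-sided signed-rank p-value by enumerating all sign patterns
## (valid for distinct |d|, n small).
h_signed_rank_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

## Angle (degrees) between two rotation matrices.
angular_error_rotation <- function(R1, R2) {
  R <- R1 %*% t(R2)
  tr <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, tr))) * 180 / pi
}

crossprod_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

## Build a symmetry system directly from a 3x3 matrix of axis columns.
symmetry_system_axes <- function(B, anchor) {
  symfruit:::symmetry_system(B[, 1], B[, 2], B[, 3], anchor)
}

## Quasi-uniform (Fibonacci lattice) sphere sampling: near-constant local
## neighbourhoods, so per-point curvature is tight around its true value.
h_fib_sphere <- function(n, r = 10, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  m <- r * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  point_cloud(sweep(m, 2, center, `+`))
}
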