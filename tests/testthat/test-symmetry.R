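test_that("RANSAC ellipsoid fitting matches the algebraic oracle", {
  fr <- h_ellipsoid_fruit(semi = c(30, 25, 20), n = 2000, sigma = 0, seed = 1)
  m <- cloud_matrix(fr$cloud)
  shifted <- point_cloud(sweep(m, 2, c(1, 2, 3), `+`))
  fit <- fit_ellipsoid_ransac(shifted, seed = 11)
  oracle <- h_ellipsoid_oracle(cloud_matrix(shifted))
  expect_lt(sqrt(sum((fit$center - oracle$center)^2)), 0.1)
  expect_lt(max(abs(fit$semi_axes / oracle$semi_axes - 1)), 0.01)
  expect_lt(max(abs(fit$semi_axes - c(30, 25, 20)) / c(30, 25, 20)), 0.01)

  sph <- h_ellipsoid_fruit(semi = c(18, 18, 18), n = 1500, seed = 2)
  fs <- fit_ellipsoid_ransac(sph$cloud, seed = 12)
  expect_lt(max(fs$semi_axes) / min(fs$semi_axes) - 1, 0.01)
})

test_that("RANSAC survives gross outliers", {
  fr <- h_ellipsoid_fruit(semi = c(30, 25, 20), n = 1500, sigma = 0.1, seed = 3)
  m <- cloud_matrix(fr$cloud)
  out <- withr::with_seed(4, {
    g <- matrix(stats::rnorm(3 * 300), ncol = 3)
    90 * g / sqrt(rowSums(g^2))    # 3x the major radius
  })
  mixed <- point_cloud(rbind(m, out))
  fit <- fit_ellipsoid_ransac(mixed, iters = 300, inlier_tol = 1, seed = 13)
  oracle <- h_ellipsoid_oracle(m)        # inlier-only oracle
  expect_lt(sqrt(sum((fit$center - oracle$center)^2)), 0.5)
  expect_error(fit_ellipsoid_ransac(point_cloud(m[1:20, ])), "N >= 30")
})

test_that("initial plane is the covariance principal axis, equivariantly", {
  fr <- h_ellipsoid_fruit(semi = c(40, 22, 22), n = 2000, seed = 5)
  p <- initial_symmetry_plane(fr$cloud, fr$truth$center)
  e <- eigen(stats::cov(cloud_matrix(fr$cloud)), symmetric = TRUE) # oracle
  expect_lt(angular_error(p$normal, e$vectors[, 1]), 1e-6)
  expect_lt(angular_error(p, plane(c(1, 0, 0))), 1)

  tr <- random_pose(21)
  p2 <- initial_symmetry_plane(apply_transform(tr, fr$cloud),
                               as.vector(tr$rotation %*% fr$truth$center) +
                                 tr$translation)
  expect_lt(angular_error(p2$normal, as.vector(tr$rotation %*% p$normal)), 1)

  sph <- h_fib_sphere(2000, r = 15)
  expect_warning(initial_symmetry_plane(sph, c(0, 0, 0)), "near-spherical")
})

test_that("signed projection and half-space counts follow their definitions", {
  pl <- plane(c(0, 0, 1), c(0, 0, 0))
  expect_equal(signed_projection(c(1, 2, 3), pl), 3)
  expect_equal(signed_projection(pl$anchor, pl), 0)

  cl <- h_sphere_cloud(500, r = 10, seed = 7)
  pl2 <- plane(c(1, 2, -1), c(0.3, -0.2, 0.1))
  d <- signed_projection(cl, pl2)
  ## brute-force per-point evaluation
  nrm <- pl2$normal
  d_oracle <- apply(cloud_matrix(cl), 1,
                    function(p) sum((p - pl2$anchor) * nrm))
  expect_equal(d, unname(d_oracle))
  hs <- halfspace_split(cl, pl2)
  expect_equal(hs$n_positive, sum(d_oracle > 0))
  expect_equal(hs$n_negative, sum(d_oracle < 0))
  expect_equal(hs$n_positive + hs$n_negative + hs$on_plane, nrow(cl))

  five <- point_cloud(cbind(0, 0, 1:5))
  hs5 <- halfspace_split(five, plane(c(0, 0, 1), c(0, 0, 0)))
  expect_equal(unlist(hs5), c(n_positive = 5, n_negative = 0, on_plane = 0))

  ## a mirror-symmetric cloud splits evenly
  sym <- point_cloud(rbind(cbind(1:50, 0, 0), cbind(-(1:50), 0, 0)))
  hsym <- halfspace_split(sym, plane(c(1, 0, 0), c(0, 0, 0)))
  expect_equal(hsym$n_positive, hsym$n_negative)
})

test_that("reflection is an isometric involution", {
  pl <- plane(c(1, 0, 0), c(0, 0, 0))
  expect_equal(cloud_matrix(reflect_points(point_cloud(rbind(c(1, 0, 0))), pl)),
               rbind(c(-1, 0, 0)))
  cl <- h_sphere_cloud(50, r = 8, seed = 8, sigma = 1)
  pl2 <- plane(c(1, -2, 0.5), c(1, 1, -1))
  twice <- reflect_points(reflect_points(cl, pl2), pl2)
  expect_lt(max(abs(cloud_matrix(twice) - cloud_matrix(cl))), 1e-9)
  refl <- reflect_points(cl, pl2)
  expect_lt(max(abs(stats::dist(cloud_matrix(refl)) -
                      stats::dist(cloud_matrix(cl)))), 1e-9)
  ## projection antisymmetry
  expect_equal(signed_projection(refl, pl2), -signed_projection(cl, pl2))
})

test_that("edge contour flags boundaries and not interiors", {
  g <- h_grid_cloud(20, 20, spacing = 1)
  ec <- extract_edge_contour(g, k = 8, gap_angle_deg = 120)
  m <- cloud_matrix(g)
  interior <- which(m[, 1] > 5 & m[, 1] < 15 & m[, 2] > 5 & m[, 2] < 15)
  expect_length(intersect(as.integer(ec), interior), 0)
  corner <- which(m[, 1] == 1 & m[, 2] == 1)
  expect_true(corner %in% as.integer(ec))

  ## independent neighbour/angle oracle at the corner
  k <- 8
  D <- as.matrix(stats::dist(m))
  nb <- m[order(D[corner, ])[2:(k + 1)], ]
  ctr <- colMeans(nb)
  ev <- eigen(crossprod(sweep(nb, 2, ctr)), symmetric = TRUE)
  rel <- sweep(nb, 2, m[corner, ])
  ang <- sort(atan2(rel %*% ev$vectors[, 2], rel %*% ev$vectors[, 1]))
  gap <- max(diff(c(ang, ang[1] + 2 * pi))) * 180 / pi
  expect_gte(gap, 120)

  sph <- h_fib_sphere(2000, r = 15)
  ec_s <- extract_edge_contour(sph, k = 20, gap_angle_deg = 120)
  expect_lt(length(ec_s) / nrow(sph), 0.01)
  expect_error(extract_edge_contour(g[1:5, ], k = 8), "N > k")
})

test_that("ICP recovers known rigid motions", {
  src <- h_ellipsoid_fruit(semi = c(30, 24, 20), n = 1200, seed = 10)$cloud
  est0 <- icp_align(src, src)
  expect_lt(rotation_axis_angle(est0$rotation)$angle * 180 / pi, 0.01)
  expect_lt(sqrt(sum(est0$translation^2)), 1e-4)

  R <- rotation_about(c(0, 0, 1), 5 * pi / 180)
  tr <- rigid_transform(R, c(1, 2, 0))
  tgt <- apply_transform(tr, src)
  est <- icp_align(src, tgt)
  expect_lt(angular_error_rotation(est$rotation, R), 0.5)
  expect_lt(sqrt(sum((est$translation - tr$translation)^2)), 0.1)

  ## partial overlap: 30% of source deleted
  part <- point_cloud(cloud_matrix(src)[-sample(seq_len(1200), 360), ])
  est2 <- icp_align(part, tgt)
  expect_lt(angular_error_rotation(est2$rotation, R), 1)

  expect_error(icp_align(point_cloud(matrix(numeric(0), ncol = 3)), src),
               "non-empty")
})

test_that("refine_plane applies the alignment rotation to the normal", {
  p <- plane(c(1, 0, 0), c(2, 2, 2))
  expect_equal(refine_plane(p, rigid_transform())$normal, p$normal)
  r90 <- rigid_transform(rotation_about(c(0, 0, 1), pi / 2))
  expect_lt(angular_error(refine_plane(p, r90)$normal, c(0, 1, 0)), 1e-9)
  expect_equal(refine_plane(p, r90)$anchor, p$anchor)
  for (s in 1:5) {
    rr <- random_pose(s)
    n2 <- refine_plane(p, rigid_transform(rr$rotation))$normal
    expect_equal(sqrt(sum(n2^2)), 1, tolerance = 1e-12)
  }
})

test_that("angular error is a sign-invariant plane metric", {
  a <- plane(c(1, 0, 0)); b <- plane(c(0, 1, 0))
  expect_equal(angular_error(a, a), 0)
  expect_equal(angular_error(a, plane(-a$normal)), 0)
  expect_equal(angular_error(a, b), 90)
})

test_that("assm_find_plane recovers the symmetry plane of synthetic fruit", {
  ## noise-free complete fruit: initial plane already optimal, tiny error
  fr <- generate_fruit(fruit_spec(semi_axes = c(36, 28, 25), sigma = 0,
                                  n_points = 3000, seed = 14,
                                  pose = random_pose(14)))
  cfg <- pipeline_config(seed = 14)
  p <- assm_find_plane(fr$cloud, cfg)
  expect_lt(angular_error(p, plane(fr$truth$normal)), 1)

  ## exactly mirror-symmetric cloud (half plus its reflection): the
  ## refinement has nothing to correct and the plane is recovered sharply
  m <- cloud_matrix(fr$cloud)
  d <- signed_projection(fr$cloud, plane(fr$truth$normal, fr$truth$center))
  half <- m[d > 0, , drop = FALSE]
  sym <- point_cloud(rbind(half, cloud_matrix(
    reflect_points(point_cloud(half), plane(fr$truth$normal, fr$truth$center)))))
  psym <- assm_find_plane(sym, cfg)
  expect_lt(angular_error(psym, plane(fr$truth$normal)), 0.5)

  ## 30% cap occlusion with 0.5 mm noise
  fr2 <- generate_fruit(fruit_spec(semi_axes = c(36, 28, 25), sigma = 0.5,
                                   n_points = 4000, seed = 15,
                                   pose = random_pose(15)))
  occ <- apply_occlusion(fr2$cloud, fr2$truth,
                         occlusion_pattern("cap", 0.30, seed = 16))
  p2 <- assm_find_plane(occ$cloud, pipeline_config(seed = 15))
  expect_lt(angular_error(p2, plane(fr2$truth$normal)), 5)

  ## sphere: degeneracy warning propagated in the result
  sph <- h_fib_sphere(3000, r = 15)
  ps <- assm_find_plane(sph, pipeline_config(seed = 16))
  expect_true(any(grepl("near-spherical", attr(ps, "warnings"))))
})

test_that("assm_find_plane is rigid-motion equivariant", {
  fr <- generate_fruit(fruit_spec(semi_axes = c(34, 27, 24), sigma = 0.3,
                                  n_points = 3000, seed = 17))
  occ <- apply_occlusion(fr$cloud, fr$truth,
                         occlusion_pattern("cap", 0.15, seed = 18))
  cfg <- pipeline_config(seed = 17)
  p1 <- assm_find_plane(occ$cloud, cfg)
  tr <- random_pose(19)
  p2 <- assm_find_plane(apply_transform(tr, occ$cloud), cfg)
  expect_lt(angular_error(p2$normal, as.vector(tr$rotation %*% p1$normal)), 1)
})
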