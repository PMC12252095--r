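test_that("orthogonal plane construction aligns with the principal axes", {
  fr <- h_ellipsoid_fruit(semi = c(30, 25, 20), n = 8000, seed = 1)
  primary <- plane(c(1, 0, 0), fr$truth$center)
  sys <- build_orthogonal_planes(primary, fr$cloud)
  N <- vapply(sys$planes, function(p) p$normal, numeric(3))
  expect_lt(angular_error(N[, 2], c(0, 1, 0)), 1)
  expect_lt(angular_error(N[, 3], c(0, 0, 1)), 1)
  ## exact agreement with the projected-covariance oracle
  m <- cloud_matrix(fr$cloud)
  rel <- sweep(m, 2, fr$truth$center)
  proj <- rel - outer(as.vector(rel %*% c(1, 0, 0)), c(1, 0, 0))
  ev <- eigen(stats::cov(proj), symmetric = TRUE)
  expect_lt(angular_error(N[, 2], ev$vectors[, 1]), 1e-6)
  ## orthogonality and right-handedness on random inputs
  for (s in 1:5) {
    cl <- h_ellipsoid_fruit(semi = c(33, 26, 22), n = 800, seed = s,
                            pose = random_pose(s))$cloud
    pr <- plane(withr::with_seed(s, stats::rnorm(3)), colMeans(cloud_matrix(cl)))
    sy <- build_orthogonal_planes(pr, cl)
    M <- vapply(sy$planes, function(p) p$normal, numeric(3))
    dots <- abs(c(sum(M[, 1] * M[, 2]), sum(M[, 1] * M[, 3]),
                  sum(M[, 2] * M[, 3])))
    expect_lt(max(dots), 1e-6)
    expect_gt(sum(crossprod_vec(M[, 1], M[, 2]) * M[, 3]), 0)
  }
})

test_that("joint system refinement preserves orthogonality and helps", {
  h <- h_occluded_fruit(seed = 21, rate = 0.35)
  ell <- fit_ellipsoid_ransac(h$cloud, seed = 21)
  primary <- assm_find_plane(h$cloud, pipeline_config(seed = 21))
  sys0 <- build_orthogonal_planes(primary, h$cloud)
  sys <- refine_symmetry_system(h$cloud, sys0, ellipsoid = ell)
  M <- vapply(sys$planes, function(p) p$normal, numeric(3))
  expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
  expect_lte(attr(sys, "objective"),
             sum(vapply(1:3, function(i) {
               J <- symfruit:::mirror_objective(cloud_matrix(h$cloud), sys0$anchor)
               J(vapply(sys0$planes, function(p) p$normal, numeric(3))[, i])
             }, numeric(1))) + 1e-9)
})

test_that("mirror completion restores a half-cut ellipsoid", {
  fr <- h_ellipsoid_fruit(semi = c(30, 25, 20), n = 4000, sigma = 0, seed = 2)
  m <- cloud_matrix(fr$cloud)
  half <- point_cloud(m[m[, 1] <= 0, ])     # cut exactly at the primary plane
  sys <- symmetry_system_axes(diag(3), fr$truth$center)
  comp <- mirror_complete(half, sys, gap_threshold = 2)
  expect_false(attr(comp, "already_complete"))
  dims <- measure_dimensions(comp, sys)
  expect_lt(max(abs(unlist(dims) - fr$truth$dimensions) / fr$truth$dimensions),
            0.02)
  ## original evidence never moved: first rows equal the input
  expect_equal(cloud_matrix(comp)[seq_len(nrow(half)), ], cloud_matrix(half),
               ignore_attr = TRUE)

  full <- mirror_complete(fr$cloud, sys, gap_threshold = 2)
  expect_lt(sum(full$provenance > 0) / nrow(full), 0.01)
})

test_that("voxel fusion deduplicates and stays near the input", {
  fr <- h_ellipsoid_fruit(semi = c(25, 22, 20), n = 1500, seed = 3)
  m <- cloud_matrix(fr$cloud)
  doubled <- point_cloud(rbind(m, m))
  fused <- fuse_and_filter(doubled, voxel = 1)
  expect_equal(nrow(fused), nrow(fuse_and_filter(fr$cloud, voxel = 1)))
  d <- RANN::nn2(m, cloud_matrix(fused), k = 1)$nn.dists[, 1]
  expect_true(all(d <= sqrt(3) / 2 + 1e-12))
  expect_identical(cloud_matrix(fuse_and_filter(fused, voxel = 1)),
                   cloud_matrix(fused))
})

test_that("assm_complete restores dimensions and is deterministic", {
  fr <- generate_fruit(fruit_spec(semi_axes = c(34, 27, 24), sigma = 0.2,
                                  n_points = 4000, seed = 7,
                                  pose = random_pose(7)))
  occ <- apply_occlusion(fr$cloud, fr$truth,
                         occlusion_pattern("multi_patch", 0.5, seed = 7))
  cfg <- pipeline_config(seed = 7)
  res <- assm_complete(occ$cloud, cfg, report = FALSE)
  dims <- measure_dimensions(res$cloud, res$system)
  expect_lt(max(abs(unlist(dims) - fr$truth$dimensions) / fr$truth$dimensions),
            0.03)
  ## repeat run: identical output
  res2 <- assm_complete(occ$cloud, cfg, report = FALSE)
  expect_identical(cloud_matrix(res$cloud), cloud_matrix(res2$cloud))
  expect_identical(res$cloud$provenance, res2$cloud$provenance)
})

test_that("completing an unoccluded fruit changes almost nothing", {
  fr <- generate_fruit(fruit_spec(semi_axes = c(32, 26, 23), sigma = 0.2,
                                  n_points = 3000, seed = 8))
  cfg <- pipeline_config(seed = 8)
  res <- assm_complete(fr$cloud, cfg, report = FALSE)
  base <- fuse_and_filter(fr$cloud, cfg$voxel)
  expect_lt(abs(nrow(res$cloud) - nrow(base)) / nrow(base), 0.02)
  expect_lt(sum(res$cloud$provenance > 0) / nrow(res$cloud), 0.02)
})

test_that("completion invariants hold on generator fixtures", {
  h <- h_occluded_fruit(seed = 31, rate = 0.45, sigma = 0.2, n = 8000)
  cfg <- pipeline_config(seed = 31)
  ## preprocessed as the pipeline would: strays removed, density normalised
  cl_in <- voxel_downsample(
    statistical_outlier_removal(h$cloud, cfg$sor_k, cfg$sor_std_ratio),
    cfg$voxel)
  res <- assm_complete(cl_in, cfg, report = FALSE)
  m <- cloud_matrix(res$cloud)
  ## post-completion symmetry: one-sided Hausdorff to each reflection
  for (pl in res$system$planes) {
    refl <- cloud_matrix(reflect_points(res$cloud, pl))
    dh <- max(RANN::nn2(m, refl, k = 1)$nn.dists[, 1])
    expect_lt(dh, 2 * cfg$voxel)
  }
  ## occlusion monotonicity against the generator's complete area
  a_in <- estimate_surface_area(cl_in)
  a_out <- estimate_surface_area(res$cloud)
  r_in <- suppressWarnings(occlusion_rate(a_in, h$truth$area))
  r_out <- suppressWarnings(occlusion_rate(a_out, h$truth$area))
  expect_lte(r_out, r_in)
  ## every input point is represented: its fusion voxel has an output point
  ## within one voxel diagonal
  d <- RANN::nn2(m, cloud_matrix(cl_in), k = 1)$nn.dists[, 1]
  expect_true(all(d <= cfg$voxel * sqrt(3) + 1e-9))
})

test_that("heavy multi-patch occlusion is substantially filled", {
  fr <- generate_fruit(fruit_spec(semi_axes = c(35, 28, 25), sigma = 0.2,
                                  n_points = 5000, seed = 9,
                                  pose = random_pose(9)))
  occ <- apply_occlusion(fr$cloud, fr$truth,
                         occlusion_pattern("multi_patch", 0.68, seed = 9))
  res <- assm_complete(occ$cloud, pipeline_config(seed = 9), report = FALSE)
  ## generator-side oracle: fraction of true surface area farther than 2 mm
  ## from the cloud, before and after completion
  ctr <- fr$truth$mesh_centroids
  w <- fr$truth$mesh_areas / sum(fr$truth$mesh_areas)
  miss_in <- sum(w[RANN::nn2(cloud_matrix(occ$cloud), ctr,
                             k = 1)$nn.dists[, 1] > 2])
  miss_out <- sum(w[RANN::nn2(cloud_matrix(res$cloud), ctr,
                              k = 1)$nn.dists[, 1] > 2])
  expect_gt(miss_in, 0.6)
  expect_lt(miss_out, 0.05)
})
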