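test_that("euclidean clustering matches a union-find oracle", {
  s1 <- h_sphere_cloud(150, r = 1, center = c(0, 0, 0), seed = 1)
  s2 <- h_sphere_cloud(120, r = 1, center = c(100, 0, 0), seed = 2)
  cl <- point_cloud(rbind(cloud_matrix(s1), cloud_matrix(s2)))
  expect_length(euclidean_cluster(cl, tolerance = 5), 2)
  expect_length(euclidean_cluster(cl, tolerance = 200), 1)

  rnd <- h_sphere_cloud(300, r = 15, seed = 7, sigma = 4)
  tol <- 2.5
  got <- euclidean_cluster(rnd, tolerance = tol)
  ## brute-force union-find over the full pairwise distance matrix
  D <- as.matrix(stats::dist(cloud_matrix(rnd)))
  parent <- seq_len(nrow(D))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(D))) for (j in which(D[i, ] <= tol)) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(nrow(D)), find, integer(1))
  oracle <- unname(split(seq_len(nrow(D)), roots))
  oracle <- oracle[order(lengths(oracle), decreasing = TRUE)]
  canon <- function(part) lapply(part, sort)
  expect_setequal(canon(got), canon(oracle))
})

test_that("clustering partition is invariant under rigid motion", {
  rnd <- h_sphere_cloud(200, r = 12, seed = 3, sigma = 3)
  tr <- random_pose(11)
  a <- euclidean_cluster(rnd, tolerance = 2)
  b <- euclidean_cluster(apply_transform(tr, rnd), tolerance = 2)
  expect_setequal(lapply(a, sort), lapply(b, sort))
})

test_that("surface stats recover plane normals and flat curvature", {
  g <- h_grid_cloud(15, 15, spacing = 1)
  st <- estimate_surface_stats(g, k = 8)
  expect_true(all(st$curvature < 1e-3))
  expect_true(all(abs(abs(st$nz) - 1) < 1e-6))
  expect_error(estimate_surface_stats(g[1:5, ], k = 8), "N > k")
})

test_that("surface stats agree with a brute-force eigendecomposition", {
  rnd <- h_sphere_cloud(50, r = 10, seed = 5, sigma = 1)
  k <- 10
  st <- estimate_surface_stats(rnd, k = k)
  m <- cloud_matrix(rnd)
  D <- as.matrix(stats::dist(m))
  for (i in c(1, 17, 42)) {
    nb <- m[order(D[i, ])[1:(k + 1)], ]
    e <- eigen(stats::cov(nb), symmetric = TRUE)
    n_oracle <- e$vectors[, 3]
    got <- c(st$nx[i], st$ny[i], st$nz[i])
    expect_lt(min(sum((got - n_oracle)^2), sum((got + n_oracle)^2)), 1e-12)
    expect_equal(st$curvature[i], e$values[3] / sum(e$values), tolerance = 1e-10)
  }
  ## curvature of a uniformly sampled sphere is approximately uniform
  dense <- h_fib_sphere(2000, r = 10)
  cv <- estimate_surface_stats(dense, k = 20)$curvature
  expect_lt(stats::sd(cv) / mean(cv), 0.2)
})

test_that("region growing separates a fruit from a tangent leaf plane", {
  ## quasi-uniform sphere tangent to a coarser flat grid at its bottom pole
  ns <- 4000
  sph <- h_fib_sphere(ns, r = 20)
  leaf <- h_grid_cloud(30, 30, spacing = 4, z0 = -20)
  ctr <- 31 * 4 / 2
  leaf <- point_cloud(sweep(cloud_matrix(leaf), 2, c(ctr, ctr, 0)))
  cl <- point_cloud(rbind(cloud_matrix(sph), cloud_matrix(leaf)))
  st <- estimate_surface_stats(cl, k = 15)
  ## curvature scale of the sphere under this sampling, known by construction;
  ## the window must exclude the leaf's zero curvature
  c_sph <- stats::median(st$curvature[seq_len(ns)])
  regions <- region_grow_fruit(cl, st, curvature_seed_quantile = 0.7,
                               smoothness_deg = 25, curvature_tol = 0.6 * c_sph)
  expect_gt(length(regions), 0)
  main <- regions[[1]]
  expect_gte(sum(main <= ns), 0.95 * ns)              # recovers the sphere
  expect_lte(sum(main > ns), 0.02 * length(main))     # little leaf contamination
  ## disjointness of regions
  expect_equal(anyDuplicated(unlist(regions)), 0)
})

test_that("region growing keeps isolated and multiple fruits pure", {
  s1 <- h_sphere_cloud(900, r = 25, center = c(0, 0, 0), seed = 9)
  one <- region_grow_fruit(s1, estimate_surface_stats(s1, k = 15))
  expect_gte(length(one[[1]]), 0.99 * nrow(s1))

  s2 <- h_sphere_cloud(700, r = 12, center = c(120, 0, 0), seed = 10)
  cl <- point_cloud(rbind(cloud_matrix(s1), cloud_matrix(s2)))
  st <- estimate_surface_stats(cl, k = 15)
  regions <- region_grow_fruit(cl, st, curvature_tol = 0.05)
  expect_gte(length(regions), 2)
  top2 <- regions[1:2]
  purity <- vapply(top2, function(idx) {
    max(mean(idx <= 900), mean(idx > 900))
  }, numeric(1))
  expect_true(all(purity >= 0.95))
})
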