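test_that("dimension measurement matches closed-form extents", {
  fr <- h_ellipsoid_fruit(semi = c(30, 25, 20), n = 4000, seed = 1)
  sys <- symmetry_system_axes(diag(3), fr$truth$center)
  dims <- measure_dimensions(fr$cloud, sys)
  expect_lt(max(abs(unlist(dims) - c(60, 50, 40)) / c(60, 50, 40)), 0.01)

  ## unit-cube corners: all extents equal
  cube <- point_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  dc <- measure_dimensions(cube, symmetry_system_axes(diag(3), c(0.5, 0.5, 0.5)))
  expect_equal(unname(unlist(dc)), c(1, 1, 1))

  ## invariance under a common rigid motion
  tr <- random_pose(2)
  moved_sys <- symmetry_system_axes(tr$rotation %*% diag(3),
                                    as.vector(tr$rotation %*% fr$truth$center) +
                                      tr$translation)
  dims2 <- measure_dimensions(apply_transform(tr, fr$cloud), moved_sys)
  expect_equal(unlist(dims), unlist(dims2), tolerance = 1e-6)
  expect_error(measure_dimensions(point_cloud(matrix(numeric(0), ncol = 3)), sys),
               "empty")
})

test_that("the ellipsoid baseline agrees with extents on complete data", {
  fr <- h_ellipsoid_fruit(semi = c(30, 25, 20), n = 3000, seed = 3)
  cfg <- pipeline_config(seed = 3)
  base <- ellipsoid_baseline_dimensions(fr$cloud, cfg)
  sys <- symmetry_system_axes(diag(3), fr$truth$center)
  dims <- measure_dimensions(fr$cloud, sys)
  expect_lt(max(abs(unlist(base) - unlist(dims)) / unlist(dims)), 0.01)

  sph <- h_ellipsoid_fruit(semi = c(20, 20, 20), n = 2000, seed = 4)
  bs <- unlist(ellipsoid_baseline_dimensions(sph$cloud, cfg))
  expect_lt(max(bs) / min(bs) - 1, 0.01)
})

test_that("regression metrics follow their definitions", {
  expect_equal(unlist(regression_metrics(c(10, 20, 30), c(10, 20, 30))),
               c(r_squared = 1, rmse = 0, rrmse = 0))
  hand <- regression_metrics(c(11, 19, 31), c(10, 20, 30))
  expect_equal(hand$rmse, 1)
  expect_equal(hand$rrmse, 0.05)
  expect_equal(hand$r_squared, 0.985)
  ## predicting the mean gives R^2 = 0
  expect_equal(regression_metrics(rep(20, 3), c(10, 20, 30))$r_squared, 0)
  expect_error(regression_metrics(c(1, 2), c(5, 5)), "constant")
  ## scale equivariance
  p <- c(11, 19, 31); t <- c(10, 20, 30)
  m1 <- regression_metrics(p, t)
  m2 <- regression_metrics(10 * p, 10 * t)
  expect_equal(m2$rmse, 10 * m1$rmse)
  expect_equal(m2$r_squared, m1$r_squared)
  expect_equal(m2$rrmse, m1$rrmse)
})

test_that("signed-rank p-values match exhaustive enumeration", {
  expect_error(paired_signed_rank(1:8, 1:8), "zero")
  expect_error(paired_signed_rank(1:4, 2:5), "at least 6")

  ## 8 uniform-sign pairs: exact two-sided p = 2 / 2^8
  a <- c(1.1, 2.2, 3.1, 4.4, 5.2, 6.3, 7.1, 8.5)
  p <- paired_signed_rank(a, a + c(1, 2, 1.5, 0.7, 2.2, 1.3, 0.4, 3))
  expect_equal(p, 2 / 2^8)

  ## symmetry of the two-sided test
  b <- a + c(1, -2, 1.5, 0.7, -2.2, 1.3, 0.4, 3)
  expect_equal(paired_signed_rank(a, b), paired_signed_rank(b, a))

  ## random no-tie fixtures vs enumeration, n <= 10
  for (s in 1:5) {
    d <- withr::with_seed(s, stats::rnorm(8 + s %% 3))
    expect_equal(paired_signed_rank(d, rep(0, length(d))),
                 h_signed_rank_enum(d), tolerance = 1e-12)
  }
})

test_that("experiments aggregate per level, method and dimension", {
  cohort <- generate_cohort(6, c(0.10, 0.25), seed = 21, n_points = 2500,
                            sigma = 0.3)
  res <- run_experiment(cohort, config = pipeline_config(seed = 21))
  expect_s3_class(res, "assm_experiment")
  expect_equal(sort(unique(res$per_fruit$method)), c("assm", "ellipsoid"))
  expect_equal(nrow(res$metrics), 2 * 3)   # one level: 2 methods x 3 dims
  expect_named(res$metrics,
               c("level", "method", "dimension", "n", "r_squared", "rmse", "rrmse"))
  expect_true(all(res$metrics$rmse >= 0))
  expect_true(all(res$metrics$r_squared <= 1))
  expect_equal(nrow(res$p_values), 3)
  ## aggregates recompute from the emitted per-fruit table
  check <- res$per_fruit |>
    dplyr::filter(method == "assm", dimension == "length")
  expect_equal(
    res$metrics$rmse[res$metrics$method == "assm" &
                       res$metrics$dimension == "length"],
    sqrt(mean((check$predicted - check$truth)^2)))
  ## tidiers
  expect_identical(tidy(res), res$metrics)
  expect_equal(glance(res)$n_fruit, 6)
})

test_that("perfect information gives near-perfect recovery", {
  specs <- purrr::map(1:5, function(i) {
    preset_fruit_spec("tomato", seed = 100 + i, sigma = 0, n_points = 2500)
  })
  rows <- purrr::map(seq_along(specs), function(i) {
    fr <- generate_fruit(specs[[i]])
    tibble::tibble(id = i, cloud = list(fr$cloud), truth = list(fr$truth),
                   target_rate = 0, achieved_rate = 0, pattern = "none",
                   level = "Low")
  })
  cohort <- dplyr::bind_rows(rows)
  res <- run_experiment(cohort, methods = "assm",
                        config = pipeline_config(seed = 5))
  expect_true(all(res$metrics$r_squared >= 0.999))
})
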