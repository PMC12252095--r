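## Synthetic fruit generator: superellipsoid surfaces sampled uniformly by
## area, with radial Gaussian noise, arbitrary pose, and programmable
## occlusion masks whose removed-area fraction is calibrated against the
## generator's own surface mesh. Every stage is deterministic per seed, so
## the generator doubles as the package's ground-truth oracle.

## Signed power: the superellipsoid parametrisation's cos/sin exponent.
spow <- function(v, e) sign(v) * abs(v)^e

## Triangle mesh of a superellipsoid in canonical pose (axes = x, y, z).
## Returns vertices, triangle indices, per-triangle areas, centroids and
## unit normals. eta is latitude, omega longitude.
superellipsoid_mesh <- function(a, b, c, eps1 = 1, eps2 = 1,
                                n_eta = 120, n_om = 240) {
  eta <- seq(-pi / 2, pi / 2, length.out = n_eta + 1)
  om <- seq(-pi, pi, length.out = n_om + 1)[-(n_om + 1)]
  ETA <- matrix(eta, n_eta + 1, n_om)
  OM <- matrix(om, n_eta + 1, n_om, byrow = TRUE)
  V <- cbind(as.vector(a * spow(cos(ETA), eps1) * spow(cos(OM), eps2)),
             as.vector(b * spow(cos(ETA), eps1) * spow(sin(OM), eps2)),
             as.vector(c * spow(sin(ETA), eps1)))
  idx <- function(i, j) (j - 1L) * (n_eta + 1L) + i
  i <- rep(seq_len(n_eta), n_om)
  j <- rep(seq_len(n_om), each = n_eta)
  jp <- ifelse(j == n_om, 1L, j + 1L)
  tri <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, jp)),
               cbind(idx(i, j), idx(i + 1L, jp), idx(i, jp)))
  P1 <- V[tri[, 1], , drop = FALSE]
  P2 <- V[tri[, 2], , drop = FALSE]
  P3 <- V[tri[, 3], , drop = FALSE]
  cr <- cbind((P2[, 2] - P1[, 2]) * (P3[, 3] - P1[, 3]) - (P2[, 3] - P1[, 3]) * (P3[, 2] - P1[, 2]),
              (P2[, 3] - P1[, 3]) * (P3[, 1] - P1[, 1]) - (P2[, 1] - P1[, 1]) * (P3[, 3] - P1[, 3]),
              (P2[, 1] - P1[, 1]) * (P3[, 2] - P1[, 2]) - (P2[, 2] - P1[, 2]) * (P3[, 1] - P1[, 1]))
  nrm <- sqrt(rowSums(cr^2))
  keep <- nrm > 1e-12          # degenerate polar slivers contribute nothing
  list(vertices = V,
       P1 = P1[keep, , drop = FALSE], P2 = P2[keep, , drop = FALSE],
       P3 = P3[keep, , drop = FALSE],
       areas = nrm[keep] / 2,
       centroids = (P1[keep, , drop = FALSE] + P2[keep, , drop = FALSE] +
                      P3[keep, , drop = FALSE]) / 3,
       normals = cr[keep, , drop = FALSE] / nrm[keep])
}

#' Specification of a synthetic fruit
#'
#' @param semi_axes Length-3 positive semi-axes (a, b, c) in mm.
#' @param eps Length-2 superellipsoid squareness exponents in (0.3, 2); (1,
#'   1) gives an ellipsoid.
#' @param pose A [rigid_transform()] placing the fruit in the scene.
#' @param sigma Radial Gaussian surface-noise standard deviation (mm), >= 0.
#' @param n_points Number of surface samples.
#' @param seed Integer seed.
#' @return A `fruit_spec` list.
#' @export
fruit_spec <- function(semi_axes, eps = c(1, 1), pose = rigid_transform(),
                       sigma = 0, n_points = 5000, seed = 1L) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            length(eps) == 2, all(eps > 0.3), all(eps < 2),
            inherits(pose, "rigid_transform"),
            sigma >= 0, n_points >= 10)
  structure(list(semi_axes = as.numeric(semi_axes), eps = as.numeric(eps),
                 pose = pose, sigma = sigma,
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "fruit_spec")
}

#' A uniformly random pose derived from a seed
#'
#' Rotation from the QR decomposition of a Gaussian matrix (Haar-uniform up
#' to sign fixing), translation uniform in a cube of the given half-width.
#'
#' @param seed Integer seed.
#' @param translation_range Half-width of the translation cube (mm).
#' @return A [rigid_transform()].
#' @export
random_pose <- function(seed = 1L, translation_range = 200) {
  with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9), 3))
    R <- qr.Q(qr_)
    R <- R %*% diag(sign(diag(qr.R(qr_))))
    if (det(R) < 0) R[, 3] <- -R[, 3]
    t <- stats::runif(3, -translation_range, translation_range)
    rigid_transform(R, t)
  })
}

#' Generate a synthetic fruit cloud with ground truth
#'
#' Samples the superellipsoid surface uniformly by area (triangles of a
#' dense parametric mesh drawn proportionally to area, then uniform
#' barycentric points), perturbs each sample radially by Gaussian noise,
#' and poses the result. The ground truth records the posed centre, the
#' posed symmetry-axis normal (the principal axis of the largest
#' semi-axis), the dimensions (sorted descending doubled semi-axes), the
#' mesh surface area, and the complete posed cloud. Per-point normals are
#' the (posed) facet normals of the pre-noise sample locations.
#'
#' @param spec A [fruit_spec()].
#' @return A list: `cloud` (a [point_cloud()] with normals) and `truth`
#'   (class `fruit_truth`).
#' @export
generate_fruit <- function(spec) {
  stopifnot(inherits(spec, "fruit_spec"))
  s <- spec$semi_axes
  mesh <- superellipsoid_mesh(s[1], s[2], s[3], spec$eps[1], spec$eps[2])
  n <- spec$n_points
  pts <- with_seed(stage_seed(spec$seed, "surface-sampling"), {
    ti <- sample.int(length(mesh$areas), n, replace = TRUE, prob = mesh$areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    P <- (1 - r1) * mesh$P1[ti, , drop = FALSE] +
      r1 * (1 - r2) * mesh$P2[ti, , drop = FALSE] +
      r1 * r2 * mesh$P3[ti, , drop = FALSE]
    N <- mesh$normals[ti, , drop = FALSE]
    if (spec$sigma > 0) {
      rad <- P / pmax(sqrt(rowSums(P^2)), 1e-9)
      P <- P + rad * stats::rnorm(n, 0, spec$sigma)
    }
    list(P = P, N = N)
  })
  R <- spec$pose$rotation
  tr <- spec$pose$translation
  posed <- sweep(pts$P %*% t(R), 2, tr, `+`)
  posed_n <- pts$N %*% t(R)
  cl <- point_cloud(posed, normals = posed_n)
  major <- which.max(s)
  axes <- R %*% diag(3)                      # posed canonical axes as columns
  truth <- structure(list(
    center = tr,
    normal = as.vector(axes[, major]),
    axes = axes,
    semi_axes = s,
    dimensions = sort(2 * s, decreasing = TRUE),
    area = sum(mesh$areas),
    cloud = cl,
    mesh_centroids = sweep(mesh$centroids %*% t(R), 2, tr, `+`),
    mesh_normals = mesh$normals %*% t(R),
    mesh_areas = mesh$areas,
    spec = spec), class = "fruit_truth")
  list(cloud = cl, truth = truth)
}

#' @export
print.fruit_truth <- function(x, ...) {
  cat(sprintf(
    "Fruit ground truth: dims %.1f/%.1f/%.1f mm, area %.0f mm^2, centre (%.1f, %.1f, %.1f)\n",
    x$dimensions[1], x$dimensions[2], x$dimensions[3], x$area,
    x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Occlusion pattern description
#'
#' @param kind `"cap"` (one polar cap), `"lateral_patch"` (one equatorial
#'   patch), `"multi_patch"` (a polar cap plus 1-3 lateral patches) or
#'   `"random_viewpoint"` (back-facing surface removal from a random
#'   station).
#' @param target_rate Target removed-area fraction in \[0.05, 0.70\].
#' @param seed Integer seed.
#' @param n_patches For `multi_patch`: total patch count (2-4).
#' @return An `occlusion_pattern` list.
#' @export
occlusion_pattern <- function(kind = c("cap", "lateral_patch", "multi_patch",
                                       "random_viewpoint"),
                              target_rate, seed = 1L, n_patches = 2L) {
  kind <- match.arg(kind)
  stopifnot(target_rate >= 0.05, target_rate <= 0.70,
            n_patches >= 2, n_patches <= 4)
  structure(list(kind = kind, target_rate = target_rate,
                 seed = as.integer(seed), n_patches = as.integer(n_patches)),
            class = "occlusion_pattern")
}

## Bisect a monotone scalar mask parameter until the removed mesh-area
## fraction matches the target within tol.
bisect_mask <- function(frac_fun, lo, hi, target, tol = 0.005, iters = 60) {
  f_lo <- frac_fun(lo)
  f_hi <- frac_fun(hi)
  increasing <- f_hi >= f_lo
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    f <- frac_fun(mid)
    if (abs(f - target) <= tol) return(mid)
    if ((f < target) == increasing) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Remove surface regions to a calibrated occlusion rate
#'
#' Builds the requested mask in posed space, sizes it by bisection so the
#' removed fraction of the ground-truth mesh area lands within 2 percentage
#' points of `target_rate`, and drops the cloud points inside the mask. The
#' achieved rate is the mask's mesh-area fraction (the generator-side
#' equivalent of the occlusion-rate definition).
#'
#' @param cloud The complete fruit cloud (from [generate_fruit()]).
#' @param truth The matching `fruit_truth`.
#' @param pattern An [occlusion_pattern()].
#' @return A list: `cloud` (occluded [point_cloud()]), `achieved_rate`,
#'   `kept` (logical index into the input).
#' @export
apply_occlusion <- function(cloud, truth, pattern) {
  stopifnot(inherits(truth, "fruit_truth"), inherits(pattern, "occlusion_pattern"))
  cloud <- as_point_cloud(cloud)
  m <- as_xyz(cloud)
  cen <- truth$center
  ctr <- truth$mesh_centroids
  w <- truth$mesh_areas / sum(truth$mesh_areas)
  axis <- truth$normal
  a_max <- max(truth$semi_axes)
  target <- pattern$target_rate

  mask_of <- with_seed(stage_seed(pattern$seed, paste0("occlusion-", pattern$kind)), {
    switch(pattern$kind,
      cap = {
        sgn <- sample(c(-1, 1), 1)
        dirv <- sgn * axis
        h_of <- function(h) function(p) as.vector(sweep(p, 2, cen) %*% dirv) > h
        frac <- function(h) sum(w[h_of(h)(ctr)])
        h <- bisect_mask(frac, -a_max, a_max, target)
        h_of(h)
      },
      lateral_patch = {
        phi <- stats::runif(1, 0, 2 * pi)
        B <- tangent_basis(axis)
        dirv <- as.vector(B %*% c(cos(phi), sin(phi)))
        seedpt <- ctr[which.max(ctr %*% dirv - as.numeric(cen %*% dirv)), ]
        r_of <- function(r) function(p) sqrt(rowSums(sweep(p, 2, seedpt)^2)) < r
        frac <- function(r) sum(w[r_of(r)(ctr)])
        r <- bisect_mask(frac, 0, 4 * a_max, target)
        r_of(r)
      },
      multi_patch = {
        np <- pattern$n_patches
        sgn <- sample(c(-1, 1), 1)
        pole <- ctr[which.max(ctr %*% (sgn * axis) - as.numeric(cen %*% (sgn * axis))), ]
        B <- tangent_basis(axis)
        phis <- stats::runif(np - 1L, 0, 2 * pi)
        seeds <- rbind(pole, t(vapply(phis, function(phi) {
          dirv <- as.vector(B %*% c(cos(phi), sin(phi)))
          ctr[which.max(ctr %*% dirv - as.numeric(cen %*% dirv)), ]
        }, numeric(3))))
        rel <- stats::runif(np, 0.7, 1.3)
        r_of <- function(r) function(p) {
          inside <- rep(FALSE, nrow(p))
          for (k in seq_len(np)) {
            inside <- inside | sqrt(rowSums(sweep(p, 2, seeds[k, ])^2)) < r * rel[k]
          }
          inside
        }
        frac <- function(r) sum(w[r_of(r)(ctr)])
        r <- bisect_mask(frac, 0, 4 * a_max, target)
        r_of(r)
      },
      random_viewpoint = {
        dirv <- unit3(stats::rnorm(3))
        vp <- cen + dirv * 4 * a_max
        ## remove surface whose outward normal faces away from the station;
        ## tau slides the visibility threshold
        tau_of <- function(tau) {
          force(tau)
          function(p, nrm) {
            tov <- sweep(-p, 2, -vp)       # vp - p
            tov <- tov / pmax(sqrt(rowSums(tov^2)), 1e-12)
            rowSums(nrm * tov) < tau
          }
        }
        frac <- function(tau) sum(w[tau_of(tau)(ctr, truth$mesh_normals)])
        tau <- bisect_mask(frac, -1, 1, target)
        f <- tau_of(tau)
        function(p, nrm = NULL) {
          if (is.null(nrm)) stop("random_viewpoint mask needs normals", call. = FALSE)
          f(p, nrm)
        }
      })
  })

  achieved <- if (pattern$kind == "random_viewpoint") {
    sum(w[mask_of(ctr, truth$mesh_normals)])
  } else {
    sum(w[mask_of(ctr)])
  }
  if (abs(achieved - target) > 0.02) {
    stop(sprintf(
      "occlusion pattern '%s' cannot reach target rate %.2f (achieved %.3f)",
      pattern$kind, target, achieved), call. = FALSE)
  }
  removed <- if (pattern$kind == "random_viewpoint") {
    if (!has_normals(cloud)) stop("random_viewpoint needs cloud normals", call. = FALSE)
    mask_of(m, cbind(cloud$nx, cloud$ny, cloud$nz))
  } else {
    mask_of(m)
  }
  keep <- which(!removed)
  list(cloud = rebuild_cloud(m[keep, , drop = FALSE], cloud, keep),
       achieved_rate = achieved,
       kept = !removed)
}

#' Draw a fruit specification from a named crop preset
#'
#' Both presets enforce a distinct major axis so the ground-truth symmetry
#' direction is well defined: `"tomato"` draws semi-axes a in \[28, 40\] mm
#' with a/b in \[1.15, 1.35\] and c/b in \[0.85, 1\] (b and c floored at 22
#' and 20 mm), squareness exponents in \[0.9, 1.1\]; `"eggplant"` draws an
#' elongated a in \[60, 110\] mm over a \[25, 40\] mm cross-section. Surface
#' noise defaults to uniform in \[0.2, 0.8\] mm and the sample count to
#' 3000-8000 points unless fixed. The pose is random per seed.
#'
#' @param preset `"tomato"` or `"eggplant"`.
#' @param seed Integer seed (drives shape, pose, noise and sampling).
#' @param sigma Optional fixed surface noise (mm).
#' @param n_points Optional fixed sample count.
#' @return A [fruit_spec()].
#' @export
preset_fruit_spec <- function(preset, seed, sigma = NULL, n_points = NULL) {
  with_seed(stage_seed(seed, paste0("spec-", preset)), {
    if (preset == "tomato") {
      a <- stats::runif(1, 28, 40)
      b <- max(22, a / stats::runif(1, 1.15, 1.35))
      cc <- max(20, b * stats::runif(1, 0.85, 1.0))
      eps <- stats::runif(2, 0.9, 1.1)
    } else if (preset == "eggplant") {
      a <- stats::runif(1, 60, 110)
      b <- stats::runif(1, 25, 40)
      cc <- b * stats::runif(1, 0.9, 1.0)
      eps <- c(stats::runif(1, 0.7, 1.0), stats::runif(1, 0.85, 1.1))
    } else {
      stop("unknown preset: ", preset, call. = FALSE)
    }
    fruit_spec(semi_axes = c(a, b, cc), eps = eps,
               pose = random_pose(stage_seed(seed, "pose")),
               sigma = sigma %||% stats::runif(1, 0.2, 0.8),
               n_points = n_points %||% sample(3000:8000, 1),
               seed = seed)
  })
}

## Default pattern kind for a target rate, mirroring the occlusion-level
## scenarios: light leaf occlusion for Low rates, a top-plus-side composite
## for Middle, dense multi-source for High.
default_pattern <- function(rate, seed) {
  if (rate <= 0.30) {
    occlusion_pattern("cap", rate, seed)
  } else if (rate <= 0.50) {
    occlusion_pattern("multi_patch", rate, seed, n_patches = 2L)
  } else {
    occlusion_pattern("multi_patch", rate, seed,
                      n_patches = with_seed(stage_seed(seed, "npatch"),
                                            sample(2:4, 1)))
  }
}

#' Generate a cohort of occluded synthetic fruits
#'
#' Draws `n` fruits from a preset, assigns each a target occlusion rate
#' uniform in `occlusion_band`, applies the default occlusion pattern for
#' its severity (or a fixed `pattern_kind`), and returns everything in a
#' nested tibble. Per-fruit seeds derive deterministically from the cohort
#' seed.
#'
#' @param n Cohort size, >= 1.
#' @param occlusion_band Length-2 target-rate band within \[0.05, 0.70\].
#' @param preset `"tomato"` or `"eggplant"`.
#' @param seed Cohort seed.
#' @param sigma Fix the surface noise (mm) instead of drawing it per fruit.
#' @param n_points Fix the sample count instead of drawing it per fruit.
#' @param pattern_kind Optional fixed [occlusion_pattern()] kind.
#' @return A tibble with columns `id`, `cloud`, `truth` (list columns),
#'   `target_rate`, `achieved_rate`, `pattern`, `level`.
#' @export
generate_cohort <- function(n, occlusion_band, preset = "tomato", seed = 1L,
                            sigma = NULL, n_points = NULL, pattern_kind = NULL) {
  stopifnot(n >= 1, length(occlusion_band) == 2,
            occlusion_band[1] >= 0.05, occlusion_band[2] <= 0.70,
            occlusion_band[1] <= occlusion_band[2])
  rows <- purrr::map(seq_len(n), function(i) {
    fseed <- stage_seed(seed, paste0("cohort-fruit-", i))
    spec <- preset_fruit_spec(preset, fseed, sigma = sigma, n_points = n_points)
    fr <- generate_fruit(spec)
    rate <- with_seed(stage_seed(fseed, "rate"),
                      stats::runif(1, occlusion_band[1], occlusion_band[2]))
    pat <- if (is.null(pattern_kind)) {
      default_pattern(rate, stage_seed(fseed, "pattern"))
    } else {
      occlusion_pattern(pattern_kind, rate, stage_seed(fseed, "pattern"))
    }
    occ <- apply_occlusion(fr$cloud, fr$truth, pat)
    tibble::tibble(id = i,
                   cloud = list(occ$cloud),
                   truth = list(fr$truth),
                   target_rate = rate,
                   achieved_rate = occ$achieved_rate,
                   pattern = pat$kind,
                   level = classify_occlusion(occ$achieved_rate))
  })
  dplyr::bind_rows(rows)
}
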