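---
title: "Symmetry-based completion of occluded fruit point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry-based completion of occluded fruit point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symfruit)
```

## The problem

Canopy-level laser scans of greenhouse crops deliver fruit point clouds
with 5-70% of the surface missing: leaves, stems and limited station
placement shadow large patches. Direct geometric fitting (an ellipsoid
through the visible points) degrades quickly as the missing fraction
grows, because nothing constrains the hidden side. Fruits, however, are
approximately mirror-symmetric about an axis through the peduncle, and a
partial scan usually contains the mirror image of much of what is missing.
`symfruit` exploits that: it estimates the symmetry plane from the partial
cloud, builds a triple-orthogonal system of mirror planes through the
fruit centre, and fills holes with reflected copies of observed surface.

## The model and its assumptions

A fruit is treated as a noisy sample of a closed surface that is
(approximately) invariant under reflection across three mutually
orthogonal planes through its geometric centre -- exactly true for
ellipsoids and superellipsoids, approximately true for real tomatoes and
eggplants. The method assumes:

* the visible surface determines the centre well enough for an ellipsoid
  fit (the cloud covers enough of the fruit that a quadric is
  identifiable; in practice >= 30% of the surface);
* the fruit has a distinct principal axis, so "the" symmetry plane is
  well defined. Near-spherical fruits trigger a degeneracy warning and any
  plane through the centre is accepted;
* coordinates are millimetres; no unit autodetection is attempted.

## Plane detection

1. **Centre**: RANSAC ellipsoid fitting. Hypotheses are algebraic quadrics
   through minimal 9-point samples. Because an interpolating quadric
   through 9 noisy points is numerically wild (and almost never
   ellipsoid-typed), each hypothesis receives one least-squares refit on a
   wide-gate consensus (3x the inlier tolerance) before scoring -- the
   local-optimisation step familiar from LO-RANSAC. Inliers are gated by
   the first-order geometric distance |F(p)|/||grad F(p)|| (the exact
   point-to-ellipsoid distance has no closed form). Ellipsoid validity
   (positive-definite quadratic form, real semi-axes) is enforced on the
   consensus refit. The full-data least-squares fit always competes as an
   additional hypothesis so the noise-free case sits exactly at the global
   optimum.
2. **Initial plane**: the principal axis of the cloud's covariance,
   anchored at the ellipsoid centre. An eigenvalue ratio below 1.05 raises
   the near-spherical warning.
3. **Self-matching refinement**: the cloud is reflected across the
   candidate plane and aligned back onto itself with point-to-point ICP
   under an annealed correspondence gate (15, 8, 4, 2, 1 mm by default).
   The composition of the true and candidate reflections is a rotation by
   *twice* the plane error about the planes' intersection line, so the
   plane normal is advanced by **half** of the recovered ICP rotation;
   applying the full rotation verbatim reflects the error to the other
   side and oscillates. Each step is accepted only if a robust
   mirror-distance objective improves (half step first, quarter step as
   fallback); the loop stops when the incremental rotation falls below
   0.5 degrees or after 10 iterations.
4. **Polish and axis anchoring**: a 2-D Nelder-Mead polish of the normal
   (parameterised in its tangent plane) runs on the same objective, for
   both the self-matching result and the ellipsoid's major axis as an
   alternative start. Every principal plane of a near-superellipsoid is a
   true mirror plane, so the objective alone cannot distinguish the fruit
   axis from a perpendicular one; when the fitted ellipsoid is clearly
   anisotropic (axis ratio >= 1.08) candidates within 45 degrees of its
   major axis are preferred. This matches the biological premise that the
   symmetry plane follows the fruit's peduncle axis.

**The robust objective.** For a unit normal n the objective is the RMS of
nearest-neighbour distances between the cloud and its reflection, with
each distance capped at a *fixed* value (three median point spacings,
floor 2 mm). Reflected points that fall into occlusion holes pay a
constant penalty, so the objective rewards matching more surface and
matching it closely. The cap is deliberately not quantile-adaptive: an
adaptive cap lets a badly oriented plane appear good by re-weighting
which points it must fit -- on 50%-occluded test fruit the
quantile-trimmed variant has its global minimum more than 18 degrees from
the true axes, while the fixed-cap variant peaks at the true plane.

**Why not contour-to-contour ICP?** Edge contours of the mirrored and
unmirrored clouds carry no usable plane-error signal: the rim where a
half-cloud is cut lies *on* the candidate plane and is pointwise invariant
under the reflection, and an occlusion-hole boundary has no mirrored
counterpart on the other side (the hole is only on one side). Contour
alignment therefore either returns the identity or matches unrelated
curves. Edge extraction ([extract_edge_contour()]) is still part of the
loop: hole-boundary points are *excluded* from the ICP source, removing
correspondences that have no partner by construction.

## Triple-orthogonal system and completion

The second plane normal is the maximum-variance direction of the cloud
projected into the primary plane; the third is their cross product. The
whole triad is then refined jointly over SO(3) (Nelder-Mead on the summed
per-plane objective), multi-started from both the projected-covariance
construction and the ellipsoid's principal axes -- under heavy occlusion
the projected covariance can be tens of degrees off while the ellipsoid
axes stay within a few degrees, and the best final objective wins.
Because only rigid rotations of the triad are searched, orthogonality is
exact by construction.

Completion reflects the cloud across each plane in turn. A reflected
point is a hole filler only if its nearest existing point is farther than
the gap threshold (default 2 mm, raised automatically to 1.5x the cloud's
95th-percentile point spacing so sparse-but-observed surface is never
mistaken for a hole). Each patch is rigidly seated by a small gated ICP
against the original points near it, with the correction rejected if it
asks for more than 10 degrees or two gap widths -- large occlusions must
not drag their patch. A second sweep over the three planes with half the
gate closes the gate-wide erosion bands along hole rims; its candidates
are restricted to the neighbourhood of first-sweep fills so it cannot
fire on intact surface. Sequential sweeps mean later mirrors see earlier
fills, which realises the full 8-element orbit of the three reflections
(compositions included). Original points are never moved or deleted, and
every appended point carries its source plane in a `provenance` column.
Finally the union is fused on a 1 mm voxel grid (centroid per occupied
cell).

## Occlusion quantification

The occlusion rate is `1 - a_observed / a_complete`, the missing surface
fraction, classified Low (<= 30%), Middle (30-50%] or High (50-70%];
rates above 70% fall outside the calibrated range. Surface area is
estimated without a watertight mesh: each point's k-neighbourhood is
projected onto its PCA tangent plane; an interior point is credited the
area of its local Voronoi cell (the polygon of circumcenters of its
incident Delaunay triangles -- robust to triangulation differences
between neighbouring patches), while a boundary point (recognised by a
polar-angle gap >= 120 degrees among its projected neighbours) is
credited one third of its incident triangle area. Local cells tile the
surface, so the sum estimates total area; measured accuracy is about 3%
on dense spheres (the contract is 5% on closed convex shapes) and the
estimator carries a floor of roughly 1.5-3% "apparent occlusion" even on
complete clouds, from the boundary treatment of small gaps. Comparisons
that need to be sharper than that floor (for example, residual missing
area after completing a 70%-occluded fruit) are therefore made against
the generator's mesh-area bookkeeping rather than through the estimator.

## The synthetic generator

`generate_fruit()` samples superellipsoid surfaces uniformly by area
(triangles of a dense parametric mesh drawn proportionally to area), adds
radial Gaussian noise, and poses the fruit rigidly. Ground truth records
the posed centre, the symmetry-axis normal (the principal axis of the
largest semi-axis), sorted dimensions, the mesh surface area, and the
complete cloud. `apply_occlusion()` removes cap, lateral-patch,
multi-patch or viewpoint-culled regions, sized by bisection against the
ground-truth mesh so the removed area lands within 2 percentage points of
the target. The default pattern per severity mirrors the field scenarios:
a single cap for light (leaf) occlusion, a top-plus-side composite for
medium, two to four patches for heavy multi-source occlusion.

The tomato preset draws semi-axes a in [28, 40] mm with a/b in
[1.15, 1.35] and c/b in [0.85, 1.0] (floors keep b >= 22 and c >= 20 mm,
inside the nominal 20-40 mm band), squareness exponents in [0.9, 1.1],
noise 0.2-0.8 mm, 3000-8000 points. The axis-distinctness constraint is
deliberate: with independently drawn near-equal semi-axes the ground-truth
symmetry axis is ill-defined (any principal axis flip is equally valid)
and an angular-error benchmark against it is meaningless. The eggplant
preset elongates a to 60-110 mm over a 25-40 mm cross-section.

What the generator does *not* emulate: real leaf silhouettes (the four
mask families are declared surrogates), uneven scan density, registration
artefacts between stations, non-superellipsoid shape details (shoulders,
ribs, scars) and colour. Passing the synthetic suites therefore
demonstrates correct geometry and robustness to the modelled effects, not
performance on every real scan.

## Numerical choices and degenerate inputs

* Voxel grids anchor on the origin-aligned lattice (`floor(x / voxel)`),
  which makes voxel filtering exactly idempotent; a min-corner anchor is
  not (re-anchoring can merge adjacent centroids). The pass-through filter
  is idempotent trivially. Statistical outlier removal is *not* exactly
  idempotent -- removing the upper tail tightens the recomputed threshold
  -- and no such claim is made for it.
* Plane equality is always judged by [angular_error()] (sign-invariant);
  `plane(n, c)` and `plane(-n, c)` are the same object to every consumer
  except the half-space split, which uses the orientation explicitly.
* Ties and degeneracies: clustering re-queries exactly those points whose
  neighbour cap saturated, so components are exact at any tolerance;
  coincident neighbourhoods get curvature 0 and an "unreliable" flag;
  spheres warn and proceed (any plane through the centre is valid).
* All stochastic stages draw child seeds from the master seed and a stage
  label ([stage_seed()]), so any stage can be re-run in isolation and the
  full pipeline is a pure function of (input, config, seed): reruns are
  byte-identical.
* Region growing visits seeds in increasing curvature order within the
  above-quantile seed set; anchoring the curvature window at an
  extreme-curvature seed would exclude ordinary surface. The "dynamic"
  threshold adjustment is one relaxation step (x1.5 on both thresholds)
  when the largest region covers less than 30% of non-planar points.

## Problem sizes

The validation protocols are sized for a single CPU: the symmetry-plane
protocol runs 40 fruits of 3000-8000 points (about three minutes), the
medium-occlusion dimension protocol 30 fruits (about five), and the unit
suites use clouds of 300-8000 points. Reflection-symmetry invariants of
completed clouds are asserted on 8000-point fixtures, the density at
which voxel-scale symmetry is measurable at all: even a *perfect*
complete cloud of 3000-4000 points has reflected nearest-neighbour gaps
above 2 mm simply from sampling sparsity.

## Known limitations

* Fruits whose true shape breaks mirror symmetry (ribbed or malformed)
  violate the model; the completion then regularises the shape toward its
  symmetric idealisation.
* At occlusion beyond ~70%, or when a region *and* its entire mirror
  orbit are hidden, no symmetry-based method can recover the surface; the
  residual is reported, not invented.
* The ellipsoid-axis anchoring presumes the major axis is the symmetry
  axis. For fruit whose symmetry axis is the *minor* axis of a flattened
  shape the preference would need to be inverted; the preset fruits and
  the crops targeted here have a distinct major axis.
* Point-to-point ICP slides on nearly spherical surfaces; the objective
  guard prevents divergence but convergence is slower the closer the
  fruit is to a sphere.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
fr  <- generate_fruit(preset_fruit_spec("tomato", seed = 3, sigma = 0.3))
occ <- apply_occlusion(fr$cloud, fr$truth,
                       occlusion_pattern("multi_patch", 0.45, seed = 3))
res <- assm_complete(occ$cloud, pipeline_config(seed = 3))
res
measure_dimensions(res$cloud, res$system)
fr$truth$dimensions
autoplot(res)
```
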