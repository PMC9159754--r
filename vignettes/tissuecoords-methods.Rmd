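---
title: "Organ-centric quantification of segmented tissue meshes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ-centric quantification of segmented tissue meshes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuecoords)
```

## Overview

Modern plant developmental biology quantifies growth on segmented cellular
meshes: curved triangulated surfaces carrying an epidermal segmentation
(2.5D), or full complexes of closed per-cell surfaces (3D). The scientific
questions — where does an organ grow, in which directions, how do cells
divide, where do polarity proteins accumulate — are answered by *positional*
quantities defined relative to the organ itself rather than the microscope
frame. `tissuecoords` implements that quantification layer as a scriptable
library: organ-centric coordinate systems, growth tensors from time-lapse
pairs, radial-basis-function deformation fields, division-plane analysis,
a catalogue of per-cell shape/network/signal measures, cell-type and layer
classification, and a synthetic-tissue generator that makes every algorithm
testable with known ground truth.

This vignette explains the models and the numerical choices. Everything it
states quantitatively is computed by the package's test suite or by
`scripts/acceptance.R`; no empirical claims beyond those are made.

## Meshes, labels and units

All geometry is in micrometres, right-handed axes. Cell labels are positive
integers; 0 marks background/outside. A `surface_cell_mesh` stores vertices,
outward-oriented triangles, one cell label per triangle and an optional
non-negative per-vertex signal. A `volumetric_cell_mesh` stores one closed
outward surface per cell with a per-triangle *wall tag* naming the neighbor
cell behind each wall patch (0 for the organ outside); matching patches of
adjacent cells have equal areas, which `validate_mesh()` checks along with
watertightness and per-cell connectivity.

*Junctions* — vertices where at least three cells meet, or two cells meet
the tissue border — are the material landmarks used for growth fitting:
they are identifiable across time points, unlike arbitrary surface points.

Adjacency requires a shared boundary of positive measure (a triangle edge
in 2.5D, a wall patch in 3D). A single shared vertex does not make two
cells neighbors; on rectangular grids this prevents spurious diagonal
adjacencies.

Label images (TIFF stacks) are imported by extracting, per label, the exact
0.5-level isosurface of the binary voxel mask: axis-aligned voxel faces,
two triangles each, tagged with the neighboring voxel's label. No smoothing
is applied, so wall areas equal voxel-face counts exactly and the topology
is bit-reproducible. The price is blocky geometry; for the wall-area and
volume statistics the import serves, that is the right trade-off.

## Organ-centric coordinates

**Cell distance.** Multi-source shortest-path distance over the cell
connectivity graph (Dijkstra semantics, ties resolved toward lower labels).
Three edge weights are supported: `euclidean` (centroid-to-centroid
distance, micrometres), `cells` (unit per edge, i.e. cells crossed) and
`inv_wall` (reciprocal shared-wall measure, floored at 1e-9 to avoid
division blow-up). Centroid distance was chosen for the Euclidean weight —
wall-crossing distance is an alternative reading, but centroid distance is
simple, symmetric, and reduces to it on regular files.

**Bezier axis coordinate.** An organ axis is a clamped composite cubic
Bezier spline. Each cell is assigned the arc length at the spline point
nearest its centroid, its distance to that point, and the unit tangent
there. The arc-length table uses 1000 samples per segment with 5-point
Gauss–Legendre quadrature on each subinterval; the nearest point is located
on that dense polyline and refined by golden-section search, so coordinates
are accurate to well below mesh resolution (the tests verify 0.1 µm against
a 1e5-sample brute-force projection). Organ axes can be fitted to an
ordered cell file by constrained least squares: segment knots are placed at
centroids, which the spline interpolates exactly.

**Polar coordinate.** Angle of the centroid's projection about a Cartesian
axis, measured from a reference direction, in [0°, 360°). Cells on the axis
are unassigned.

**Relative radial coordinate.** For layered organs, a ray from the nearest
axis point through the cell centroid is intersected with the organ surface;
the relative coordinate is (centroid distance from axis)/(surface-exit
distance from axis), i.e. 0 on the axis and 1 at the surface. The *last*
ray–surface intersection is used so that interior wall hits of blocky
surfaces cannot truncate the ray. Cells whose ray misses the surface are
unassigned with a warning.

**Direction frames.** Per-cell orthonormal right-handed triads are built
either from an attribute gradient (d1 = in-tangent-plane gradient of, e.g.,
a cell-distance field over the 1-ring neighborhood, d2 = surface normal,
d3 = d1 × d2) or from two user directions with Gram–Schmidt
re-orthogonalization (inputs with |d1·d2| > 0.99 are rejected as parallel).
The tangent plane of a cell is defined by its area-weighted mean triangle
normal throughout the package.

## Growth tensors

Between two segmented time points related by a parent map (child label at
t1 → mother label at t0), each mother's deformation gradient F is the
least-squares linear map (with translation) sending its junction landmarks
at t0 to the corresponding junctions of its daughters' union at t1. On
surface meshes the fit is performed in the mother's tangent frame, with the
t1 frame aligned by projecting the t0 in-plane basis onto the daughters'
mean plane — the projection convention is ours; the underlying method does
not prescribe one. Polar decomposition (via SVD) yields the right stretch
tensor U = sqrt(F'F), whose eigenvalues kmax ≥ kmin are the principal
stretch ratios and whose eigenvectors are the principal directions of
growth. For landmark sets generated by any affine map the estimator is
exact (the tests require 1e-6 recovery; the linear fit reproduces
polynomials of degree one).

Derived quantities: areal extension (summed daughter area over mother area;
volumes in 3D), proliferation (terminal descendants per ancestor after
composing parent maps across intervals; a once-divided mother scores 2),
directional stretch |F d| of a fiber initially along d (exact for
axis-aligned pure stretches, maximal at the kmax direction — we chose |F d|
over a component of U because it is the physically meaningful fiber-length
ratio), and change maps (ratio/percent/difference, daughters aggregated by
sum for sizes or mean for intensities). Growth is reported per interval,
not per unit time.

## Deformation functions

Scattered landmark correspondences are interpolated by a cubic
radial-basis-function field: phi(r) = r³ kernel plus a full affine term,
solved as the standard augmented symmetric system with side conditions
(RBF weights orthogonal to constants and coordinates). Landmarks are
pre-scaled to unit RMS radius for conditioning. With ridge eps = 0 the
field interpolates exactly; eps > 0 trades interpolation for smoothness.
Strictly coplanar landmark sets make the polynomial block rank-deficient
and are rejected with guidance (the internal tracking fitter falls back to
a minimal-norm solve in that case, which still interpolates).

The field's Jacobian is analytic: F(x) = A + Σᵢ 3 rᵢ wᵢ (x − cᵢ)ᵀ, verified
against central finite differences to 1e-5 relative error. Because the
field is continuous over the whole mesh, growth can be evaluated *per
vertex*: F restricted to the local tangent plane and polar-decomposed gives
subcellular principal stretches; the reported heat value is kmax·kmin, the
local area multiplication factor. On generator tissues with an analytic
warp, interior vertices match the true Jacobian within 1%; vertices near
the tissue border are extrapolating beyond the landmark hull, where cubic
RBF error grows — a known limitation of any scattered-data approach.

### Semi-automatic lineage tracking

`auto_parent_label()` recovers the parent map from a handful of seed pairs
by iterating: fit a t1→t0 field from verified correspondences, map
unassigned child centroids, assign each to the nearest t0 centroid, verify
every assignment by neighborhood correspondence (all assigned graph
neighbors of a child must map to its parent or to a neighbor of the parent,
and at least one neighbor must be assigned), clear failures, repeat.

The bare scheme needs numerical safeguards, which are this package's
design:

* **Region growing.** New assignments are restricted to cells adjacent to
  already-verified ones, under a distance gate of 0.6× the local t0
  centroid spacing. Without the gate, a crude early field (three seeds fit
  only a similarity transform) misassigns remote cells whose mutual
  consistency the topological check cannot detect.
* **One landmark per parent.** Verified daughters of a divided mother are
  collapsed to their mean centroid before fitting. Feeding both daughters
  as separate correspondences to one target would force the interpolating
  field to fold space at every division.
* **Erosion to a fixed point.** The verification sweep repeats until
  stable, so incompatible patches erode from their edges instead of
  surviving on the strength of their interior consistency.
* **Geometric trimming.** Topologically self-consistent but *shifted*
  patches (a region assigned wholesale to neighbors of the true parents)
  are invisible to the neighborhood check. A ridge-smoothed field (eps = 2
  on unit-scaled coordinates) fitted to all verified pairs exposes them:
  correspondences whose residual exceeds 0.15× the local spacing are
  cleared worst-first, the field is refitted from the survivors, and all
  children are reassigned.

On the generator's study condition — 200 cells, a smooth non-affine growth
field, 20% of cells divided once, 3 seed pairs — the tracker recovers 100%
of cells with zero false assignments (verified across 8 generator seeds in
development and asserted for the fixed test condition in the suite), and
structures with no t0 counterpart are left unresolved rather than
misassigned. Real time-lapse data adds segmentation errors and cell loss
that the generator does not emulate; the unresolved list is the designed
escape hatch for manual curation there.

### Morphing

Mesh sequences with shared vertex correspondence are interpolated with
centripetal Catmull–Rom splines (alpha = 0.5, no cusps; one-sided endpoint
tangents), linear for two time points. Frames at knots reproduce the inputs
exactly and two-frame morphing is time-reversal symmetric. Heat values are
interpolated alongside positions.

## Division analysis

The *actual* division plane is fitted by PCA of the shared daughter-wall
vertices: plane normal = smallest-variance axis (3D); best-fit line =
largest-variance in-tangent-plane axis (2.5D). *Candidate* planes are
simulated on the merged mother: n = 1000 normals equally distributed on the
hemisphere by a Fibonacci lattice, every plane through the mother's volume
centroid — "the center of the cell" is ambiguous in common usage; the
centroid is our documented choice. Cross-section areas come from
mesh–plane intersection with consistently oriented boundary segments, so
disjoint section polygons of non-convex cells sum correctly (central
sections of a sphere are recovered within 2% at the test resolution). In
2.5D, candidates are chords of the flattened cell polygon through its area
centroid at 1° steps; degenerate vertex crossings are resolved by a tiny
direction perturbation.

Ranking reports the global minimum, local minima (candidates smaller than
all angular neighbors; k = 6 nearest directions in 3D, configurable), and
the actual plane's percentile rank. Daughter size asymmetry is
|s1 − s2|/(s1 + s2). The plane–axis angle is 90° minus the normal–axis
angle, folded into [0°, 90°]: 90° means the plane is perpendicular to the
axis. Raw angles are exported; density smoothing is left to the user
because any bandwidth choice is presentation, not measurement.

## The measure catalogue

2D measures operate on the cell flattened to its tangent plane (the 2.5D
convention). Areas are summed triangle areas; perimeters are boundary
lengths. The principal axes use the *exact* uniform-area covariance of the
polygon (triangle-centroid masses plus the per-triangle second-moment
correction), and axis lengths use the full-extent convention 2·sqrt(3λ) —
chosen, and worth stating prominently, because it reproduces the side
lengths of a rectangle and the extents of solid ellipsoids; other tools
report 2·sqrt(λ), a factor sqrt(3) smaller.

The contour-complexity family is dimensionless and equals 1 for simple
convex shapes: circularity P²/(4πA); lobeyness (perimeter over convex-hull
perimeter); rectangularity (area over minimum enclosing rectangle area, by
rotating calipers); solidarity (hull area over cell area); and visibility.
Visibility is only loosely characterized in common usage ("decreases with
contour complexity"); we formalize it as the probability that the segment
between two uniformly random boundary points stays inside the polygon,
estimated by seeded Monte Carlo (10⁴ pairs, seed 0, convex shapes
short-circuit to exactly 1). As a Monte Carlo estimate it is reproducible
given the seed but only statistically invariant under rigid motion.
`visibility_pavement` = 1 − `visibility_stomata`.

3D measures: volume by the divergence theorem, wall areas by tag, cell
length along any organ direction by ray casting from the volume centroid to
the walls in ±d, and shape analysis by mass-weighted PCA of interior sample
points with anisotropy (max − 0.5 mid − 0.5 min)/(max + mid + min),
elongation max/mid and flatness mid/min.

Network measures: neighbor count, shortest-path betweenness (unnormalized
by default; `inv_wall` weighting uses 1/wall distance) and current-flow
betweenness from the graph Laplacian pseudo-inverse (endpoints excluded,
matching the shortest-path convention; conductance = wall measure when
weighted). A "variability" neighborhood statistic is sometimes named in
this context without a definition; it is deliberately omitted.

Signal measures are area-weighted vertex means over the whole cell, the
border band (vertices within a geodesic width of the outline — computed as
Euclidean distance to the boundary segments, which coincides with geodesic
distance for the flattened star-shaped cells the generator produces) and
the interior remainder.

Tissue curvature fits a full quadric to all mesh vertices within a radius
of each cell centroid in the cell's tangent frame and evaluates the mean
curvature with the exact first-fundamental-form correction; the sign makes
outward bumps positive. Heat-map utilities: neighborhood-mean smoothing,
plateau-aware local maxima (one representative, the lowest label, per
connected equal-value plateau), and half-open binning with per-bin
mean/standard deviation.

## Polarity and fibril orientation

**Border polarity.** The border-band signal is binned by angle about the
cell centroid; each bin's value is its *mean* intensity (signal per unit
border area), and the polarity vector is the resultant of bin means. The
normalization matters: a raw sample resultant is biased by where the border
happens to carry more vertices or area, so an elongated cell with uniform
membrane signal would appear polarized. With bin means, uniform and
symmetric distributions give magnitude ≈ 0 and a single bright patch gives
magnitude → 1. The band is sampled strictly inside the cell (outline
vertices are shared with the neighbor and carry as much of its signal as
the cell's own); the effective bin count adapts to the sample count so bins
average several samples. Planted polarity directions are recovered within
5° on average across 20 generator seeds.

**Fibril orientation.** An adaptation of fibril-texture analysis to labeled
surfaces: per-triangle linear-shape-function gradients of the signal feed
an area-weighted nematic tensor of normalized gradient directions; the
orientation is the eigenvector of the *smaller* eigenvalue (fibrils run
perpendicular to the dominant intensity gradient of a striped texture) and
the anisotropy score (λ1 − λ2)/(λ1 + λ2) ∈ [0, 1]. The orientation is
axial (defined up to sign), invariant to adding a constant to the signal,
and recovers planted stripe orientations within 2°; unstructured noise
yields low anisotropy. The tensor form is validated against synthetic
fields only — no claim is made that it reproduces any particular legacy
implementation bit-for-bit.

**3D wall polarity.** Area-weighted resultant of wall-element signal about
the volume centroid, with magnitude normalized by the total first moment;
signal on one face of a cube points at that face, uniform signal cancels.

## Classification

Thresholding uses half-open intervals (a value at a threshold joins the
upper class). 2D clustering replaces interactive gating with k-means on
z-scored features (standardization is mandatory — the features mix
micrometres, ratios and intensities) or polygon gates evaluated in order.
The SVM (RBF kernel, C = 1, gamma = 1/n_features, one-vs-one) stores its
training-set standardization and reuses it at prediction, making
predictions invariant to feature rescaling. Layer detection clusters the
relative radial coordinate with 1D k-means started from evenly spaced
distinct coordinates (deterministic, no RNG), numbering layers from the
outside in; the surface-distance mode bins absolute distance by a fixed
layer thickness.

## The synthetic generator

The generator *defines* the study conditions under which the package's
claims are tested:

* **Surface tissues**: Lloyd-relaxed Voronoi cells (5 rounds) tiling a
  square domain sized for a mean cell area of 25 µm² — a typical epidermal
  cell footprint — lifted onto a plane, paraboloid or sphere cap, and
  fan-triangulated with optional midpoint refinement. Cell polygons
  partition the domain exactly.
* **3D organs**: concentric layers of watertight wedge cells around a
  straight or bent centerline, with bitwise-matched shared walls and full
  ground truth (layer/sector/ring, mid-layer relative radius). An optional
  single-cell core file provides an explicit axis for spline fitting; the
  default tiling has every layer sectored, so 4 layers × 8 cells × 10 rings
  gives exactly 320 cells.
* **Time-lapse pairs**: vertices mapped through an analytic,
  orientation-preserving deformation (affine; a growth gradient along x;
  bending) whose Jacobian is available everywhere, plus plane-cut divisions
  of a seeded fraction of cells (shortest-wall or random orientation).
  Divisions are exact cuts with re-fanned daughters, so daughter walls are
  straight and `fit_division_plane` is exact on fixtures; original vertex
  indices are preserved, giving an identity junction correspondence.
* **Signal fields**: per-cell polarized accumulation with a planted
  direction, sinusoidal stripes with a planted axial orientation and an
  anti-aliasing guard (wavelength > 2× vertex spacing), uniform, and
  log-normal noise — multiplicative log-normal being the standard model for
  fluorescence intensity statistics.

All generators are bit-reproducible per seed. What passing tests on these
tissues shows is that the *algorithms* are correct under realistic geometry;
they do not show robustness to segmentation errors, anisotropic microscope
point-spread, signal bleed-through between membranes, or cell death — none
of which the generator emulates.

## Problem sizes and numerical defaults

The shipped tests and the acceptance script run at deliberate desk scale,
chosen as the smallest sizes at which each claim is meaningful: 50–200-cell
surface tissues, 320-cell organs, 1000 candidate planes, 10⁴ Monte Carlo
pairs, icospheres at subdivision 3 (1280 triangles). Key defaults:
polyline resolution 1000 samples per Bezier segment; RBF ridge 0 (exact
interpolation) except the tracker's internal smoothing field (eps = 2);
tracking gates 0.6× local / 3× median centroid spacing; division-chord
step 1°; local-minimum neighborhood k = 6; visibility seed 0; border band
1 µm. Each is a package constant with a documented argument, not a tuned
quantity: the values were fixed from the geometry they serve (e.g. the
band must exceed one vertex ring; the chord step must resolve 180 distinct
directions) before the corresponding tests were written.

## Known limitations

* Subcellular growth degrades near tissue borders (RBF extrapolation).
* The lineage tracker assumes the tissue deforms smoothly; it will not
  track large rigid rearrangements or tissue tearing, and reports such
  regions as unresolved.
* TIFF import is exact but blocky; curvature and shape axes on imported
  voxel meshes inherit staircase bias.
* Visibility is a seeded Monte Carlo estimate (reproducible, but only
  statistically invariant under rigid motion).
* 3D division candidates assume the merged mother is watertight; meshes
  failing `validate_mesh()` must be repaired first.
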