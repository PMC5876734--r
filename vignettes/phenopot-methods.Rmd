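---
title: "Measuring potted leafy vegetables from multi-view point clouds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring potted leafy vegetables from multi-view point clouds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopot)
```

## The measurement problem

A potted leafy vegetable (lettuce is the archetype) sits on a turntable and
is scanned by a fixed consumer depth camera from 18 views, one every 20°.
Each view yields a colored point cloud plus the 3D coordinates of markers
fixed to the turntable rim.  From these clouds the package reconstructs the
visible leaf surfaces as a triangular mesh and measures five growth
parameters non-destructively:

* **relative height** `h_R` — pot bottom to plant top,
* **absolute height** — stem base to plant top, via the *soil method*
  (`h_AS`, soil surface stands in for the stem base) or the *plant-bottom
  method* (`h_AP`, lowest in-pot plant point),
* **total leaf area** — the summed triangle area of the mesh,
* **projected leaf area** `S_PA` — the area of the canopy's vertical
  projection,
* **volume** `V` — the union volume of overlapped tetrahedra built over the
  mesh vertices.

All internal computation is in meters in a right-handed turntable frame:
origin at the table center, z up, table surface (hence pot bottom) at
z = 0.  Reports convert to the customary cm / cm² / cm³.

## Pipeline stages and their models

### Registration

Per-view clouds are brought into the turntable frame by orienting the
detected table plane to z = 0 (robust consensus plane fit with a 3 mm
inlier tolerance, refit by total least squares), centering the table, and
undoing each view's nominal rotation.  Marker identities are known from
the input file, so the "iterative closest point" refinement degenerates to
the closed-form orthogonal-Procrustes solution per view against the view-0
markers; classic closest-point matching remains available behind a flag
for marker files without reliable ordering.  Gross outliers are removed by
neighbor checking: a point survives when at least 4 other points lie
within 5 mm (the radius and count are package defaults; they are not
prescribed by the reference workflow).  A pre-denoising pass against
flying pixels removes points farther than 2 mm from the centroid of their
5 mm neighborhood.

### Color segmentation

Colors are converted to HSI with the intensity-mean convention
(I = (r+g+b)/3, S = 1 − min/I, angular hue normalized to [0, 1)).  The
plant / non-plant decision uses two quadric surfaces in (H, S) with scalar
guards:

* plant: `S > 0.1` and `I > 0.05` and `I ≥ f(H, S)`,
* non-plant: `S ≤ 0.1` or `I ≤ g(H, S)`,
* ambiguous: neither.

The shipped coefficients of `f` and `g` were fitted to manually segmented
lettuce training clouds; `fitQuadricBoundary()` reproduces the fitting
step for new cultivars.  In the rare corner where both tests pass (low I,
S slightly above 0.1) the plant label wins: the plant test is the stricter
conjunctive one, and the three-class design reserves "ambiguous" for
points accepted by neither model.  Classification runs on smoothed
reference colors (Gaussian-weighted neighborhood means, radius 5 mm,
σ = radius/2) while the stored colors stay untouched.  Hue is used
linearly without circular treatment: green hues (≈0.2–0.45) are far from
the wrap point, which is a documented limitation for red or purple
cultivars, whose models must be refitted anyway.

### Layered-artifact elimination (MIE)

Time-of-flight multipath can split one leaf into two parallel point
layers when it is seen from both sides.  The elimination step is iterative
midpoint contraction: for each point, the *opposing-layer neighborhood*
is the set of points within 6 mm whose offset direction lies within 60°
of ± the point's normal (|cos| ≥ 0.5) — off-surface, across the gap, on
either side.  Each iteration moves the point half-way toward the midpoint
of itself and that neighborhood's centroid; points without an opposing
layer never move, so clean single surfaces are fixed points of the
operator.  Six iterations collapse a 4 mm two-layer fixture to a single
sheet (each iteration halves the gap), matching the canonical
`IterationTimes = 6`.

The opposition test deliberately uses the *offset direction* rather than
the sign of the two normals: PCA normals are sign-ambiguous, and
consistent orientation propagation across a 4 mm gap orients both sheets
the same way, so a signed-normal test would never fire on exactly the
artifact this stage exists to remove.

### MLS smoothing

Remaining local noise is removed by moving least squares: each point is
projected onto a local order-2 polynomial fit of its 10 mm neighborhood
(Gaussian weights, σ = radius/2).  Planes are reproduced exactly and
gently curved quadric surfaces to ≈1 µm, so the operation is close to
idempotent; points with too few neighbors for the fit pass through
unchanged.

### Meshing

The denoised cloud is down-sampled by deterministic centroid merging
(points processed in index order, merged into the earliest kept point's
running centroid, repeated until every pairwise distance is at least
`PointSpacing`).  Triangles are generated from 16-nearest-neighbor
candidates and kept when (a) all edges are shorter than `TriEdgeLength`
(so discontinuous surfaces are never connected) and (b) no other point
lies strictly inside the circumscribed ball — the Delaunay-like
empty-ball criterion; points exactly on the ball are tolerated so ties
cannot depend on enumeration order, and slivers whose circumradius
exceeds the edge bound are rejected outright.  Four defect filters are
applied in order: duplicate triangles, suspended triangles (no shared
edge), non-manifold edges (three or more incident triangles keep only the
two most coplanar), and triangles whose face normal deviates more than
70° from their mean vertex normal.  Connected components below 1 cm² are
dropped, three-edge holes are closed, and jagged boundaries are smoothed
by moving each boundary vertex to the Gaussian-weighted average of the
boundary vertices within 15 mm *along its boundary loop* (straight
boundaries are therefore fixed points); interior vertices near the
boundary follow with the weighted average of the nearby boundary
displacements.  The 70° and 1 cm² thresholds are package defaults — the
reference workflow names these filters without printing values.

### Pot model and in-pot segmentation

The pot is a truncated cone.  Two horizontal slabs of the non-plant cloud
(z₁ ± Δz and z₂ ± Δz) are fitted with 2D least-squares circles (Kasa's
algebraic fit, exact on noise-free circles); each 3D section center takes
its slab's mean z.  The apex is where the linearly extrapolated radius
vanishes,

F = (O₁ − O₂) · r₂ / (r₂ − r₁) + O₂,

and the cone axis is the O₁O₂ line — real pots tilt, so it is not forced
vertical.  For segmentation the cone is shrunk by η = 0.9 and points are
projected conically from F onto the datum plane 1 m above it; a point is
*in-pot* when its projection falls strictly inside the circle of radius
r_a = η·|r₁/(z_O₁ − z_F)| centered at the projection of O₁ (strict
inequality as specified — boundary points are excluded).  Soil is taken
from the non-plant cloud in z ∈ [0.11, 0.168] m, in-pot plant from the
denoised plant cloud in z ∈ [0.12, 1] m.  The datum plane is kept at
literally 1 m above the apex even though any plane would serve, so the
r_a numbers remain comparable with the reference configuration; the
implementation records the general form
r_a = η·r₁·(z_datum − z_F)/(z_O₁ − z_F) and asserts their equality in
tests.

The 2D circle fit of a *tapered band* has a small positive radius bias
(Jensen: it fits √E[r²]); with the canonical Δz = 5 mm the induced apex
error is a fraction of a millimeter, far below real capture noise.  The
synthetic scene generator can place the slab samples on exact rings
(`potRings = TRUE`) to isolate the apex extrapolation from this bias when
micrometer-level recovery is being verified.

### Growth measures

Heights are order statistics of the processed clouds (max z; mean soil z;
min in-pot z).  The soil method is skipped — the report carries an
explicit `NA`, not a zero — when fewer than `MinSoilPoints = 10` soil
points are visible.  Projected leaf area rasterizes nothing: a grid of
points with spacing `ProjAreaPrecision` is laid over the projected mesh's
bounding box, each point offset half a spacing from the minimum corner
(cell centers), and `S_PA = N_PA · Δd²` counts the points inside at least
one projected triangle.  Volume is analogous in 3D over the union of
overlapped tetrahedra: every 4-subset of mesh vertices with all six
pairwise distances below `TetraEdgeLength` forms a tetrahedron (overlap
is deliberate — it uses every point, unlike a disjoint subdivision), and
`V = N_V · Δd³` counts grid points inside at least one of them.
Point-in-triangle and point-in-tetrahedron tests are boundary-inclusive
with a 1e-12 tolerance.  Grid anchoring at the bounding-box minimum plus
half a spacing makes both estimators fully deterministic; anchoring to a
fixed world origin instead would change counts by O(perimeter/spacing)
points without changing the converged value.

### Calibration

Sensor-to-reference maps are carried as configuration: linear models for
the heights and projected area, saturating power laws `y = a·x^b + c` for
total area and volume (occlusion hides an increasing share of the canopy
as plants grow), plus power-law biomass predictors from volume.  The
shipped coefficients come from a 63-plant lettuce reference data set and
are not re-derived here; `fitCalibration()` provides the fitting utility
(ordinary least squares; power fits by nonlinear least squares with a
log-log initialization).

## The synthetic scene generator

The generator replaces the capture hardware.  A scene is:

* a **pot**: points exactly on a truncated cone, apex (0, 0, −0.085) m,
  half-angle ≈18.43° (radius 0.04 m at z = 0.035), wall from the table to
  z = 0.168 m, terracotta colors;
* a **soil disk** at z = 0.14 m, radius 0.062 m, Gaussian roughness
  (default sd 0.5 mm), brown colors;
* a **canopy** of `nLeaves` parametric leaf patches: ellipses (semi-axes
  a and 0.6a) whose inner tip sits on the stem axis, pitched up 35°, outer
  half drooping quadratically, spread at even azimuths and climbing a
  vertical ladder of 15 mm per leaf.  The ladder and the outer-half-only
  droop keep neighboring leaf sheets farther apart than the denoising
  radii — so MIE and MLS cannot merge distinct leaves — while every leaf
  still overlaps its neighbors in vertical projection near the stem,
  keeping projected area strictly below total area.  Optional sinusoidal
  ruffling (amplitude/wavelength pairs) emulates the curled blades of
  mature lettuce.  Colors are sampled in HSI strictly inside the plant
  acceptance region with a margin of 0.05 in intensity (an optional
  fraction falls between the two decision surfaces, reproducing the
  three-class structure of real training data) and snapped to the 8-bit
  RGB grid that survives PLY round-trips.

Multi-view duplication rotates the scene by −k·360/n about z per view,
transforms four rim markers identically, displaces a random half of the
leaf points along their normals by `layerOffset` (the two-layer ToF
artifact; its magnitude is not characterized in the reference workflow,
so it is a free parameter of millimeter order), and adds isotropic
Gaussian noise.

**Ground truth is computed by oracles independent of the measurement
code:** total area by Gauss–Legendre × midpoint quadrature of the area
element (10⁻⁶ relative accuracy on these surfaces); projected area by
point-in-polygon rasterization of the projected leaf rims at 0.25 mm
pixels (valid because each patch is a graph over its projection at the
slopes used); plant top and stem base analytically; canopy volume by a
coarse occupancy grid over the thickened surfaces.  The same seed yields
bit-identical scenes, and generator seeds never leak into the processing
stages, which are deterministic.

What the generator does **not** emulate: self-occlusion between views
(every surface point is present in every view), sensor-specific radial
noise profiles, color bleeding at leaf boundaries, specular highlights,
and real leaf morphology beyond curved ruffled ellipses.  Passing
recovery tests on these scenes therefore demonstrates the correctness of
the geometry and measurement machinery, not end-to-end accuracy on real
Kinect scans — that is what the shipped calibration models are for.

## Validation fixtures and problem sizes

Two standing experiments are wired into the tests and the acceptance
script:

* **Grid-precision study** (`gridPrecisionStudy()`): three ruffled plants
  of increasing size (4/6/8 leaves, a = 3/4/5 cm — three growth stages at
  desk scale), meshed at the canonical `PointSpacing` 2 mm /
  `TriEdgeLength` 8 mm, yield roughly 1.7–9.5 thousand triangles and
  0.1–0.45 million tetrahedra.  Projected area at Δd = 1 mm and volume at
  Δd = 0.5 mm each stay within 0.2% of their Δd = 0.1 mm references,
  which is why those spacings are the shipped defaults.
* **Clean-scene recovery**: a 4-leaf, a = 6 cm canopy without ruffles on
  a ring-sampled pot, densely sampled (0.6 mm).  Processing radii are
  matched to the data — down-sampling 0.5 mm, edge bound 2.5 mm, MLS and
  boundary smoothing 4 mm — because smoothing strength is a property of
  the noise being removed, and this scene has none; the Table-style
  defaults remain the right choice at Kinect noise and resolution.
  Recovered values: `h_R` and the cone apex to ≈1 µm, soil-method height
  to <0.1 mm, total leaf area within 3% and projected area within 2% of
  the quadrature/rasterization truths.  The residual area deficit is
  boundary erosion: down-sampling pulls rim points inward by roughly half
  the point spacing, so the mesh boundary sits just inside the true leaf
  rim — an intrinsic property of surface reconstruction from samples, not
  of the estimators.

## Numerical choices

* Deterministic neighbor ordering (distance, then index) everywhere, so
  every stage is reproducible.
* Strict-interior empty-ball test with a 1 nm tolerance; boundary ties
  accepted.
* Down-sampling, triangle candidate generation and clique enumeration are
  index-ordered; no stage after data generation consumes randomness
  except the consensus plane fit, which is seeded by the caller.
* Degenerate inputs fail loudly and early: collinear plane/circle fits,
  equal section radii (a cylinder has no apex), projections at the apex
  height, empty clouds where a measurement needs points.
* Near-degenerate tetrahedra (volume < 1e-12 m³) are dropped before
  rasterization; degenerate (vertical-plane) triangle projections
  contribute nothing.

## Known limitations

* Only truncated-cone pots are modeled; other pot shapes defeat the
  in-pot segmentation.
* The default segmentation quadrics are green-cultivar models.
* Thin stems are invisible at the emulated sensor resolution, so stem
  traits are out of reach.
* The mesh represents *visible* surfaces; occluded leaves are absent by
  construction, which is exactly why total area and volume calibrate to
  reference measurements through saturating power laws rather than the
  identity.
* Boundary erosion of order half the down-sampling spacing biases area
  slightly low on sharp leaf rims.

## Session

```{r}
sessionInfo()
```
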