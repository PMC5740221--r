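---
title: "Peak cap stress with heterogeneous intima: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak cap stress with heterogeneous intima: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Finite-element (FE) stress analysis of atherosclerotic plaques usually
treats the intima -- the thickened, heterogeneous plaque tissue that
contains the fibrous cap -- as mechanically homogeneous. Indentation
experiments on human plaque tissue, however, show local shear moduli
spanning two orders of magnitude (roughly 1 to 149 kPa). `plaqhet`
implements a simulation pipeline that quantifies what this heterogeneity
does to the peak cap stress (PCS), the biomechanical marker of rupture
risk: it builds plaque cross-section models, subdivides the intima into
four stiffness clusters from greyscale image intensity, propagates the
full reported stiffness range through a plane-strain hyperelastic FE
solver, and attributes the resulting PCS variance to the individual
cluster stiffnesses with polynomial-chaos Sobol indices.

Because real Movat-pentachrome histology of human coronaries is not
redistributable, the package ships a first-class synthetic-section
generator; every downstream stage is exercised and tested against it.

## Synthetic plaque sections

`section_params()` describes a circular-archetype cross-section: a
circular outer wall (default radius 2 mm, wall ring 0.5 mm) centered at
the origin; an eccentric circular lumen (default radius 0.6 mm) displaced
along $-x$ so the intima is thickest on the $+x$ side; and a crescent
lipid-rich necrotic core on that thick side, defined in polar coordinates
about the lumen center. The core's inner boundary is offset from the
lumen by exactly `cap_thickness`, which makes the minimal cap thickness a
single knob; its outer boundary tapers to zero with a cosine profile over
`core_angular_span`. Infeasible combinations (lumen touching the inner
wall, core hitting the wall) are rejected with an error naming the
violated constraint.

Rasters are rendered at `image_resolution` micrometres per pixel
(default 5, so a 35 um cap spans at least 7 pixels; the analysis scripts
use 10 um/px to keep rasters light). The raster convention is fixed
package-wide: matrices are `[row, col]` with the origin at the top-left
pixel, pixel centers on an integer grid, physical coordinates in mm with
$y$ up. Label codes: background 0 (standing for the gel surround), wall
1, intima 2, core 3, lumen 4.

`render_intima_texture()` emulates the greyscale heterogeneity of a
stained section with latent spatial modes: one Gaussian random field per
mode (white noise blurred at `mode_field_correlation_length`, default
150 um), argmax-thresholded into contiguous patches, each patch assigned
its mode's mean intensity (defaults 40/100/160/220) plus pixel noise
(sd 8). This makes the downstream clustering well-posed but not trivial.
What the texture does **not** emulate: staining physics and colour,
constituent-specific morphology (collagen fibre bundles, cell nuclei),
imaging artefacts, or any relation between intensity and stiffness beyond
"distinct tissue patches look different". Tests passing on these textures
therefore validate the pipeline mechanics, not histological realism.

## Intima clustering

`kmeans_intensity()` implements 1-D Lloyd iteration on the intima pixel
intensities exactly as the study design prescribes: four initial means
drawn uniformly in the observed intensity range, nearest-mean assignment,
mean update, repeated until the means stop changing. Details the
description leaves open are fixed as: assignment ties at midpoints break
toward the lower-mean cluster; an emptied cluster is re-seeded at the
intensity farthest from the surviving means; `n_restarts` (default 10)
independent initialisations are run and the lowest within-cluster sum of
squares kept; labels are relabelled in ascending-mean order so cluster
indices are stable. The per-iteration objective is recorded and its
monotonicity asserted in the tests; on instances of up to 12 pixels the
result is checked against exhaustive enumeration of contiguous optimal
partitions.

`clean_clusters()` performs the "erosion and merging" cleanup as small
component removal: same-label connected components (8-connectivity)
below `min_island_pixels` (default 25, about one 5x5 patch) are merged
into the adjacent cluster whose mean intensity is closest to the
island's own cluster mean, smallest islands first, repeated to a fixed
point. No intima pixel is ever unlabelled, so coverage is conserved, and
the operation is idempotent.

## Stiffness sampling

Cluster shear moduli are drawn by Latin hypercube sampling over
[1, 149] kPa (`latin_hypercube()`, stratified uniform jitter with
independent per-dimension permutations): with `n_samples = 100` each
1.48 kPa stratum of each dimension holds exactly one sample. The
homogeneous reference model uses 75 kPa, the midpoint/mean of the range,
implemented as a configured constant rather than recomputed from
external data.

`build_modulus_map()` assigns each intima pixel its cluster's modulus and
applies Gaussian smoothing to avoid sharp material transitions. The
smoothing is restricted to the intima mask with a kernel renormalized
over the mask, so wall (200 kPa), core (0.5 kPa) and gel (0.001 kPa)
moduli never blend into the intima and the smoothed field is a convex
combination of cluster values (bounded by the sample's min and max; a
constant field stays constant). `smoothing_sigma` defaults to 15 um
(3 px at 5 um/px) -- enough to remove single-pixel transitions without
erasing cluster geometry. Smoothing happens on the pixel grid; element
moduli are then sampled at element centroids.

## Finite-element model

`mesh_section()` builds a structured quadrilateral mesh. The geometry
family is star-shaped about the lumen center, so a mapped ray-by-layer
grid is well posed: rays fan out from the lumen center; radial layers run
lumen, intima (geometrically graded, finest near the lumen so a thin cap
holds at least two layers), wall, then a compliant gel annulus out to
2.5x the outer wall radius whose outer circle is fully fixed (encastre).
Where the core is thick enough to resolve, the two template nodes nearest
the core interfaces are snapped onto them, making the cap band
node-conforming; near the crescent tips the interface is represented by
centroid-based region tags instead, which avoids sliver elements. Region
tags and element moduli are sampled from the label and modulus rasters at
element centroids. The default `target_edge_length` of 0.025 mm yields
roughly 15-20k tissue elements on the default section; the element-count
scaling and a minimum corner angle above 15 degrees are asserted in the
tests. Only 4-node quadrilaterals are generated (the structured grid
never needs triangles).

### Material model and element technology

All tissue is incompressible neo-Hookean with strain energy
$W = C\,(I_1 - 3)$, $C$ the shear modulus and $I_1$ the first invariant
of the left Cauchy-Green tensor; under plane strain the out-of-plane
stretch is 1. Incompressibility is enforced by a volumetric penalty in
the compressible form

$$W = C\,(\bar I_1 - 3) - 2C \ln J + \tfrac{\lambda}{2}(\ln J)^2,$$

integrated with selective reduced integration: the $C$-terms at the full
2x2 Gauss rule, the $\lambda$-term at the element center only. This is
the behavioural contract of constant-pressure "hybrid" elements --
per-element $\det F$ stays within 1% of 1 -- without a mixed unknown.
The penalty is $\lambda = 1000 \max(C, 2\,\mathrm{kPa})$ for tissue (the
floor keeps the 0.5 kPa core volumetric under a ~16 kPa luminal
pressure); the gel surround is deliberately compressible with effective
Poisson ratio 0.2 and $C = 0.001$ kPa, so it suppresses rigid-body
motion while providing only weak support (asserted: outer-ring reaction
below 1% of the lumen load integral).

### Loading, initial stresses, and the solver

Pressures enter in mmHg and convert at 1 mmHg = 0.133322 kPa. Because
the section geometry is imaged while pressure-fixed at 100 mmHg, the
imaged configuration is not stress-free. The initial stresses are
recovered by prestress accumulation: pressure is ramped to 100 mmHg in
`load_steps_image` (default 5) increments on the fixed imaged geometry;
after each converged increment the incremental deformation gradient is
absorbed into a per-Gauss-point history $F_p$ and the displacements
reset; the state is then "settled" (solve/absorb at constant pressure)
until the equilibrium configuration coincides with the imaged geometry
-- the tests require agreement within 0.1% of the lumen radius. The
systolic step then ramps to 120 mmHg (default 2 increments) without
absorbing. One consequence worth knowing: the accumulated $F_p$ depends
mildly on the discrete increment path, so PCS values carry a small
(percent-level on extreme stiffness contrasts) dependence on the load
stepping; all defaults are fixed, so results are exactly reproducible.

The lumen pressure is a follower load on the current boundary. Over the
closed lumen loop it is conservative (the gradient of pressure times
enclosed area), so the full Newton matrix -- material, geometric and
load-stiffness parts -- is symmetric; the linear solver is a sparse
Cholesky whose symbolic analysis is computed once per mesh and updated
numerically, with a sparse LU fallback when the tangent is transiently
indefinite. Newton convergence is a relative residual of 1e-8, with
backtracking line search and adaptive halving of pressure increments
(down to 1/64 of the nominal step) on divergence or element inversion.
Zero load converges trivially to zero displacement and stress.

Stresses are reported as element-centroid Cauchy tensors (center Gauss
point, no nodal extrapolation -- constant-stress reporting avoids
superconvergence artifacts at material interfaces). The cap region is
the set of intima elements radially between lumen and core inner
boundary within the core's angular span plus a `shoulder_margin_deg`
(default 10 degrees; exposed because the angular extent of the
"shoulders" is a modelling choice). PCS is the maximum in-plane
principal Cauchy stress over cap elements at 120 mmHg, ties broken to
the lowest element id.

### Verification

The solver is checked against independent mechanics oracles in the test
suite: inflation of an incompressible thick-walled cylinder against
numerical integration of the 1-D radial equilibrium ODE (agreement within
1% on a refined mesh), the plane-strain Lame solution in the small-load
limit (within 2%), objectivity under rigid rotation (PCS within 0.5%),
mesh-refinement stability of PCS (within 5% under halving of the edge
length), monotonic lumen-area response, and exact reproduction of the
homogeneous result when all four cluster moduli are pinned to 75 kPa.

## Sensitivity analysis

`fit_gpce()` builds a generalized polynomial-chaos metamodel of PCS over
the four cluster moduli, affinely mapped from [1, 149] kPa to
$[-1,1]^4$ with Legendre polynomials (the orthogonal family for uniform
inputs). The basis is orthonormal, so after an ordinary-least-squares
fit the output variance is the sum of squared non-constant coefficients
and Sobol indices need no further quadrature: the main index $S_i$ is
the variance share of terms involving dimension $i$ alone
(`sobol_indices()`), and the aggregate interaction term is
$1 - \sum_i S_i$, so the decomposition closes to 1 by construction
(asserted to 1e-6).

The adaptive scheme starts from the constant term and greedily adds the
candidate whose inclusion most reduces the leave-one-out (LOO)
cross-validation error, computed in closed form from the regression hat
matrix rather than by refitting. The LOO error is normalized by the
output variance, so the 0.001 stopping target is dimensionless; growth
also stops when no candidate improves, when the basis would exhaust the
sample count, or at `max_basis_terms`. The candidate pool is all
total-degree <= 6 terms involving at most two dimensions; higher-order
interactions are opened only if that pool is exhausted short of the
target. Two degenerate cases are handled explicitly: constant outputs
yield the constant metamodel with all indices zero and a flag, and input
dimensions with no variation are excluded from the pool (a constant
input carries no attributable variance, and polynomials in it are
collinear with the intercept).

## Study orchestration and scale

`run_study()` executes the full experiment per plaque -- generate,
texture, cluster, sample, mesh once (all stiffness samples share the
plaque's mesh; only element moduli change), solve 1 + n times, extract
PCS, fit the metamodel -- and assembles tidy tables: per-solve PCS,
per-plaque summaries (median and quartiles by linear interpolation,
`stats::quantile` type 7), Sobol indices, and the ordinary-least-squares
regression of heterogeneous PCS range on homogeneous PCS with $R^2$ the
squared Pearson correlation. Failed solves are counted and excluded
rather than retried; a plaque with more than 20% failures is reported
without summaries. Seeds for every stage derive from the master seed by
hashing (master, plaque id, stage), so stages are independently
reproducible and the whole study is bit-reproducible.

The full design -- 12 plaques, 1 homogeneous + 100 heterogeneous solves
each, 1212 FE runs at ~20k elements -- is what the pipeline is built
for. The shipped analysis scripts and the test suite run a reduced
configuration chosen to keep a desktop run in minutes: 6 plaques with
cap thickness swept 400 to 50 um, 20-30 heterogeneous samples, ~0.12 mm
mesh (roughly 1.4k elements), 10 um/px rasters. At that scale the
qualitative finding -- homogeneous PCS and heterogeneous PCS range rise
together as caps thin -- is asserted as a positive rank correlation;
plaque-specific published stress values depend on the original
histology and are deliberately not asserted anywhere.

## Known limitations

* 2-D plane strain only; no residual (opening-angle) stresses, no
  anisotropy, no viscoelasticity, no fluid-structure interaction.
* The structured radial mesher requires the section to be star-shaped
  about the lumen center -- true for the synthetic family, not for
  arbitrary segmented histology.
* Prestress accumulation reproduces the imaged geometry to the stated
  tolerance but retains a small dependence on the increment path.
* Cluster labels are intensity classes, not tissue constituents; the
  sensitivity indices attribute PCS variance to stiffness classes, not
  to collagen or cells.
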