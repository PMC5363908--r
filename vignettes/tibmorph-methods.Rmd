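---
title: "Automated micro-CT morphometry of tibial epiphyses: models and methods"
author: "tibmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated micro-CT morphometry of tibial epiphyses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In murine surgical models of osteoarthritis (destabilisation of the medial
meniscus, DMM), disease progression remodels the subchondral bone of the
proximal tibia: the compact subchondral bone plate thickens at the expense
of the trabecular bone beneath it, and osteophytes grow at the medial
joint margin. Micro-CT resolves these changes, but manual delineation of
volumes of interest is slow and operator-dependent. `tibmorph` implements
an automated pipeline: rigid surface registration of paired bones, a
macro-porosity criterion that partitions epiphyseal subchondral bone into
plate and trabecular compartments inside fixed-size load-bearing windows,
surface thickness heat maps, and osteophyte volumetry both by registered
shape subtraction and by whole epiphyseal volume — together with the
agreement statistics (Pearson/Spearman correlation, RMS error of
regression residuals, %CV, Bland-Altman limits of agreement) used to
validate such measurements against a reference.

No raw animal scans ship with the package. Instead a synthetic phantom
generator produces epiphysis-like grey volumes with exact, countable
ground truth for every downstream metric; the entire test suite and the
acceptance script run on phantoms.

# Conventions

Volumes are stored with axes (medial-lateral, proximal-distal,
anterior-posterior); "coronal" slices are fixed-AP planes. Voxel indices
are 1-based in R; world coordinates are `(index - 1) * voxel_size_um`.
Intensities live on the 0-255 scale. Which end of the ML axis is medial is
a per-specimen flag (left and right knees mirror each other); meshes of
contralateral bones can be mirrored with `mirror_mesh()` before
registration.

# Binarization and cleanup

Bone is segmented by a global threshold: Otsu's method by default
(exhaustive maximisation of between-class variance over the 256 integer
thresholds, ties resolved toward the lowest threshold), or the fixed
configured value — 60 on the 0-255 scale, the value reported as optimal
for this ex vivo protocol. Foreground is strictly `intensity > t`; the
convention matters for reproducing thresholds exactly and is fixed
package-wide. Morphological cleanup (opening then closing with a 2D disk,
radius 2 voxels by default) runs slice-wise on coronal planes, matching
the disk-shaped kernel of the original workflow; whether morphology
should instead be fully 3D is genuinely open, so both the kernel radius
and the operation list are configuration, not constants.

# Compartment partition

On the middle coronal slice the proximal edge of the plate surface is
detected per ML column, its medial and lateral extremes located, and the
centre of each plateau aspect placed a fixed fraction (default 0.25,
configurable — the original description leaves the "fixed widths"
unquantified) of the ML extent inward from the extreme. Each aspect gets a
window 500 um wide, 350 um deep and 750 um along AP (100 x 70 x 150
voxels at 5 um; 50 x 35 x 75 at 10 um — micrometre geometry is kept fixed
across resolutions). Within a window, each coronal slice is scanned
row-wise from the proximal anchor (the median proximal-edge height of the
window's columns on that slice; windows are flat boxes, as drawn in the
original mappings) downward: the first row whose bone volume fraction
drops below 0.90 marks the plate/trabecular transition (plate =
macro-porosity < 10%). A configuration option can require k consecutive
sub-threshold rows; the default k = 1 is the plain first-crossing rule.

Plate volume is the bone voxel count above the boundary times the voxel
volume. Plate thickness is the mean model-independent local thickness over
the plate mask, computed on the *segmented* plate compartment — the
volume is cut at the detected boundary first. This matters: with the
trabecular lattice still attached, inscribed spheres dip diagonally into
the walls below the plate and inflate the estimate by one to two voxels;
cutting at the boundary reproduces the analytic slab value exactly. The
mean boundary depth is reported alongside as a secondary thickness
metric. Trabecular TV is the region from boundary to window depth, BV the
bone within it, BV/TV their percent ratio. BMD applies a two-point
hydroxyapatite calibration (0.25 and 0.75 g/cm^3) to the mean grey level
of the original (not binarized) volume under each bone mask; whether
pores should be included in the densitometric mask is unstated in the
source workflow, so it is a flag (`bmd_bone_only`, default bone only).

# Local thickness and heat maps

Local thickness is the model-independent definition: the diameter of the
largest sphere fully inside the structure that contains the point,
computed by exact Euclidean distance transform, distance-ridge extraction
and sphere painting. Distances are centre-to-centre, so an even-width
digital slab is exact and an odd-width slab reads one voxel high — the
inherent half-voxel parity of the convention, within every stated
tolerance. Heat maps project, for every (ML, AP) column, the thickness at
the first bone voxel from the proximal side; medial-lateral profiles
average a 750 um AP band (a single mid-plane trace is the degenerate
one-row band, and `max` aggregation is available, since the original
profile methodology does not state the aggregator).

# Registration

Surfaces are extracted by marching tetrahedra (each grid cell split into
the six tetrahedra around its main diagonal; cell faces are always cut
along the same diagonal, so the triangulation is crack-free) after a
1-voxel Gaussian anti-aliasing of the binary interface, which makes areas
and enclosed volumes of digitized spheres accurate to a few percent.
Registration is iterative closest point with a closed-form (SVD, Kabsch)
least-squares rigid fit per iteration and a reflection guard forcing
determinant +1. Correspondences pair each target vertex with the closest
*location on the source surface* (exact closest point on the triangles
incident to the grid-nearest vertex). We initially paired nearest
vertices instead, but vertex-to-vertex ICP has a discretisation floor:
once the residual motion is below the vertex spacing the correspondences
stop improving, and even half-degree perturbations stall at a fraction of
a voxel RMS. Point-to-surface correspondences remove that floor — an
exact copy re-aligns to machine precision — while the fit itself remains
the least-squares rigid fit over corresponding point pairs. Translation
is initialised from the centroids; there is no trimming or outlier
rejection (pairs come from the same animal). Large meshes are subsampled
deterministically (lexicographic order, so the result is invariant to
vertex ordering) on the target side only. Registered meshes are
voxelized back to image stacks at the original scan resolution by parity
counting along grid rays through voxel centres, with a tiny irrational
ray offset so rays never strike triangle edges.

# Osteophyte volumetry

For the registered shape-difference method, both co-registered binary
volumes are closed and dilated with the same disk kernel and
cavity-filled (whole-structure filling: internal architecture is
irrelevant to an outgrowth measurement), then subtracted voxel-wise
(operated minus control, negatives discarded) and intersected with a
medial volume-of-interest — by default the medial third of the ML extent,
since the original fixed-size VOI is unquantified. Applying the identical
morphology to both members of a pair makes the dilation largely cancel in
the subtraction, but not exactly: the difference gains a thin shell on the
protrusion's free surface and loses a slab at its base. The honest oracle
for recovery tests is therefore the same morphology applied to the
noise-free truth masks; against that oracle recovery is within a few
percent, and measured volumes are strictly monotone in the generated
ones. The red/green/yellow overlap decomposition (operated-only /
control-only / shared) is retained for visual export.

The epiphyseal-volume surrogate applies Gaussian filtering (sigma 2
voxels), binarization, closing and dilation, cavity filling, then counts
the total volume. Inputs are epiphysis-only stacks; segmenting the
epiphysis out of a whole tibia is a manual upstream step and out of
scope.

# Validation statistics

Pearson and Spearman correlations use the exact t distribution and the
large-sample approximation respectively; RMS error is the root mean
square of ordinary least-squares residuals with divisor n (the stated
definition is the RMS of residuals, not the residual standard error;
n - 2 is available); %CV is 100 x sample SD / mean; Bland-Altman reports
the bias, 1.96-SD limits of agreement with the sample (n - 1) SD, and the
regression of differences on averages for proportional bias.
`validate_methods()` assembles the per-metric comparison table (means,
SDs, r, RMS error, %CV per method, bias and limits) between an automated
and a reference table — on phantoms the reference is generator truth.

# The phantom generator

The phantom emulates a proximal tibial epiphysis as a flat-topped dome:
a power-8 superelliptic footprint (ML semi-extent 1100 um, AP 650 um,
height 700 um) whose top is flat out to 90% of the normalised footprint
radius with an elliptic shoulder beyond. A compact shell of configurable
thickness follows the outer surface — on the flat top this is exactly the
vertical plate; defining the shell by distance to the exterior (rather
than vertically) also seals the interior at the steep shoulder and
bottom, so cavity filling recovers the solid dome. The interior is a
prismatic honeycomb: two orthogonal wall families (period 100 um, wall
fraction 0.3 by default), giving bone volume fraction 1-(1-f)^2 ~ 51%,
with band edges aligned to multiples of both 5 and 10 um so digitization
is exact at both study resolutions. The first wall sits 40 um below the
plate: far enough that the default closing kernel cannot bridge the gap,
close enough that the line-wise porosity rule sees a sharp sub-threshold
row exactly at the plate bottom — the expected boundary is analytic.
Grey levels are 180 (bone) and 30 (background) with additive Gaussian
noise (SD 10, well below the class separation, so Otsu remains stable and
the fixed-60 fallback stays meaningful); an optional rigid jitter
(nearest-neighbour resampling, with the grid padded so the rotated dome
is never clipped) emulates specimen mis-orientation. Osteophytes are
half-ellipsoids embedded at the medial margin; the semi-axis is
calibrated by bisection so the digitized extra-dome voxel count matches
the requested volume within a fraction of a percent. Truth masks are
noise- and jitter-free, and every scalar truth is recomputable from them
by counting.

The dome dimensions were chosen once so that the windows placed by the
default centre-offset rule sit entirely on the flat top with at least
~190 um of flat margin — the geometric condition under which the
surface-following shell can never dip below the nominal plate depth
inside a window, for plates up to 250 um. What the phantom does *not*
emulate: real trabecular architecture (rods/plates, anisotropy), partial
volume effects, beam hardening and ring artefacts, cortical porosity, or
biological variability. Passing tests therefore demonstrate correctness
of the measurement chain on known geometry, not accuracy on animal
scans.

# Problem sizes and numerical choices

The test suite and acceptance script run phantoms at 5 um (grids around
460 x 160 x 280 voxels) where the ex vivo geometry matters, and at 10 um
elsewhere; registration tests use a 20 um phantom mesh with ~2000-vertex
target subsampling. ICP converges when the correspondence RMS changes by
less than 1e-6 um (at most 100 iterations) and flags non-convergence
rather than failing silently. The EDT treats the outside of the grid as
background. Cavity filling uses 6-connectivity for background, the
standard complement of 26-connected foreground. Degenerate inputs are
errors, not silent results: constant volumes for Otsu, empty masks for
BMD, empty foreground for thickness and meshing, sub-voxel kernels for
morphology.

# Known limitations

Vertex subsampling makes ICP's final RMS depend slightly on the sample;
point-to-plane minimisation, non-rigid registration and intensity-based
registration are out of scope. The compartment windows are flat boxes:
on strongly curved plateaus a curvature-following window would differ
(the original mappings are rectangular too). BMD is a two-point linear
calibration; no multi-point or tissue-mineral-density variant is
provided. The CLI is a thin wrapper over the exported functions, not a
batch framework.
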