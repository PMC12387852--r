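---
title: "Ear-canal segmentation and implant generation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ear-canal segmentation and implant generation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canalseg)
```

## The model

The external ear canal (EEC) is modelled as a truncated cylinder. Its side
walls coincide with the bony canal and are visible in CT as a strong
air/bone intensity step; its two base surfaces are not reliably visible: the
lateral end opens into free air with no contrast at all, and the medial end
is closed by the tympanic membrane, which cone-beam CT resolves poorly. The
pipeline therefore treats the side walls as an image-segmentation problem
and the base surfaces as a geometry problem, supplied by the user as four
landmarks.

Given landmarks A (lateral end, on the axis), B (medial end, on the axis),
C (lateral of A) and D (medial of B), the volume of interest (VOI) is the
set of points within `diameter/2` of the infinite line through A and B that
lie on the non-positive side of both cut planes: the plane through A with
outward unit normal along A→C, and the plane through B with outward unit
normal along B→D. All three containment tests are boundary-inclusive, which
makes rasterisation deterministic for voxel centres lying exactly on a
boundary.

Segmentation inside the VOI proceeds in four steps:

1. **Smoothing.** A separable Gaussian with σ given in millimetres,
   converted per axis to voxel units as `σ / spacing[axis]`, so anisotropic
   grids are smoothed isotropically in world space. The default σ is the
   mean voxel spacing — one voxel's worth of smoothing, enough to suppress
   acquisition noise while moving the apparent air/bone interface by less
   than half a voxel. Boundaries are handled by reflection, which preserves
   the intensity sum of the symmetric kernel.
2. **Thresholding.** `target = "air"` keeps voxels with intensity at or
   below the threshold; `target = "soft_tissue"` keeps a band
   `[lower_bound, threshold]` (the lower bound is a configuration parameter,
   default −200, because CT soft tissue sits in a band rather than a tail).
   When no threshold is given, the default is the midpoint of the 1st and
   99th intensity percentiles inside the VOI — with the VOI's bimodal
   air/bone histogram this lands midway between the two tissue classes, and
   it replaces an interactive threshold slider with a deterministic batch
   rule. Because the Gaussian creates a monotone intensity ramp across the
   interface, moving the threshold within this range fine-tunes the wall
   position (a looser or tighter implant fit) without changing topology.
3. **Connected components.** 6-neighbourhood (face adjacency) labelling,
   matching the conservative connectivity a segmentation should have: two
   regions touching only along an edge or corner are not merged.
4. **Selection.** For each component, the mean over its voxels of the
   Euclidean distance (world mm) from the voxel centre to the **closed
   segment** A–B; the component with the smallest mean wins. Ties break by
   larger voxel count, then smaller label. The segment — rather than the
   infinite line — is used because A and B bracket the canal axially; an
   infinite line would favour middle-ear air cells lying along the extended
   axis. The selected component is flagged if it touches the curved VOI
   wall (radial distance within one voxel spacing of the radius), which
   indicates leakage out of the bony canal: the cut planes must intersect
   the bony wall, otherwise neighbouring air spaces join the canal
   component.

## Measurements

* **Volume** is exactly the foreground voxel count times the voxel volume.
* **Length** is the distance between the centres of the two base faces.
  "Centre" is defined as the centroid of the mask voxels within half the
  maximum voxel spacing of the respective cut plane; this reduces to the
  face centre for axis-aligned cylinders and remains well-defined for
  tilted planes. The slab construction biases each centre inward by up to
  half a voxel, so the measured length of an axis-aligned tube at spacing
  `s` is shorter than the analytic length by up to `s` (exactly `s` when
  the planes are voxel-aligned).
* **Width and height** are measured on the cross-section: the plane through
  the midpoint of the length segment, orthogonal to it. The 3D mask is
  sampled on that plane by nearest-neighbour lookup on a 2D grid whose
  pixel equals the minimum voxel spacing. The width is the longest chord
  through the in-plane midpoint over directions swept at 0.5° steps
  (bounding the angular error of the chord below 0.004·radius), measured
  between the two extreme foreground pixels on the chord line — extreme
  points, not the longest contiguous run, so a chord may bridge a
  concavity. The height is the extent of the whole cross-section projected
  on the in-plane direction perpendicular to the width chord; it is a
  property of the cross-section, not of the midpoint. The in-plane basis is
  anchored to the image grid axes (the axis most orthogonal to the length
  direction), so the sampling pattern co-rotates with the scene and all
  four measurements are invariant under rigid motion of grid and landmarks
  together.

## Implant construction

The implant is the canal segmentation hollowed to a shell and trimmed at
both bases:

* **Hollowing** keeps mask voxels whose Euclidean distance to the nearest
  background voxel centre is ≤ the wall thickness `w`. The distance
  transform is exact and anisotropy-aware (per-axis physical steps),
  computed by a three-pass lower-envelope algorithm over squared distances.
  The comparison is inclusive so that on voxel-aligned grids the shell is
  exactly `w / spacing` voxel layers thick.
* **Trimming** removes shell voxels within `w` of either cut plane (the
  same planes that bound the VOI — the segmentation's base faces lie on
  them by construction). Trimming by geometric plane distance, rather than
  by erosion restricted to the base faces, gives the same result on
  straight tubes and extends unambiguously to tilted planes. The combined
  effect shortens the implant by exactly `2w` — 1 mm at the default
  `w = 0.5` mm — relative to the segmentation, leaving a sleeve whose open
  ends stand clear of the lateral opening and the tympanic membrane.

The implant surface for STL export is the exact boundary surface of the
voxel set: each foreground/background face contributes two triangles with
outward orientation. This mesh is closed, reproduces the label-map volume
exactly, and preserves component count and topology (a voxelised tube has
Euler characteristic 0). The deliberate trade-off versus an interpolating
isosurface (e.g. marching cubes) is blocky facets at the voxel scale —
0.25 mm on the study grids, well below printing tolerance — in exchange for
exact volume bookkeeping and watertightness by construction.

## Validation metrics

* **DSC** `= 2|A∩B| / (|A|+|B|)`; two empty masks count as identical.
* **HD95**: boundary voxels are foreground voxels with a background
  6-neighbour (out-of-volume counts as background). The two directed
  nearest-boundary distance sets (a→b and b→a, exact world-mm distances)
  are pooled and the 95th percentile taken with linear interpolation
  between order statistics. Pooling is the default because the symmetric
  pooled set makes the metric symmetric in its arguments; the common
  alternative — the maximum of the two directed 95th percentiles — is
  available via `mode = "max_directed"`.
* **Rigid alignment** is point-to-point ICP with exact nearest-neighbour
  correspondences and the closed-form SVD (Kabsch) rigid fit; matched MSE
  is non-increasing across iterations. No random restarts: inputs are
  assumed coarsely aligned, as is the case for surfaces derived from the
  same scanner frame.
* **RMS surface distance** is directed (query → reference) by default,
  matching the use of checking an implant surface against the surrounding
  canal; a symmetric variant pools both directions.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a bone block (1500) containing an air canal
(−1000) of length 12 mm and radius 3 mm by default, open laterally into an
air half-space, closed medially by a 0.3 mm soft-tissue membrane (40), with
a 4 mm-radius air cavity beyond the membrane standing in for the middle
ear. The centreline may be a circular arc (constant curvature in a
coordinate plane — sufficient to exercise tilted planes and oblique
geometry without free-form splines) and the radius may taper linearly.
Voxels are isotropic 0.25 mm by default, the spacing typical of temporal
bone cone-beam CT; intensities follow the CT Hounsfield convention because
cone-beam units are scanner-specific and only their ordering matters to the
pipeline. Noise is additive Gaussian with a seeded RNG, so phantoms are
bit-reproducible; the generator calls `set.seed()` with the spec's seed.
The suggested landmarks sit on the centreline ends with C and D displaced
5 mm along the local tangents, and the grid is snapped so the cut planes
fall on voxel boundaries.

The phantom grounds the test suite's claims: with σ = 0 and no noise the
segmentation equals the analytic truth voxel-for-voxel; with defaults the
Dice coefficient against truth exceeds 0.95 (measured ≈ 0.998) and HD95 is
below half a voxel; with noise of 10 % of the air–bone contrast Dice stays
above 0.90. A two-cavity variant adds a parallel decoy canal to exercise
the proximity-based selection rule in both directions (decoy rejected when
the landmarks sit on the canal; decoy selected when they sit on the decoy —
the documented failure mode of misplaced medial planes).

What passing these tests does **not** show: the phantom has sharp two-class
interfaces, no beam hardening, scatter, metal artefacts, partial-volume
mixtures of three or more tissues, anatomical wall irregularity, or
operator variability in landmark placement. Published clinical agreement
figures for this class of method (Dice ≈ 0.9, HD95 ≈ 0.5 mm against manual
segmentation of patient scans) depend on such data and cannot be reproduced
from synthetic phantoms; the phantom establishes algorithmic correctness,
not clinical accuracy.

## Numerical and design choices

* **World frame.** All internal coordinates are LPS (the DICOM convention),
  chosen because the source data of interest is DICOM and a single
  conversion site is easiest to audit. NIfTI affines and Slicer markups
  (RAS) are sign-flipped on x and y at the I/O boundary; exported
  control-point files declare their frame. Measurements are frame-invariant
  either way.
* **Voxel model.** 0-based indices; a voxel's world position is its centre;
  a mask's volume is count × voxel volume exactly.
* **Boundary conventions.** Containment and hollowing comparisons are
  inclusive (`≤`), with a 1e-9…1e-12 guard where floating-point ties are
  possible. Grids in tests are constructed so cut planes fall on voxel
  boundaries, making the `2w` length-reduction identity exact rather than
  approximate.
* **File formats.** NIfTI I/O delegates to RNifti. The NRRD reader/writer
  (raw little-endian encoding, 3D, LPS/RAS spaces) and the DICOM series
  reader (single-frame grayscale slices, explicit/implicit VR little
  endian, uncompressed pixel data, consistency checks on orientation,
  pixel spacing and slice spacing) are minimal purpose-built
  implementations of those format subsets. Binary STL follows the 84 +
  50·F byte layout exactly; ASCII STL is also supported.
* **Degenerate inputs** fail loudly with stage-named messages: coincident
  control points, a VOI missing the volume, an empty threshold result, a
  segmentation that does not reach a cut plane, an implant trimmed to
  nothing, meshes with zero faces.
* **Problem sizes.** Tests and examples run phantoms of roughly
  60×60×120 voxels (0.25 mm spacing) and measurement-convergence checks at
  0.5/0.25/0.125 mm on small analytic cylinders; these sizes make every
  geometric claim testable in seconds while keeping discretisation error
  visibly below the stated tolerances. Convergence tests use a cylinder
  axis slightly off the lattice symmetry axes: a perfectly centred circle
  can have coincidentally equal quantisation error at two successive
  spacings.

## Known limitations

* The threshold default assumes a bimodal VOI histogram; volumes dominated
  by soft tissue need an explicit threshold.
* Width chords bridge concavities by definition; for strongly non-convex
  cross-sections the reported width exceeds any contiguous run.
* The DICOM reader supports uncompressed single-frame series only.
* ICP is a local optimiser; grossly misaligned surfaces need manual
  coarse alignment first.
* The interactive workflow this package automates exposes a rendering
  density control for the VOI preview; it has no algorithmic meaning and
  is intentionally not implemented.
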