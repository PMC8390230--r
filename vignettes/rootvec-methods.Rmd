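---
title: "Vectorizing root system architecture: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vectorizing root system architecture: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootvec)
```

## The problem

Root distribution in the soil determines where a plant can take up
water and nutrients, but three-dimensional root phenotyping lags far
behind above-ground traits because the raw data — X-ray CT or MRI
volumes of pots — are large, noisy, and hard to summarize. For monocots
the root system architecture (RSA) decomposes naturally: each radicle
or crown root is a single curve, so the whole RSA can be represented as
a small set of polylines. `rootvec` implements that vectorization step
and the trait calculations that follow from it, taking as input a
segmented volume (roots bright, soil dark; segmentation itself is an
upstream concern) and a few operator-registered coordinates per root.

Vectorized data are tiny compared to the volumes they summarize, which
makes archiving, sharing, and re-analysis practical.

## Data model

### Volumes

A `RootVolume` is an integer array of 8-bit intensities indexed
`(z, y, x)` with an isotropic voxel resolution in mm. Slices are read
from a directory in lexicographic filename order (zero-padded numerals
recommended); z grows with soil depth and z = 0 is the topmost slice.
The paired writer emits `slice_0000.png`-style names, so write→load
round-trips are bit-identical — an invariant the tests assert.

Coordinates are continuous, 0-based voxel units: voxel `(z, y, x)`
spans the half-open cube `[z, z+1) × [y, y+1) × [x, x+1)` and its
center sits at index + 0.5. Continuous coordinates are necessary
because COG-corrected nodes land between voxel centers. All public
interfaces order coordinates `(x, y, z)`; the z-fastest array layout is
internal. Inputs at higher bit depth are min–max rescaled to 0..255
with a warning rather than rejected, since 16-bit TIFF stacks are
common upstream.

### The RSA tree and rinfo

The RSA is a tree of depth exactly 2: a base node at the seed position,
one inner node per single root, and leaf relay nodes (the operator's
clicks) on each root. An RSA of one radicle and two crown roots is one
base node with three root nodes. Trees serialize to "rinfo" JSON:

```json
{"format": "rinfo", "version": 1, "resolution_mm": 0.3,
 "base": {"xyz": [x, y, z]},
 "roots": [{"id": 1, "interpolation": "cog",
            "relay_nodes": [[x, y, z]], "polyline": [[x, y, z]]}],
 "annotations": {}}
```

The schema is deliberately minimal and self-describing; the version
field guards future drift. Coordinates are stored in voxel units with
the resolution alongside so every physical trait stays recomputable.
Root ids are assigned in registration order and never reused after
deletion. Round-trip identity (field for field, coordinates to 1e-9)
is property-tested over randomized trees.

## Interpolation algorithms

**Straight** connects base and relay nodes in order. It adds no
vertices; duplicate consecutive nodes are collapsed with a warning.

**Spline** fits an interpolating cubic parametric spline through all
nodes — natural cubic splines per coordinate against the chord-length
parameter, zero smoothing — sampled at 10 points per inter-node span.
All registered nodes appear verbatim among the output vertices; with
only two distinct nodes the result degenerates to the straight case,
and fewer than four distinct nodes simply lowers the effective degree.
On five nodes spanning a quarter-circle of radius 50 voxels the sampled
curve stays within 0.5 voxels of the circle (asserted in the tests).

**COG tracking** is the workhorse for noisy volumes. Tracking runs from
the relay node farthest (Euclidean) from the base node, through the
remaining registered nodes in base-ward order, to the base; the output
is reversed to run base→tip so that `z_1` is at the base end, which
makes the angle and RDI formulas directly indexable. Each step:

1. A forward-looking cone (half-angle 45°, length `searchRadius` = 8
   voxels by default) selects candidate voxels. The cone is aimed along
   the current direction of travel; it is re-aimed straight at the
   target node at the start of each leg, once the target is within
   `searchRadius`, or after a step that failed to close in on the
   target.
2. Among above-threshold voxels (threshold 1, i.e. any nonzero voxel),
   only the component 6-connected to the voxels under the tracker
   (within 2 voxels of its position) counts as *the root segment*. The
   new node direction is given by the intensity-weighted COG of that
   component inside the cone, and the tracker advances `step` = 4
   voxels along it (or onto the COG itself when nearer than one step).
3. If no root-segment voxel lies in the cone — or no bright voxel lies
   under the tracker at all — the tracker takes the pure geometric step
   toward the target and **appends no node**. Consecutive geometric
   steps toward one target are collinear, so omitting them never
   changes the polyline geometry; on an all-zero volume the output is
   exactly the straight interpolation.
4. Within `arrivalRadius` (= `step`) of the target, the target's exact
   coordinate is appended, so registered nodes are always preserved
   verbatim.
5. Three consecutive steps without progress toward the target force a
   geometric step — this prevents the tracker from circling the end of
   a root segment when the path to the next node crosses open soil.

### Why these choices

The forward cone bounds the influence of nearby parallel roots, which
is the reason for a narrow search region in the first place. Aiming it
along the direction of travel (rather than at the distant target) is
what lets the tracker follow a bend: a target-aimed cone samples the
inner side of every curve asymmetrically and systematically
underestimates arc length (on the default helical phantom by ~4.5%
even without noise, versus ~0.1% for the travel-aimed cone). The
6-connected component restriction implements "COG of the root segment"
literally: isolated salt-noise voxels — which at realistic densities do
percolate under 26-connectivity but not under 6-connectivity — get no
vote, and with 10% salt noise the helix arc length is still recovered
to within ~0.2%. The momentum is surrendered whenever a step loses
ground, because a track that stops closing in on its target is either
leaving the registered path or circling a segment end.

COG weights use raw 8-bit intensity rather than binary occupancy:
segmented images are graded, and brighter ≈ more root. The step of 4
voxels between COG corrections is the tracking granularity; the
interpolated nodes it produces are what the length integral sees, so
much larger steps chord-sample curves and much smaller ones gain
little (the correction window, not the step, sets the resolution
limit). Ties for "farthest relay" break by registration order.

`maxSteps` defaults to 10·(volume diagonal)/`step`; exceeding it
raises "tracking did not converge" rather than silently truncating.

## Trait calculations

With `P_1 … P_n` a polyline base→tip in voxel units and `r` mm/voxel:

* θ = atan(|z_n − z_1| / √((x_n−x_1)² + (y_n−y_1)²)), in [0, π/2];
  only the two end vertices enter, matching the field convention of
  the angle between the horizontal and the end-to-end chord. A root
  with zero horizontal displacement is vertical: θ = π/2, not an
  error. θ is stored in radians and exported in degrees.
* L = (r/10) Σ √((x_{i+1}−x_i)² + (y_{i+1}−y_i)² + (z_{i+1}−z_i)²) cm.
  All three coordinate differences use the i+1 pattern.
* θ̄ is the arithmetic mean of per-root angles, TL the sum of per-root
  lengths.
* RDI is computed after linear resampling of each polyline at 1-voxel
  arc spacing (original vertices retained; inserted vertices lie on
  existing segments, so geometry and length are unchanged). The
  per-root mean vertex depth, averaged over roots, minus the base
  depth, times r/10, gives the depth centroid in cm. Roots reaching
  above the base node contribute negatively and are averaged as-is —
  the centroid is allowed to be negative for a root system growing
  upward past its base.

CSV export writes a per-root file (`root_id, method, theta_deg,
length_cm`) and a summary file (`n_roots, mean_theta_deg,
total_length_cm, rdi_cm`), numbers at 6 significant digits; an empty
tree yields a summary row with `n_roots = 0` and empty trait fields.

## The phantom generator

Synthetic phantoms make every claim testable without imaging data.
A `PhantomSpec` describes bright tubular roots along parametric
centerlines — straight, helix, sine, cubic Bézier — rasterized by
setting every voxel whose center lies within the tube radius of the
centerline (sampled at 0.25-voxel arc steps) to the root's intensity.
Tubes get flat ends rather than spherical caps, so a straight tube is
a true finite cylinder and its voxel count can be checked against
π r² L. The generator returns the dense centerline polylines, the
closed-form arc lengths (exact for straight and helix, fine
quadrature for sine and Bézier), and the endpoint growth angles.

Noise emulates what segmentation leaves behind in real CT volumes of
soil with voids: salt voxels (a stated fraction set to 255, mimicking
speckle from soil-particle gaps) plus additive Gaussian noise clipped
to [0, 255]. Noise is applied after rasterization under a private RNG
stream seeded from the spec, so identical specs give identical volumes
and the caller's RNG state is untouched.

The default phantom is a single helical root: helix radius 8 voxels,
pitch 64 voxels per turn, 1.5 turns, tube radius 3, intensity 255, in
a 128×64×64 volume at 0.3 mm/voxel. This emulates the gentle 3D
waviness of a rice crown root: the tangent stays ~38° from vertical,
and the end-to-end chord underestimates the true arc length by ~20% —
exactly the regime where straight/spline chording is misleading and
tracking pays off. Phantom sides of 64–128 voxels keep the full test
suite in the tens of seconds on one CPU.

What the phantoms do *not* emulate: partial-volume effects, beam
hardening, intensity falloff with depth, branching laterals, root
crossings, and segmentation dropouts. Passing phantom tests therefore
demonstrates correctness of the geometry and tracking machinery, not
segmentation robustness on real CT data; on real volumes the operator
compensates by registering more relay nodes per root.

## Numerical choices and degenerate inputs

* Duplicate consecutive nodes are collapsed (warning) before
  interpolation; coincident nodes are de-duplicated before spline
  fitting.
* Arrival at a target uses a radius (default = `step`) rather than an
  exact hit; the target's exact coordinate is appended on arrival.
* Resampling walks each segment in exact 1-voxel arc steps, keeping
  the original vertices; the final sub-step of a segment may be
  shorter. A polyline already denser than the spacing is returned
  unchanged.
* Serialization keeps full double precision (`digits = NA`);
  round-trip coordinate error is below 1e-9 by test.
* The intensity threshold treats a voxel as root when
  intensity ≥ threshold, with default 1, so any nonzero voxel counts.

## Problem sizes used in the tests

Trait-formula oracles run on 200 randomized polylines against
brute-force loop implementations (agreement to 1e-9 relative error).
Tracking accuracy uses the default helical phantom (noiseless and with
10% salt), a straight centered tube of radius 3 (centerline RMS < 0.5
voxels), and 20 randomized sinusoidal tubes with 2–10% salt noise for
the COG-vs-straight comparison. The end-to-end pipeline check runs a
two-root phantom (helix + oblique straight root) twice and compares
CSV bytes. `scripts/acceptance.R` recomputes all of these from scratch
at a caller-supplied seed.

## Known limitations

* Depth-2 trees only: no lateral-root hierarchy, no branch-point
  inference, no automatic root detection — registered nodes are the
  contract.
* COG tracking assumes the root segment is locally the dominant bright
  structure near the track; two roots running closer than the search
  radius for an extended stretch can capture each other's trackers
  (registering intermediate relay nodes is the remedy, as in real
  operation).
* Anisotropic voxels are out of scope; resolutions are isotropic
  mm/voxel.
* The rinfo schema is this package's own; compatibility with any other
  tool's native annotation format is not guaranteed.
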