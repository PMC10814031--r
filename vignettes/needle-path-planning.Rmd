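---
title: "Methods: automatic needle path planning for lung tumor ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic needle path planning for lung tumor ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needleplan)
```

## The planning problem

CT-guided thermal ablation destroys a lung tumor in situ by heating it
through a percutaneously inserted needle applicator. Choosing the insertion
trajectory is a constrained multi-objective problem: the straight path from
a skin entry point to the target must avoid every structure that must not be
punctured, stay within the usable needle length, meet the pleura steeply
enough that the needle does not slip along the lung surface, and bury the
ablation zone deep enough in lung parenchyma for hemostasis and applicator
fixation. Among the trajectories that satisfy all of these, clinicians
prefer paths that stay far from vital structures, are short, and meet the
pleura as perpendicularly as possible.

`needleplan` operates on a labeled segmentation volume (integer label map
with voxel spacing in mm; segmentation itself is an upstream task) in which
labels are bound to anatomical roles: skin, target lung lobe, other lung
tissue, tumor, bone, heart, vessels, bronchi, mediastinum. The *target* C is
the tumor centroid — the unweighted mean of tumor voxel centers in world
coordinates. Every boundary voxel of the volume bounding box contributes one
candidate insertion point I, and the segment I→C is one candidate
trajectory. Enumerating boundary voxels directly realizes the corrected
cube-mapping construction at its fixed point: exactly one sight line per
bounding-box surface element, with no perspective-camera bookkeeping, and a
sampling density tied only to the CT grid itself. Edge and corner voxels are
assigned to a single face with the fixed priority x−, x+, y−, y+, z−, z+, so
the number of candidates is exactly `W·H·D − (W−2)(H−2)(D−2)`.

## Hard constraints

Each candidate is classified against four hard constraints; a cell is
feasible iff none fails (an OR-integration of the four blocked layers, with
open cells carrying gray value 1 and blocked cells 0):

* **H1 — organ avoidance.** The segment I→C must not enter any risk
  structure (default risk roles: bone, bronchi, vessels, heart, mediastinum,
  non-target lung). Target-lobe and tumor labels never block.
* **H2 — needle length.** With E the skin entry (first skin crossing from I
  toward C), the percutaneous length `l = ‖E−C‖` must be *strictly* less
  than the configured needle length. Equality fails.
* **H3 — pleural entry angle.** With P the first target-lobe crossing after
  E, the angle α between the path and the lung surface at P must *exceed*
  the threshold (default 20°). α is defined as 90° minus the acute angle
  between the path direction and the surface normal, which makes it
  invariant to the normal's orientation; equality with the threshold fails.
  A path that never reaches the target lobe is treated as blocked (an
  H1-style failure).
* **H4 — insertion depth.** The expected ablation zone (tumor dilated by
  the ablation margin, default 5 mm — the lower bound of the usual 5–10 mm
  coagulation safety margin) is expanded by the depth margin (default
  5 mm); whatever part of the expansion falls outside lung parenchyma is
  treated as a vital structure. Paths crossing that shell would leave the
  ablation zone too close to the pleura.

### Sub-voxel collision model

All collision queries against labeled structures use the 0.5-level set of
the trilinearly interpolated binary mask of the structure — the implicit
surface that a marching-cubes reconstruction of the mask defines. Rays are
sampled at half the smallest voxel spacing and crossings are refined by
bisection to 0.05 mm. Nearest-voxel lookup would instead dilate every
structure by up to the voxel half-diagonal (a tangentially grazing ray sees
the supremum of the staircase surface), which measurably biases occlusion
classification; the interpolated isosurface localizes boundaries to
sub-voxel accuracy from the same label data. `trace_segment()` and
`first_crossing()` keep plain nearest-voxel semantics for label inspection;
the constraint checks use the isosurface membership.

Surface normals for H3 are computed as the normalized negative gradient of
the Gaussian-smoothed (σ = 1 voxel) binary mask of the target lobe (tumor
included so the mask has no internal hole), sampled by central differences
of trilinear interpolation. This avoids the mesh-resolution dependence of
polygon-mesh normals; a sphere-phantom test requires agreement with the
analytic radial normal within 5°.

## Soft constraints and grayscale maps

Over the feasible set, three per-cell raw quantities are measured:

* `d` — minimum distance (mm) from the percutaneous portion E→C to the
  nearest risk structure, read by a per-ray minimum projection through an
  exact anisotropic Euclidean distance transform of the risk mask
  (Felzenszwalb–Huttenlocher, voxel-center to voxel-center distances).
  The minimum is taken over the in-body portion only, since only there can
  tissue be injured; a configuration switch (`s1_full_ray`) restores
  whole-sight-line semantics for fidelity testing.
* `l` — percutaneous length `‖E−C‖` (mm). A cross-check formulation
  (`s2_dtf_mip()`) reproduces it as the per-ray maximum projection of a
  rendered field holding each voxel's distance from C, clipped to zero
  outside the body; the package requires agreement within one voxel
  diagonal on every feasible cell.
* `α` — pleural entry angle (deg) from H3.

Each is normalized to `[0,1]` over the feasible cells:
`R = (d − d_min)/(d_max − d_min)`, `L = 1 − (l − l_min)/(l_max − l_min)`,
`A = (α − α_min)/(α_max − α_min)`, so that larger distance, shorter path and
steeper entry all score higher. Two deliberate choices:

* The normalization extrema are taken over *feasible* cells only. Scores
  are only ever compared among feasible candidates; whole-map extrema would
  let infeasible outliers compress the usable range.
* The `A` score increases with the angle. The printed form of the angle
  normalization in the source formulation decreases with the angle, which
  contradicts both the stated clinical goal (as-large-as-possible entry
  angle) and the >70° excellence criterion; the package follows the
  clinical goal and keeps the inverted orientation available behind
  `s3_printed_form = TRUE`. The two are never mixed or averaged.

If a raw quantity is constant over the feasible set (degenerate range), all
its scores are set to 1: every candidate satisfies that preference equally.

## Pareto selection and ranking

The final selection intersects the three pairwise 2D Pareto fronts —
(R,L), (R,A), (L,A) — and ranks the intersection by the weighted sum
`G = λ1·R + λ2·L + λ3·A` with `λ1 = λ2 = λ3 = 1/3` by default (the
aggregation is written as a sum; a weighted-product option exists for
sensitivity analysis only). Each 2D front is built by the sort-and-prune
sweep — sort descending by the first objective then the second; repeatedly
promote the best unprocessed point (with its exact duplicates) and prune
everything whose second objective does not exceed it — which provably equals
the O(n²) weak-dominance oracle (dominance = ≥ on both axes, > on at least
one; duplicate vectors are all retained). The pairwise intersection can be
empty, because points non-dominated in different pairs need not coincide; in
that case the full 3D non-dominated set is used instead and the result is
flagged (`fallback = TRUE`). Every 2D-front member is 3D non-dominated, so
the fallback is a superset of the intended set. Ties in G are broken by
(R, L, A, cell id) lexicographically, making the ranking deterministic and
invariant under input permutation. Weights that do not sum to one are
renormalized with a warning rather than rejected.

If no cell survives the hard constraints the planner returns a distinct
`"no-feasible-path"` outcome naming the constraint that eliminated the most
cells — never an error.

## The synthetic thorax phantom

Clinical CT label maps cannot ship with the package, so a deterministic
analytic phantom stands in: a body ellipsoid with a 4 mm skin shell, two
lung ellipsoids, a mediastinal compartment, a heart ellipsoid, trachea and
main bronchi as capsules, pulmonary vessels as capsules, ribs as circular
arc tubes whose ring radius follows the body taper, and a spherical tumor
inside the right lung. The default scene is 128³ voxels at 2 mm — a
256 mm adult-scale thorax — with 12 ribs (4 mm tube radius, 12 mm
spacing, a 60° anterior gap) and a 15 mm-diameter tumor. Structures are
rasterized in the fixed order body < mediastinum < lungs < heart < bronchi
< vessels < ribs < tumor, and the geometry is arranged so that no non-risk
structure rasterized later overlaps a risk primitive, keeping the voxel
labels consistent with the analytic primitives. The phantom is
mirror-symmetric about the sagittal plane except for the tumor, which
enables mirror-image feasibility tests. The only randomness is an optional
seeded uniform jitter of the tumor center (the acceptance script uses
±2 mm); identical spec and seed give bit-identical volumes.

Because every primitive is analytic, an exact occlusion oracle exists:
`shadow_oracle()` declares a face cell occluded iff the segment I→C
intersects any risk primitive, testing closed-form point–primitive
membership at 0.1 mm inside analytically clipped per-primitive intervals —
entirely independent of the voxelization. The oracle-equivalence check runs
on the `ribarc` preset (adult-scale body and lungs plus a single
anatomically thick rib arc, 6 mm tube radius): voxelized occlusion must
agree with the oracle on at least 99% of face cells, and every disagreement
must lie on a sight line grazing a primitive surface within one voxel
diagonal. With a full multi-rib cage at 2 mm spacing the fraction of such
razor-tangent sight lines along the many rib silhouettes exceeds 1% of all
cells — those rays are genuinely undecidable from 2 mm labels (we measured
~97% raw agreement for an eight-rib cage, with disagreements confined to
the grazing band) — so the cage scene is used for the band-confinement and
monotonicity properties rather than the raw agreement figure.

What the phantom does *not* emulate: real CT intensities (labels only),
segmentation error, lobar fissures, respiratory motion, or tissue and
needle deformation. Passing the phantom suite therefore demonstrates the
geometric and algorithmic correctness of the pipeline on exact label maps,
not robustness to segmentation noise or motion.

## Independent verification

`verify_plan()` re-checks every returned path against H1–H4 with a separate
pure-R tracer that shares no code with the planner's C++ classification:
its own trilinear interpolator and bisection, its own local-patch surface
normal, and a brute-force reconstruction of the H4 shell from exhaustive
nearest-tumor-voxel distances. It also evaluates the three excellence marks
(distance > 10 mm, length < 100 mm, angle > 70°), with the risk distance
recomputed by brute force against risk voxel centers. The planner's
returned paths must pass this re-verification at a rate of 100% — that is
the package's construction-guaranteed headline property, recomputed from
scratch by `scripts/acceptance.R`.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `needle_length_mm` | 150 | mm | usable applicator shaft length; H2 bound. A common microwave antenna shaft length; no single value is canonical, so it is explicit in the configuration. |
| `angle_threshold_deg` | 20 | deg | minimum pleural entry angle (H3), the usual clinical slippage threshold |
| `ablation_margin_mm` | 5 | mm | tumor-to-ablation-zone safety margin (H4) |
| `depth_margin_mm` | 5 | mm | required lung depth beyond the ablation zone (H4) |
| `weights` | (1/3, 1/3, 1/3) | — | soft-constraint weights λ1–λ3 |
| `top_k` | 5 | — | number of ranked paths returned |
| `ray_step_mm` | half min spacing | mm | ray sampling step; must not exceed the smallest spacing |

## Numerical choices and degenerate inputs

* Coordinates: 0-based voxel indices, voxel-center world mapping
  `world = origin + index·spacing`, all geometry in mm. Oblique direction
  matrices are rejected at load time.
* Distance transform: exact squared-distance lower envelope per axis with
  anisotropic spacing; background is seeded with a large finite squared
  distance (1e15 mm²) so obstacle-free scan lines stay well defined. The
  result is property-tested against an all-pairs brute-force oracle to
  1e-9 mm.
* Crossing refinement: bisection to 0.05 mm (reported boundary within
  0.1 mm of the discrete surface).
* Empty risk set (a scene with no risk roles): H1 never fails and all
  S1 scores are 1.
* Zero-gradient normals (flat mask interior): treated as tangential
  (α = 0), which fails H3 rather than silently passing.
* Problem sizes in the shipped tests: the default 128³ phantom for the
  end-to-end and consistency checks (~97 000 candidate trajectories,
  planned in a few seconds), the 48³ mini phantom for fast unit tests, the
  128³ single-rib scene for oracle equivalence, 200 random instances up to
  n = 500 for the Pareto oracle, and 50 random masks up to 20³ for the
  distance-transform oracle.

## Known limitations

* Single straight needle only; no multi-needle plans, no curved
  trajectories, no coagulation-zone simulation.
* No modeling of respiration, tissue deformation, or needle bending.
* Lobar fissures are only representable if segmented as part of the
  non-target-lung or mediastinum roles.
* The verifier shares the scene's label data with the planner (it is a
  check of the classification, not of the segmentation).
* NIfTI is the supported volume format in this implementation.
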