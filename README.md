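# needleplan

Automatic needle trajectory planning for CT-guided percutaneous thermal
ablation of lung tumors.

Preoperative path planning for lung ablation is a constrained
multi-objective problem: the straight trajectory from a skin entry point to
the tumor must avoid bones, airways, vessels, heart, mediastinum and the
non-target lung (**H1**), keep the percutaneous length strictly below the
needle length (**H2**), meet the pleura at more than 20° to avoid needle
slippage (**H3**), and insert deep enough into lung parenchyma that the
ablation zone is not subpleural (**H4**). Among feasible trajectories,
clinicians prefer paths that are far from vital structures (**S1**), short
(**S2**), and as perpendicular to the pleura as possible (**S3**).

`needleplan` takes a labeled CT segmentation (NIfTI integer label map plus a
JSON role binding) and:

1. enumerates one candidate trajectory per boundary voxel of the volume
   bounding box, aimed at the tumor centroid `C` — the cube-mapping
   construction taken to one exact sight line per bounding-box surface
   element (`W·H·D − (W−2)(H−2)(D−2)` candidates);
2. classifies every candidate against H1–H4, using sub-voxel isosurface
   collision tests, an exact anisotropic 3D Euclidean distance transform,
   and smoothed-mask surface normals;
3. builds three grayscale soft-constraint maps and normalizes them over the
   feasible set:
   `R = (d − d_min)/(d_max − d_min)`,
   `L = 1 − (l − l_min)/(l_max − l_min)`,
   `A = (α − α_min)/(α_max − α_min)`;
4. intersects the three pairwise Pareto fronts of (R, L, A) and ranks the
   survivors by the weighted score `G = λ1·R + λ2·L + λ3·A`
   (λ = 1/3 each by default), returning the top-k paths with full
   provenance;
5. independently re-verifies every returned path against H1–H4 with a
   separate pure-R tracer.

A deterministic analytic thorax phantom (body, lungs, mediastinum, heart,
bronchi, vessels, ribs, tumor — all closed-form primitives) makes the whole
pipeline testable without clinical data, including an exact geometric
occlusion oracle that is independent of any voxelization.

## Worked example

```r
library(needleplan)

spec  <- phantom_spec("default")       # 128^3 voxels at 2 mm, 12 ribs
scene <- generate_phantom(spec)
plan  <- plan_paths(scene, plan_config())
plan
#> <plan_result> ok
#>   candidates: 96776 | feasible: 24693
#>   top 5 paths (G = weighted score):
#>   rank face  d_mm  l_mm alpha_deg      G
#> 1    1   y+ 13.81 80.09     64.89 0.7584
#> 2    2   y+ 13.83 79.68     64.33 0.7582
#> 3    3   y+ 13.80 79.53     64.08 0.7569
#> 4    4   y+ 13.77 79.94     64.55 0.7566
#> 5    5   y+ 13.90 80.59     64.39 0.7559
```

Of the 96 776 candidate trajectories, 24 693 satisfy all four hard
constraints; the five best enter through the anterior chest (`y+` face),
staying 13.8 mm clear of the nearest risk structure (`d_mm`) over an
80 mm percutaneous path (`l_mm`) with a ~64° pleural entry angle
(`alpha_deg`). `G` is each path's weighted aggregate score in [0, 1].

```r
report <- verify_plan(plan, scene)
report
#> <run_report> pass rate: 100.0% | excellent rate: 0.0%
```

The independent verifier re-traces each returned path and confirms all four
hard constraints (pass rate 100%); it also reports the per-path excellence
marks (distance > 10 mm, length < 100 mm, angle > 70° — here the first two
hold for every path and the angle mark for none, so the all-three excellent
rate is 0%).

Results serialize to JSON (`write_plan_json()`), 16-bit TIFF face maps
(`write_face_maps()`) and VTK polylines (`write_vtk_paths()`). A
command-line front end with `phantom`, `plan` and `verify` subcommands is
installed at `system.file("cli", "needleplan.R", package = "needleplan")`.

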