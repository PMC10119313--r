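# articmorph

Quantitative morphometry of articular surfaces on triangulated bone
meshes, built around the first and second tarsometatarsal (TMT) joints of
the midfoot — the articulations of the medial and intermediate cuneiforms
with the first and second metatarsal bases.  Surgical procedures in this
region (Lisfranc injury fixation, TMT arthrodesis) need quantitative
knowledge of articular surface size, shape and curvature that
dissection-based anatomy cannot provide; this package computes those
quantities automatically from segmented bone-surface meshes, and ships a
synthetic phantom generator with analytic ground truth so that every stage
is testable without imaging data.

It is aimed at skeletal-morphology and orthopaedic-biomechanics
researchers working with micro-CT or clinical CT bone segmentations.

## What it computes

Given a closed bone mesh in mm (STL/PLY/OBJ):

* **Per-vertex principal curvatures** k1 ≥ k2 (1/mm) by Gaussian-weighted
  local polynomial height fits over a configurable fitting radius, in the
  convex-negative convention (a convex sphere of radius r has
  k1 = k2 = −1/r), plus the sign-attributed Gaussian curvature
  K_signed = sign(−(k1+k2))·|k1·k2| (convex positive, concave negative,
  1/mm²).
* **Articular surface extraction**: the connected region with
  k2 ≥ threshold (flatter than the threshold) bounded by the
  high-curvature rim, with interior holes filled.  Default thresholds:
  −0.25 1/mm (medial cuneiform, first metatarsal), −0.35 1/mm
  (intermediate cuneiform, second metatarsal).
* **Automatic anatomic frames** from surface centroids and directional
  extrema: proximal–distal, dorsal–plantar and medial–lateral axes with
  the analyzed surface centroid as origin.
* **Morphometry** in the anatomic frame: surface area, maximal width and
  height, signed medial/lateral width profiles every 2 mm of height, and
  the dorsal-medial / plantar-medial / dorsal-lateral / plantar-lateral
  quadrant split.
* **Curvature similarity** of opposing surfaces,

  s(k_cun, k_met) = −sign(k_cun·k_met) / (1 + |ln|k_cun/k_met||) ∈ [−1, 1],

  where +1 means equal magnitudes with matched curvature (one concave, one
  convex — a congruent pairing), −1 equal magnitudes with mismatched
  curvature, and values near 0 a large magnitude mismatch.
* **Cohort statistics**: means/SD/95% CI, paired and one-sample t-tests,
  Shapiro–Wilk, main-effects three-way ANOVA (Type II SS) and
  Games–Howell post-hoc comparisons.
* **Synthetic phantoms**: bone-like closed meshes whose articular caps are
  spherical patches of prescribed curvature and extent, with cap
  membership, curvature, frames, extents and joint similarity known in
  closed form, plus voxelization/remeshing and surface-noise operators to
  emulate image provenance.

## Worked example

Generate a phantom first-TMT joint with known ground truth, then recover
its cuneiform articular surface, frame, extents, curvature and similarity:

```r
library(articmorph)

jp <- make_joint_phantom(k_cun = 0.003, k_met = -0.004, gap = 2,
                         extents = list(cun = c(width = 18.2, height = 29.2),
                                        met = c(width = 17.6, height = 28.5)),
                         resolution = 0.3, joint = "TMT1", seed = 1)
bone <- jp$cuneiform

field   <- principal_curvatures(bone$mesh, fitting_radius = 1.5)
surface <- extract_articular_surface(
  bone$mesh, field, threshold = -0.25,
  seed_point = surface_centroid(surface_patch(bone$mesh, bone$truth$caps$distal)))
prox    <- extract_articular_surface(
  bone$mesh, field, threshold = -0.25,
  seed_point = surface_centroid(surface_patch(bone$mesh, bone$truth$caps$proximal)))
frame   <- cuneiform_frame(prox, surface, "medial",
                           dorsal_hint = c(0, 1, 0), side = "right")
max_extents(surface, frame)

sm     <- patch_submesh(surface)
gfield <- principal_curvatures(sm$mesh, fitting_radius = 10)
k_cun  <- region_mean_curvature(gfield, sm$patch)
curvature_similarity(k_cun, jp$k_met)
```

Output from this run:

```
surface_patch: 34065 faces, area 471.301 mm^2
   width   height
18.08287 29.01170
mean signed Gaussian curvature: 0.00299 1/mm^2 (truth 0.00300)
similarity vs the opposing metatarsal truth: 0.7751 (closed form 0.7766)
```

The extracted surface recovers the generator's 18.2 × 29.2 mm cap within a
mesh edge length, the prescribed convex curvature of +0.003 1/mm² to
three decimal places, and the joint's closed-form similarity within 0.002.

A full cohort run mirrors the study layout — 24 phantom joints, report
tables for size, width profiles, curvature and similarity, and the
statistics battery:

```r
co  <- phantom_cohort("phantoms", n_joints = 24, seed = 7)
res <- run_pipeline("phantoms/manifest.csv", pipeline_config(), outdir = "report")
```

writing `table1_size.csv`, `table2_profiles.csv`, `table3_curvature.csv`,
`table4_similarity.csv`, `stats_report.csv` and a run log with the full
configuration echo.

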