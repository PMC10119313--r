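---
title: "Articular-surface morphometry with articmorph: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Articular-surface morphometry with articmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

articmorph quantifies the size, shape and curvature of subchondral articular
surfaces on triangulated bone meshes, with the first and second
tarsometatarsal (TMT) joints — medial cuneiform vs first metatarsal and
intermediate cuneiform vs second metatarsal — as the target anatomy.  This
vignette is the package's account of its methods: the models and conventions,
the parameters that matter, the numerical choices, what the synthetic
phantoms do and do not establish, and the known limitations.

## The analysis in one paragraph

A bone arrives as a closed triangle mesh in millimetres (typically exported
from micro-CT segmentation).  Per-vertex principal curvatures are estimated
by local surface fitting; the articular surface is the connected region of
low second-principal curvature bounded by the high-curvature rim, selected
by thresholding and cleaned by interior-hole filling.  Centroids of the
articular surfaces (and, for metatarsals, the bone's volume centroid)
anchor an automatic anatomic coordinate frame.  In that frame the package
measures surface area, maximal medial–lateral width and dorsal–plantar
height, and a width profile at fixed 2-mm height steps; the surface is also
cut into dorsal-medial, plantar-medial, dorsal-lateral and plantar-lateral
quadrants.  Mean signed Gaussian curvature is computed per surface and
quadrant, and opposing surfaces of a joint are compared by a curvature
similarity statistic in [-1, 1].  A cohort layer aggregates specimens and
runs the statistics battery (summaries with 95% CIs, paired and one-sample
t-tests, Shapiro–Wilk, main-effects three-way ANOVA, Games–Howell post
hoc).

## Sign conventions

Everything downstream depends on one convention, fixed package-wide:
**principal curvatures are convex-negative.**  A convex sphere of radius
$r$ has $k_1 = k_2 = -1/r$; flat regions sit near zero; sharp convex rims
are strongly negative.  This is the convention under which an extraction
threshold such as $-0.25\,\mathrm{mm^{-1}}$ classifies *flatter* areas as
values *greater than* the threshold.

Raw Gaussian curvature $K = k_1 k_2$ cannot distinguish convex from
concave (both elliptic cases give $K > 0$).  Because the analysis needs a
convex-positive / concave-negative reading — and the similarity statistic
needs a sign — the package uses the *sign-attributed* Gaussian curvature

$$K_{signed} = \operatorname{sign}(-(k_1 + k_2)) \cdot |k_1 k_2|,$$

i.e. the magnitude of $K$ carrying the sign of the (negated) mean
curvature: positive on overall convex surfaces, negative on concave ones,
zero where $k_1 + k_2 = 0$.  On elliptic patches (the relevant regime for
these joint surfaces) this coincides with the intuitive convex/concave
reading; on strongly hyperbolic patches the attribution follows the mean
curvature, which is the only continuous choice.

## Curvature estimation

For each vertex, all vertices within Euclidean distance $r_{fit}$ (the
*fitting radius*) are collected through a spatial hash, and a polynomial
height function is fitted by weighted least squares in the tangent frame of
the area-weighted vertex normal.  Principal curvatures are the eigenvalues
of the shape operator assembled from the first and second fundamental forms
of the fit at the origin.

Two numerical choices deserve explanation:

* **Fit degree (default: up to 4).**  A pure quadric
  $z = ax^2 + bxy + cy^2$ carries a systematic truncation bias of order
  $(r_{fit}/R)^2$ on a surface of curvature radius $R$ — about 5% per
  principal curvature when $r_{fit}/R = 0.5$, i.e. 10% on Gaussian
  curvature, which is far too coarse for calibration against analytic
  shapes.  Adding cubic and quartic terms (with linear terms to absorb
  normal-estimate error) removes this bias; the unit-sphere Gaussian
  curvature magnitude is then recovered to well under 1% even with a
  fitting radius of half the sphere radius.  The degree adapts downward
  when neighborhoods are small.  High-order fits amplify measurement
  noise, however, so `max_degree = 2` is recommended (and used in the
  robustness tests) when thresholding curvature on voxelized or noisy
  meshes; the quadratic fit's bias is irrelevant there because the
  threshold separates values an order of magnitude apart.
* **Gaussian distance weights** ($\sigma = r_{fit}/2$) localize the fit
  within the ball.  On smooth surfaces weighting does not bias the
  estimate; at curvature discontinuities (the articular rim) it sharpens
  the flat-to-curved transition, which makes the extracted boundary land
  close to the true tangency line.

Vertices with fewer than 6 support points have their radius grown by 50%
up to three times, then are flagged failed (`ok = FALSE`) and excluded from
region averages.  Very dense neighborhoods are subsampled deterministically
(default cap 500 points).

Two fitting radii appear in the pipeline, and they play different roles:
the *extraction* radius (default 1.5 mm) used to threshold the whole bone,
and the *Gaussian* radius (default 10 mm, roughly half the articular
surface height) used to average curvature over the extracted surface part.
The 10-mm stage is computed on the exported articular patch as its own
mesh, not on the whole bone — a 10-mm ball around a surface vertex would
otherwise swallow the rim and shaft and the height-function model would
break down.

## Extraction

Faces whose three vertices all satisfy $k_2 \ge$ threshold form the
candidate set; requiring all three vertices is deliberately conservative —
isolated noisy vertices punch holes rather than bridge across the rim, and
interior holes are refilled afterwards.  Connected components are computed
by edge adjacency; the component containing (or nearest) an optional seed
point is selected, else the largest by area.  Interior holes (every
boundary loop except the longest) are fan-triangulated from the loop
centroid; holes on these surfaces are small and near-planar, so the
simplest deterministic triangulation suffices.  Default thresholds are
bound to bone labels: $-0.25\,\mathrm{mm^{-1}}$ for the medial cuneiform
and first metatarsal, $-0.35\,\mathrm{mm^{-1}}$ for the intermediate
cuneiform and second metatarsal, both overridable.

Degenerate configurations are errors, not silent results: a threshold that
excludes the whole surface, and a "flat" set that covers the entire mesh
(no bounding high-curvature region — e.g. a sphere).

## Anatomic frames

Axis conventions: `axis_pd` points distal-ward (proximal→distal surface
centroid in cuneiforms; proximal surface centroid→volume centroid in
metatarsals, only the proximal bone end being available in the images this
emulates); `axis_dp` always points dorsal; `axis_ml` always points medial.
Axes are Gram–Schmidt-orthogonalized in the order PD → DP → ML, because
the raw centroid/extremum constructions are not exactly orthogonal and the
extent and profile measures require an orthonormal frame.  The origin is
always the centroid of the analyzed articular surface.

A frame whose axes are *anatomically* fixed cannot be right-handed on both
sides: articmorph keeps ML medial on both sides, so
$\det(\mathbf{ml}, \mathbf{dp}, \mathbf{pd}) = +1$ on the right and $-1$
on the left.  Signed medial/lateral distances in the width profile then
mean the same thing on both sides.

The dorsal (and for MT1, lateral) *orientation hints* are required inputs.
The extremum constructions ("most dorsal points", "most plantar point",
"most lateral points on the dorsal and plantar halves") need a reference
direction that scan orientation supplies implicitly in practice; the hint
makes it explicit, defaults to scanner +z, and only needs to be right to
within about 85 degrees (it is orthogonalized against PD; within 5 degrees of
PD it is rejected as ambiguous).  For MT1 the dorsal/plantar halves are cut
by the hint-derived dorsal direction, which breaks the chicken-and-egg
between the halves and the DP axis.

## Morphometry

Maximal width/height are coordinate spans of the patch vertices along ML
and DP.  The width profile projects the patch's outer boundary loop onto
the frontal (ML–DP) plane through the surface centroid and intersects it
with lines parallel to ML at heights spaced every 2 mm (the approximate
thickness of an arthrodesis saw blade — the clinically meaningful step, so
heights are deliberately *not* normalized to bone size).  At each height
the *outermost* crossings are kept, with signed values: the medial distance
is the signed ML coordinate of the outermost medial crossing and can be
negative when the contour at that height lies entirely lateral of the DP
axis, as happens at the far plantar heights of real medial cuneiforms.
Heights with no crossing are flagged absent; the cohort report keeps a
height only when at least half the specimens contribute (min-n rule,
12 of 24 at study scale), but also writes the unfiltered table.

Quadrants are assigned per face by the sign of the face centroid's DP and
ML coordinates, which yields an exact area partition (vertex-based
assignment would double-count boundary vertices).

## The curvature similarity statistic

For a joint, let $k_{cun}$ and $k_{met}$ be the mean sign-attributed
Gaussian curvatures of the opposing surfaces.  The similarity is

$$s(k_{cun}, k_{met}) = \frac{-\operatorname{sign}(k_{cun} k_{met})}
{1 + \left|\ln\left|k_{cun}/k_{met}\right|\right|}$$

with natural log by default (the base changes only the decay rate, never
the $\pm 1$ landmarks; it is configurable).  $+1$ means equal magnitudes
with matched curvature — one convex and one concave surface, the congruent
pairing; $-1$ equal magnitudes with mismatched curvature (two convex or
two concave); the value decays toward 0 as magnitudes diverge.  When either
input is numerically zero ($|k| < 10^{-9}$) the value is defined as 0: the
statistic carries no information about flat surfaces, and 0 is the limit
of "no information" consistent with its interpretation.  Quadrants are
paired by identical anatomical label (dorsal-medial with dorsal-medial,
and so on); mirror-pairing across the joint is a defensible alternative
the package does not implement.

## Statistics

All standard machinery is delegated: `t.test`, `shapiro.test` (Royston's
approximation), `lm` with `car::Anova` for Type II sums of squares, and
`ptukey`/`qtukey` for the studentized range.  Choices that were genuinely
open:

* The three-way ANOVA is main-effects only with Type II SS: the factor
  sets (region/bone, specimen, side) leave no replication to identify
  interactions at study scale, and Type II is robust to the mild imbalance
  caused by absent regions.  Specimen is treated as a fixed factor; a
  mixed model with specimen as a random effect would be the modern choice
  but changes the question being asked.
* Games–Howell is implemented directly (Welch-type standard errors,
  Welch–Satterthwaite df, studentized-range reference at
  $q = |t|\sqrt{2}$), since no installed package provides it; it is
  validated against an independent implementation and by a seeded
  null simulation of its family-wise error rate, and it reduces to Tukey
  HSD as variances and sizes equalize.
* One-tailed one-sample t-tests choose their direction from the sample
  mean unless a direction is given.  Zero-variance samples at the null
  return $p = 1$ by convention.

## Synthetic phantoms: what they emulate and what they prove

The phantom generator replaces cadaveric specimens for validation.  A
phantom bone is a closed prism-like solid whose end caps are *spherical
patches* over elliptical extents, joined to the body by a
tangent-continuous circular fillet (the "rim").  Spherical caps are the
deliberate design: every downstream quantity — cap membership, cap
curvature ($\pm 1/R^2$ exactly), frame axes, extents, and the elliptical
width contour — is known in closed form, so recovery error is measurable,
not estimated.  Phantoms are generated axis-aligned and posed by recorded
rigid motions, making frame-recovery error measurable in degrees.

Generator conditions (the defaults are the study conditions, not tuning
knobs):

* Cap extents are drawn per bone from the study-scale means and SDs
  (width/height 18.20/29.21 mm for medial-cuneiform-like bones,
  17.59/28.53 for MT1-like, 13.26/21.85 for intermediate-cuneiform-like,
  12.48/20.59 for MT2-like), truncated at $\pm 2$ SD.
* Cap curvature magnitudes are drawn in the *spherical-cap-feasible* band
  for the drawn extents: a spherical cap of half-diagonal $\rho$ requires
  $R \ge \rho$, i.e. $|K| \le 1/\rho^2$ (with a 10% safety margin, about
  0.0015–0.0075 mm$^{-2}$ at these extents).  Real TMT surfaces are not
  spherical and their reported mean curvatures partially exceed this
  band; phantom realism is bounded by the spherical-cap idealization, by
  design.  Half the cohort is generated congruent (convex cuneiform on
  concave metatarsal), half mismatched (both convex), covering both signs
  of the similarity statistic.
* The rim radius defaults to $1/(2|\mathrm{threshold}|)$ (2 mm for the
  $-0.25$ bones, 1.43 mm for the $-0.35$ bones), which places the
  extraction threshold exactly midway between the cap and rim principal
  curvatures — the unbiased choice for boundary recovery — while keeping
  the rim at the full 2x margin below the threshold.
* Default resolution is 0.3 mm target edge length, about twice the 0.148-mm
  voxel pitch of the imaging protocol this emulates, giving desk-scale
  meshes of roughly $10^5$ faces per bone.  Cap rings are graded three
  times finer in the outer 1.5-mm band so that boundary-recovery error is
  not dominated by radial quantization at the rim.
* Joint gap defaults to 2 mm (apex to apex), a plausible unloaded TMT
  joint space; nothing downstream depends on it because dissected-style
  analysis never measures across the gap.

Degradation operators emulate image provenance: `voxelize_remesh`
rasterizes the solid at a given pitch by z-column ray parity, lightly
smooths the occupancy field (two passes of a separable 3-point box filter
— enough to suppress staircase normals while moving the 0.5-level surface
by much less than a voxel; the reconstructed sphere area is correct to
well under 1%), and re-triangulates the 0.5 isosurface with naive surface
nets; `add_vertex_noise` displaces vertices along their normals by seeded
uniform noise.

What passing phantom tests shows: that the implementation correctly
recovers what it claims to measure when its modeling assumptions hold, at
image-realistic mesh density, and degrades gracefully under voxelization
and noise.  What it does not show: performance on real subchondral bone,
whose surfaces are non-spherical, whose rims are irregular, and whose
segmentation artifacts are structured rather than uniform.  The package's
cohort numbers on real meshes therefore carry the usual caveats of any
curvature-threshold method.

## Validation scales and reproducibility

The test suite validates at these problem sizes: analytic primitives at
three mesh resolutions; a seeded 24-joint phantom cohort at 0.3-mm
resolution for end-to-end recovery (extraction overlap, 2-degree frame
recovery, extent recovery within one mean edge length, similarity within
±0.05 of closed form); a voxelized-plus-noise robustness subset at the full
0.148-mm image pitch; and 200–1000-replicate seeded simulations for the
statistical calibration checks.  Reports are deterministic: identical seed
and configuration reproduce the CSV tables byte for byte (the run log
contains wall-clock timings and is excluded from byte-identity; it echoes
the full configuration needed to reproduce the run).  Configuration files
are YAML.

## Known limitations

* The Euclidean (not geodesic) fitting neighborhood slightly mixes
  geometry across the rim for vertices within one fitting radius of it;
  the Gaussian weighting mitigates but does not eliminate this.
* The sign attribution of Gaussian curvature is a reconstruction needed to
  make a signed similarity statistic possible; it is exact on elliptic
  regions and convention-bound on hyperbolic ones.
* Multi-facet articular surfaces (e.g. the second metatarsal's medial
  facet toward the medial cuneiform) are not decomposed; one surface per
  bone end is extracted, with the seed point available to disambiguate.
* Frames depend on per-specimen orientation hints; grossly wrong hints
  (beyond ~85 degrees) flip the DP/ML axes rather than failing loudly.
* Width profiles use the outer boundary loop only; deeply non-convex
  contours are handled by the outermost-crossing rule, which is the
  convention that reproduces negative medial distances at extreme heights.
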