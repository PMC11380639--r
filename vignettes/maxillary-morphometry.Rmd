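---
title: "Region-wise maxillary surface morphometry and two-segment reconstruction planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-wise maxillary surface morphometry and two-segment reconstruction planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(maxillomorph)
```

## The analysis in one paragraph

Reconstructing a resected maxilla with a free fibula flap (FFF) requires
bending a straight bone into the curved midface. If the relevant geometry of
the maxilla varies little across adults, a partially standardized,
mean-value-based cutting-guide system becomes feasible, avoiding per-patient
virtual surgical planning. `maxillomorph` implements the digital analysis
behind that question: every subject skull surface is rigidly registered to one
common reference skull, the signed deviation between the two surfaces is
measured over four reconstructive regions of interest (R1 paranasal, R2 facial
maxillary sinus wall, R3 zygomatic bone, R4 alveolar process, each on both
sides), seven summary parameters are computed per region, and a set of
reproducible landmarks is used to measure the two planned fibula segments —
lengths AX (A-point to premolar apex) and MX (zygoma midpoint to apex) and the
three-point angle between them — which are pooled over sides and subjects into
the cutting-guide template.

## Coordinate conventions and the sign of a deviation

All coordinates are millimetres. The package assumes nothing about patient
orientation except through its phantom, which uses +X = subject's right,
+Y = anterior, +Z = superior ("caudal" = smaller Z).

The deviation sign follows inspection-software convention as fixed by the
false-colour semantics: for a reference sample point $p$ with outward unit
normal $\hat n$ and matched subject point $q$,

$$ d = -\operatorname{sign}\big((q - p)\cdot \hat n\big)\,\lVert q - p\rVert , $$

so a subject surface **in front of / outside** the reference is **negative**
(rendered blue), behind/inside is positive (red), and $|d| < 1$ mm is the
neutral green band. Samples whose unsigned distance exceeds the validity
window (5 mm by default, i.e. a 1 cm corridor) are *invalid* (grey): no
comparison is possible there. The phantom generator specifies its injected
region offsets in this same signed convention, so an injected offset of
−2 mm is expected to be recovered as a Dmean of −2 mm.

## Registration: three-point alignment plus local best fit

Subjects are registered to the reference in two stages, mirroring the standard
inspection workflow:

1. **Three-point alignment** on the A-point and the deepest points of the two
   inferior orbital rims (IOr, IOl), solved in closed form by the Kabsch
   algorithm (`kabsch_align()`). No scaling and no reflection are permitted;
   the rotation determinant is constrained to +1.
2. **Local best fit** (`local_best_fit()`): point-to-point iterative closest
   point, trimmed by a fixed correspondence radius of 4.0 mm — the only
   published parameter of the proprietary refinement it models. Samples are
   the moving-mesh face centroids (all faces, stable under remeshing),
   weighted by face area; correspondences are exact point-to-triangle closest
   points, re-trimmed at every iteration; iteration stops when the RMS change
   falls below 1e-6 mm or after 100 iterations (both configurable). The RMS
   over each iteration's correspondence set is non-increasing by construction
   (each Kabsch update is the weighted least-squares optimum for that set).

Point-to-point ICP on smooth, nearly featureless surfaces converges linearly
and can slide tangentially for hundreds of iterations; from a 1 mm / 2°
cold start it needs roughly 400 iterations to reach 0.05 mm / 0.1°. In the
pipeline this is irrelevant because the landmark alignment provides a warm
start within the basin of quadratic convergence, but `max_iter` should be
raised when using `local_best_fit()` without landmarks.

A registration caveat that matters for interpretation: the least-squares fit
absorbs a small fraction of any genuine regional offset, roughly the offset
times the effective area fraction of the deforming region in the matched
surface (with a rotation term that can double the naive ratio). When whole
skulls are registered — the situation the phantom reproduces by extending its
surface well beyond the labeled regions — the bias is a few hundredths of a
millimetre; registering tightly cropped surfaces would inflate it.

## The seven deviation parameters

Each reference region is discretized into one sample per face (centroid,
outward normal, face area $a_i$); over the valid samples with signed
distances $d_i$:

| parameter | definition | units |
|---|---|---|
| Dmax, Dmin | $\max d_i$, $\min d_i$ | mm |
| Dmean | $\sum a_i d_i / \sum a_i$ | mm |
| DSD | $\sqrt{\sum a_i (d_i - \text{Dmean})^2 / \sum a_i}$ | mm |
| AVD | $\sum a_i$ (area of valid distance) | mm² |
| ID | $\sum a_i d_i$ (integrated distance) | mm³ |
| IAD | $\sum a_i |d_i|$ (integrated absolute distance) | mm³ |

Means are **area-weighted**: this makes `ID = Dmean * AVD` an exact identity
(asserted in the tests to 1e-9 relative) and is consistent with published
per-region values, where Dmean times AVD reproduces the printed ID to within
rounding. A region with no valid sample yields the designated empty summary
(AVD = 0, distances undefined).

### Closest point versus normal projection

Two correspondence rules are implemented in `signed_deviation()`:

* `"closest"` (function default): exact closest point on the subject surface.
* `"normal"`: intersection of the subject surface with the sample's normal
  line, taking the crossing of smallest absolute offset within the window.

For smooth opposing surfaces the two agree to within curvature terms (the
concentric-sphere oracle in the test suite passes under both). They differ
radically over *missing* surface: a hole in the subject (edentulous /
resorbed alveolar bone, cropped scans) leaves closest-point correspondences
almost everywhere valid — every sample inside the hole is matched to the hole
rim, and at anatomical scale (regions of 20–40 mm, window 5 mm) nearly the
whole hole lies within 5 mm of its rim. Normal projection instead finds no
crossing over the hole and marks exactly the missing area invalid, which is
the behaviour the grey "no comparison possible" areas describe. The
**pipeline therefore defaults to normal projection**, while the function-level
default remains closest point; the choice is a config entry
(`deviation_method`).

## Landmarks and the cutting-guide template

Per side, the planning landmarks are constructed on the registered surface:

* **J** — most caudal and lateral point of the zygomatic bone. "Most caudal
  and lateral" is not operationalized in the source description; here it is
  the region vertex maximizing $w_c(-z') + w_l|x|'$ with both coordinates
  standardized to the mesh bounding box (weights default to (1, 1),
  configurable). Ties break to the lowest vertex index.
* **O** — foot of the shortest connecting line from J to the orbital-rim
  polyline (vertices *and* segment interiors; exact ties go to the earlier
  segment).
* **M** — midpoint of J and O (an exact identity, asserted to 1e-9).
* **A** (A-point) and **X** (second-premolar apex) are annotations passed
  through: on real data they are digitized (the apex is often reconstructed
  by approximation in edentulous patients), on phantoms the generator places
  them.

Segment lengths are `AX = ||A - X||` and `MX = ||M - X||`; the three-point
angle is measured **at the shared endpoint X** between the legs XA and XM.
The source description places the angle "at the center point of these lines",
which is geometrically ambiguous; vertex-at-X is the only construction that
uses exactly the three named points, and it is the angle "between segments A
and B" that the template needs. Lengths are labeled strictly AX and MX
because the published anterior/posterior wording is internally inconsistent
(the abstract and the results table swap the assignment); the package never
uses the anterior/posterior labels for values.

Side pooling (`pool_sides()`) concatenates left and right measurements —
lengths and angles are side-symmetric scalars, so no mirroring is needed —
doubling the sample. For equal side counts the pooled mean equals the
unweighted mean of the side means; this identity is what lets the published
combined cells (131.24°, 30.71 mm, 28.15 mm) be reproduced from the printed
side cells alone, to the printed two-decimal precision under truncation.
The published pooled SDs (±1.29°, ±0.86, ±0.57 mm) are *not* reproducible
from any pooling of raw values consistent with the printed side SDs (~2–6);
their formula is unknown and the package reports ordinary sample SDs of the
pooled values instead.

## Cohort statistics

Outliers use Tukey fences at 1.5×IQR (normal) and 3×IQR (extreme), with
linear-interpolation quantiles (the common statistical-software default; the
convention is not stated in the source). Values exactly on a fence are not
outliers, so constant data yields none, and flags are affine-invariant.
Welch's t (exactly two groups), fixed-effects one-way ANOVA (more than two),
the Pearson chi-square (nominal level; Yates correction available but off by
default, as its use is unstated) and Pearson's r delegate to the standard R
implementations behind the module interface; the test suite validates each
against an independently coded textbook formula on 100 seeded random inputs
to 1e-9.

Clustering is univariate k-means (`stats::kmeans`, best of 10 restarts,
seeded, centers reported sorted). The elbow diagnostic picks the k with the
largest second difference of the within-cluster sum of squares over
k = 1..6, ties to the smaller k. A weak bend is flagged low-confidence when
the largest second difference is below 0.8 of the total WSS drop across the
scanned range — a heuristic threshold chosen so that a single Gaussian
cluster (relative bend ≈ 0.6 under the 1/k² WSS decay) is flagged while two
separated masses (ratio ≈ 1) are not. Pipeline defaults fix k = 2, the
favoured solution in the motivating analysis, with the elbow scan always
reported alongside. No multiple-testing correction is applied: the
motivating analysis reports unadjusted p-values and the package follows it
(`stats::p.adjust` can always be applied downstream to the reported values).

Subjects whose R4 AVD is an extreme outlier are excluded from the R4 cohort
summaries (the analogous exclusion in the motivating analysis removed
incomplete alveolar regions); exclusions are logged and reuse
`iqr_outliers()`.

## The phantom: what it emulates, and what it does not

`make_reference_phantom()` builds a parametric midface-like open surface: an
ellipsoidal dome blended into *exactly planar* lateral (zygomatic) wings.
The planar wings are a deliberate construction device: J, O and M are
constructed on them, so all seven landmarks lie on the triangulated surface
to machine precision — which turns landmark construction into an exactly
testable operation. The labeled regions are boxes in the parameter plane
with ≥3 mm unlabeled gaps (labels are pairwise disjoint and a strict subset
of all faces), and the surface extends well beyond them (domain
144 × 100 mm; the labeled regions are ~13% of the area, R1 alone ~2%) so
that registration is dominated by stable surface, as it is when whole skulls
are superimposed.

`synthesize_subject()` derives a subject by, in order: sex-conditioned
per-region offsets along the reference vertex normals (negative = outward;
defaults: males −1.5 mm in R1 and R3, emulating the qualitative finding that
males sit in the anterior clusters of those regions; between-subject SD
0.5 mm); per-vertex isotropic Gaussian noise (default 0.3 mm, the scale of
CT-surface extraction error); one contiguous dropout patch per side in R4
(default 15% of the side's R4 area, grown breadth-first from a random seed
face) emulating edentulous/invalid areas; isotropic landmark digitization
jitter (default 1.5 mm, which produces segment-measurement spread of the
order seen across real subjects); and a random rigid misalignment (uniform
within ±5 mm / ±5° by default). Ages are uniform over 20–89 years; the male
fraction is 0.68 of the cohort rounded. Age is not linked to geometry by
default (`age_slope_mm_per_year = 0`): the motivating analysis associates age
with outlier membership only, not with a continuous geometric trend.

Everything is deterministic given the spec and its seed — cohorts, meshes and
truth tables are bit-identical across runs — and every draw is recorded in a
`PhantomTruth` record (offsets, removed faces and their area, the applied
transform), which is what the recovery tests assert against.

What the phantom does **not** model: real craniofacial shape variation
(the geometry is smooth and parametric, with none of the ridges, foramina and
curvature extremes of bone), soft-tissue or imaging physics, segmentation
artifacts, or correlated (non-isotropic) digitization error. Passing recovery
tests therefore demonstrates that the *pipeline measures what was injected* —
signs, magnitudes, areas, group separations — not that its numbers on real
CT cohorts would carry clinical precision.

## Numerical choices and degenerate inputs

* Closest-point queries are exact point-to-triangle (not vertex-nearest),
  via a uniform-grid spatial index; ray casts use Möller–Trumbore in both
  directions along the normal.
* Hounsfield thresholding uses inclusive bounds (226 ≤ HU ≤ 48,060 by
  default; inclusivity is unstated in the source and the boundary voxel is a
  measure-zero choice). Empty and full masks are rejected (no iso-surface).
* Iso-surfaces come from marching tetrahedra over boundary cells with
  midpoint edge cuts and outward orientation enforced per triangle; the cube
  and sphere oracles in the test suite bound its area and radius error.
* `clean_mesh()` keeps the largest connected component *by area*, drops
  zero-area faces and unreferenced vertices, and is idempotent.
* Collinear three-point sets (triangle area ≤ 1e-6 mm²) are rejected in
  `kabsch_align()`; zero-length angle legs are rejected in
  `three_point_angle()`; missing X annotations are rejected naming the side.
* Test sizes: the standard phantom is the "coarse" 2 mm grid (7,200 faces);
  sphere oracles use subdivision-5 icospheres (20,480 faces), at which the
  discretization error of the concentric-sphere distance is below 0.001 mm.

## Known limitations

* Point-to-point ICP is used for the local best fit; the proprietary original
  may use point-to-plane and may trim differently (re-trimming per iteration
  is assumed here). Only its 4.0 mm radius is published.
* Normal projection can miss a crossing over very crinkled surfaces at
  grazing angles; for the noise levels modelled this was not observed to
  change any region summary beyond the reported tolerances.
* The A-point and premolar apex are inputs, not detected features; automatic
  cephalometric landmarking is out of scope.
* Volumetric (voxel-overlap) comparison, deformable registration, and defect
  classification are out of scope.
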