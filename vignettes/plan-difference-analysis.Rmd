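---
title: "Measuring differences between orthognathic surgical plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring differences between orthognathic surgical plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnathodiff)
```

## The measurement model

`gnathodiff` treats each osteotomized segment — dental maxilla, dental
mandible, and the bony mandibular distal segment — as a rigid body whose
position and orientation at one planning timepoint are proxied by a
*virtual triangle*: three named anatomical landmarks in a fixed
(right-side, midline, left-side) order. For the dental arches these are
the mesial buccal cusps of the first molars and the midline incisor
point; for the bony mandible, the mental foramina and pogonion. Because
the same three physical points are identified at both timepoints, the
T0 and T1 triangles of a segment are congruent up to landmarking error,
and the segment's plan-to-plan movement is exactly the proper rigid
transform between the ordered vertex triples.

That transform is estimated by rigid Kabsch superimposition (the
closed-form SVD solution of the orthogonal Procrustes problem restricted
to proper rotations). Scaling is deliberately excluded — a jaw segment
does not change size between plans, and a scale factor has no clinical
meaning here — and reflections are excluded by the determinant
correction in the SVD solution. On congruent triangles the solution is
exact (zero residual), which the test suite asserts at machine
precision.

### Axes, angles, and signs

All coordinates are expressed in a canonical patient frame:
+X = patient left (transverse axis), +Y = anterior (sagittal axis),
+Z = cranial (vertical axis), in millimetres. File readers require an
explicit frame tag so that data from other conventions fail loudly
rather than silently flipping signs.

The rotation is reported as clinical pitch/roll/yaw under the fixed
factorization

\[ R = R_z(\mathrm{yaw}) \, R_x(\mathrm{pitch}) \, R_y(\mathrm{roll}), \]

with every angle anti-clockwise positive about its positive axis
(right-hand rule). The factorization order is a package convention: the
underlying clinical literature names the three rotations but not an
order, and for the small angles that arise in planning comparisons
(a few degrees) the order effect is second-order — swapping conventions
changes angles by roughly the product of two angles in radians, well
below landmarking noise. The same composition is used by the synthetic
generator, so generated ground truth and recovered metrics are directly
comparable. At gimbal lock (|pitch| = 90°, far outside the clinical
range) yaw and roll are not separately identifiable; the decomposition
then sets roll to 0 and flags the result.

The interpretation of "anti-clockwise about the transverse axis as seen
from the patient's right" depends on the viewing convention; here it is
implemented strictly as the right-hand rule about +X (patient left), and
the convention is pinned by round-trip tests rather than by anatomy.

### Where translation is measured

For a rotating rigid body the reported translation depends on the
reference point. The package evaluates the displacement of the **T0
triangle centroid** under the segment transform: the centroid is
symmetric in the three landmarks, reproducible, and close to the
segment's center of clinical interest. Reporting at a single landmark
(incisor point, pogonion) would systematically differ by
(R − I) · (landmark − centroid); with rotations of a few degrees and
lever arms of 2–3 cm this is a few tenths of a millimetre. Positive
LR/AP/UD mean the presurgical plan sits further left / anterior /
cranial than the pretreatment plan.

## Surface registration

Before triangles are compared, both plans must share a frame. The
imaging workflow this package models aligns the plans on the bony
non-dental maxilla of the presurgical plan; volume-based registration of
the cranial base is out of scope, so `gnathodiff` substitutes a
landmark-initialized, trimmed, point-to-point iterative-closest-point
(ICP) match between segment surfaces (STL meshes, ASCII or binary).

Design choices, all overridable:

* point-to-point correspondences on vertices (not point-to-plane) — the
  simplest contract that satisfies surface-based matching;
* trimming: the largest `trim_fraction` (default 0.1) of squared
  residuals is discarded each iteration, which makes the fit robust to
  partial overlap and outlying geometry (the tests recover a 2° / 1 mm
  displacement to better than 0.1° / 0.1 mm with 20% of vertices
  replaced by uniform noise at `trim_fraction = 0.25`);
* convergence when the trimmed RMS residual changes by less than `tol`
  (default 1e-6 mm), capped at `max_iter` (default 200); the trimmed
  residual is non-increasing across iterations up to that tolerance;
* meshes are uniformly subsampled to at most `n_max` (default 5000)
  vertices; nearest neighbours are found by a chunked vectorised exact
  search, which at these sizes is faster than tree construction;
* a correspondence gate (initial median correspondence distance above
  10× the target's median vertex spacing) turns non-overlapping inputs
  into a diagnostic failure result instead of a misleading fit;
* an optional region mask restricts the source to the bony non-dental
  reference region; how that region is delineated is left to the user
  (sidecar index file or bounding box) since no standard definition
  exists.

Crucially, the registration reference must be a structure **shared** by
the two plans. Registering on a segment that itself moved between plans
would absorb that segment's movement into the frame and zero out its
metrics — the pipeline therefore registers on the bony maxilla reference
surface and applies the resulting transform to all T0 landmark sets.

## Cohort statistics

Per segment × parameter, across patients:

* `one_sample_summary()`: mean, SEM = SD/√n, two-sided one-sample
  t-test against 0 with df = n − 1, and the 95% CI
  mean ± t(0.975, n−1) · SEM. With zero sample variance the p-value is
  reported as its 0/1 limit and flagged degenerate.
* `top10_value()`: the 90th percentile of |differences| — the magnitude
  exceeded by 10% of observations — using linear interpolation between
  order statistics (`stats::quantile()` type 7, stated here for
  bit-reproducibility).
* `out_of_range_percent()`: share of patients with |difference|
  **strictly** greater than the clinical tolerance (defaults 2 mm for
  translations, 4° for rotations); a patient exactly at tolerance is in
  range. `tolerance_report()` adds per-segment `mean_rotations` /
  `mean_translations` rows, each the arithmetic mean of its three
  parameter percentages (an identity the tests assert).
* `subgroup_test()`: unpaired contrast (covariate present minus absent)
  per covariate × segment × parameter. Welch's unequal-variance test is
  the default — the reference analyses were run in R, whose default is
  Welch, and equal variances cannot be assumed between, say, SARME and
  non-SARME patients — with pooled-variance Student as an option.
* No multiple-testing correction is applied, matching standard practice
  in this literature; the JSON report records the number of tests
  performed so readers can judge the look-elsewhere effect themselves.

Published summary statistics of the 26-patient reference cohort are
shipped as plain-text CSVs (`reference_cohort_summary()`,
`reference_out_of_range()`). Two of the printed CI bounds are stable
under 2-decimal rounding of their inputs (maxillary pitch lower bound,
mandibular LR upper bound) and are used as reconstruction checks; other
cells differ in the last digit depending on whether rounded or unrounded
means/SEMs are used, and one printed row (maxillary UD) carries an
apparent sign inconsistency between its mean and CI, so those are not
asserted.

## The synthetic cohort generator

Real planning data cannot be redistributed, so validation rests on a
generator whose defaults *are* the reference study's conditions:

* n = 26 patients; covariate composition 15 SARME, 4 maxillary
  extraction, 13 mandibular extraction (configurable);
* per segment × parameter, each patient's true displacement component is
  drawn from a Gaussian whose mean is the published mean difference and
  whose SD is SEM · √26 — the cohort-level spread implied by the
  published SEMs;
* the six components are composed into a rigid transform in the same
  `Rz Rx Ry` order used by the decomposition, rotating about the
  segment's T0 triangle centroid (consistent with the translation
  convention), and applied to fixed template landmarks at realistic
  adult dimensions;
* optional isotropic Gaussian landmark noise (default 0 mm; 0.2 mm in
  the noisy validation runs, the scale of reported landmarking error in
  this field) is added independently at both timepoints;
* covariate effects default to zero and can be supplied as additive
  mean shifts;
* seeding: one root seed; each (patient, segment) draws from a derived
  substream (a fixed affine counter scheme), so regenerating a smaller
  cohort under the same seed reproduces its patients bit-for-bit.

Template meshes are simple parametric surfaces — rippled parabolic
dental arches, a chin-like sheet, and a doubly-curved anterior maxillary
wall that serves as the static registration reference shared by both
timepoints. They have realistic dimensions and enough geometric relief
for surface registration to lock all six degrees of freedom, but they
are rigid proxies, not anatomy.

### What passing tests do and do not show

The generator emulates exactly what the measurement model assumes:
rigid segments, exact landmark correspondence, Gaussian displacement
and noise. Parameter recovery on synthetic cohorts therefore validates
the *pipeline* — frames, signs, composition order, estimator
implementation — not the clinical method: it cannot detect landmark
identification bias, non-rigid dental changes between timepoints, or
segmentation artefacts in real scans. Those belong to the method-error
literature, not to this package's test suite.

## Numerical choices

* Rotations are validated to orthonormality and det = +1 within 1e-9;
  degenerate (collinear) geometry is detected via the second singular
  value of the centred configuration at 1e-6 mm; triangles must exceed
  1e-6 mm² in area.
* Long transform compositions are re-orthonormalised through an SVD
  projection to keep the group closed under floating-point error.
* ICP residuals for the kept correspondences are recomputed from
  coordinate differences rather than the expanded inner-product formula,
  which loses ~7 digits near zero at these coordinate magnitudes.
* Problem sizes used by the validation suites: 1,500-vertex meshes for
  registration recovery; 1,000 replicates of the n = 26 noisy-recovery
  study; 10,000 null replicates for the type-I error check; 10,000
  random rigid candidates for the Kabsch optimality oracle. These sizes
  give Monte-Carlo error comfortably below the tolerances being
  asserted.

## Known limitations

* Voxel-based volume registration is not implemented; the landmark +
  surface surrogate assumes the supplied meshes/landmarks already sit in
  approximately comparable frames.
* The Euler order used by the original clinical analysis tool is not
  public; with large rotations (tens of degrees) reported angles could
  differ between conventions.
* Translation is reported at the triangle centroid; published cohort
  values measured at a different reference point would differ by a few
  tenths of a millimetre under combined rotation.
* Mesh handling is deliberately minimal (no repair, no decimation beyond
  uniform subsampling, no non-rigid deformation).
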