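# gnathodiff

Quantifying the three-dimensional difference between two virtual
orthognathic surgical plans for the same patient.

## The problem

In combined orthodontic–orthognathic treatment, a surgical plan can be
drafted **before any orthodontic preparation** (a pretreatment plan, T0,
built on a digital orthodontic setup) and again **just before surgery**
(the presurgical plan, T1). How far apart the two plans end up tells us
whether early planning is accurate enough to rely on. `gnathodiff`
implements the measurement pipeline and the cohort statistics that answer
this question for three osteotomized segments:

| segment | landmarks (right, midline, left) |
|---|---|
| dental maxilla | 16, UI, 26 |
| dental mandible | 46, LI, 36 |
| bony mandibular distal segment | MF_R, Pog, MF_L |

All coordinates live in a canonical patient frame: **+X = patient left,
+Y = anterior, +Z = cranial** (mm).

## The method

1. **Surface registration** (optional): the pretreatment segments are
   brought into the presurgical plan's frame by landmark-initialized
   trimmed iterative-closest-point matching on the *bony non-dental
   maxilla* — a structure both plans share — so that true dental and
   mandibular differences are not confounded with frame differences.
2. **Virtual triangles**: each segment's three landmarks span a triangle
   that rigidly proxies the segment's 3D position and orientation.
3. **Rigid Procrustes (Kabsch)**: the proper rigid transform (rotation
   `R`, translation `t`, no scaling, no reflection) minimizing
   `Σᵢ ‖R xᵢ + t − yᵢ‖²` over the ordered vertex pairs maps the T0
   triangle onto its T1 counterpart.
4. **Clinical decomposition**: the rotation is factored as
   `R = Rz(yaw) · Rx(pitch) · Ry(roll)` (anti-clockwise positive,
   right-hand rule), and the translation is reported as the displacement
   of the T0 triangle centroid on the LR/AP/UD axes — six degrees of
   freedom per segment: pitch, roll, yaw (°), trans_LR, trans_AP,
   trans_UD (mm).
5. **Cohort statistics**: per segment × parameter, a one-sample t-test
   against zero (mean, SEM, 95% CI, p), the top-10% absolute value (90th
   percentile of |differences|), the percentage of patients outside
   clinical tolerance (|difference| > 2 mm translations / 4° rotations),
   and unpaired (Welch) subgroup contrasts for SARME and extraction
   covariates.

A seeded synthetic-cohort generator (`effect_spec()`,
`generate_cohort()`) draws per-patient 6-DOF ground-truth displacements
from Gaussians patterned on the published 26-patient reference summary
(`reference_cohort_summary()`), so the whole pipeline is testable by
parameter recovery.

## Worked example

```r
library(gnathodiff)

# simulate a 26-patient cohort at the reference conditions, measure it,
# and report
dir <- tempfile()
run_simulate(effect_spec(n_patients = 26, noise_sd = 0.2, seed = 11), dir)
tab <- run_measure(dir)
rep <- run_report(tab, file.path(dir, "report"))

subset(rep$summary, segment == "dental_maxilla" & parameter == "pitch")
#>          segment parameter      mean     sem top10_value    ci_low   ci_high
#> 1 dental_maxilla     pitch -2.652081 0.68981    7.983296 -4.072772 -1.231391
#>        p_value  n
#> 1 0.0007375558 26

rep$tolerance$mean_rotations
#>  dental_maxilla dental_mandible   bony_mandible
#>        11.53846        51.28205        20.51282
```

The maxillary pitch row says: in this simulated cohort the presurgical
plan is rotated on average ~2.7° clockwise (negative pitch) about the
left–right axis relative to the pretreatment plan, the difference is
highly significant, and 10% of patients differ by more than ~8°. The
`mean_rotations` entries are the average percentage of patients beyond
the 4° tolerance across pitch/roll/yaw per segment.

A thin CLI wrapper over the same functions is installed at
`inst/scripts/gnathodiff-cli.R` (subcommands `simulate`, `measure`,
`report`, `analyze`).

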