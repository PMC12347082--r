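# Virtual triangles and the conversion of segment transforms into the six
# clinical metrics.

maxilla_set <- function(p16 = c(-25, 0, 0), ui = c(0, 30, -2), p26 = c(25, 0, 0),
                        timepoint = "T0", id = "p01") {
  landmark_set(id, timepoint, "dental_maxilla",
               list(`16` = p16, UI = ui, `26` = p26))
}

test_that("landmark sets enforce the per-segment roster", {
  expect_error(landmark_set("p", "T0", "dental_maxilla",
                            list(`16` = c(0, 0, 0), UI = c(1, 1, 1),
                                 `36` = c(2, 2, 2))),
               "requires exactly landmarks")
  expect_error(landmark_set("p", "T2", "dental_maxilla", list()), "arg")
  s <- landmark_set("p", "T0", "bony_mandible",
                    list(Pog = c(0, 45, -115), MF_L = c(24, 25, -95),
                         MF_R = c(-24, 25, -95)))
  # canonical (right, midline, left) vertex order regardless of input order
  expect_identical(rownames(s$coords), c("MF_R", "Pog", "MF_L"))
})

test_that("build_triangle computes the centroid and rejects collinear landmarks", {
  tri <- build_triangle(maxilla_set())
  expect_equal(unname(tri$centroid), c(0, 10, -2 / 3), tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:10) {
    v <- random_points(3)
    s <- maxilla_set(v[1, ], v[2, ], v[3, ])
    expect_equal(unname(build_triangle(s)$centroid), unname(colMeans(v)),
                 tolerance = 1e-12)
  }

  degenerate <- maxilla_set(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(build_triangle(degenerate), "collinear")
})

test_that("triangle_transform recovers identity, translation, and rotation", {
  t0 <- build_triangle(maxilla_set())

  same <- triangle_transform(t0, t0)
  expect_lt(max(abs(same$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(same$translation)), 1e-12)

  shifted <- maxilla_set(c(-25, 0, 0) + c(1.19, 0, 0),
                         c(0, 30, -2) + c(1.19, 0, 0),
                         c(25, 0, 0) + c(1.19, 0, 0), timepoint = "T1")
  tr <- triangle_transform(t0, build_triangle(shifted))
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-12)
  expect_equal(tr$translation, c(1.19, 0, 0), tolerance = 1e-12)

  R <- rotation_about_axis("LR", 4)
  ctr <- t0$centroid
  rot <- rigid_transform(R, ctr - as.numeric(R %*% ctr))
  t1v <- apply_transform(rot, t0$vertices)
  t1 <- build_triangle(maxilla_set(t1v[1, ], t1v[2, ], t1v[3, ], "T1"))
  rec <- triangle_transform(t0, t1)
  expect_lt(max(abs(rec$rotation - rot$rotation)), 1e-9)
  expect_lt(max(abs(rec$translation - rot$translation)), 1e-9)
})

test_that("triangle_transform is exact on congruent triangles", {
  set.seed(31)
  for (rep in 1:20) {
    v <- random_points(3, sd = 30)
    t0 <- build_triangle(maxilla_set(v[1, ], v[2, ], v[3, ]))
    g <- random_transform()
    v1 <- apply_transform(g, v)
    t1 <- build_triangle(maxilla_set(v1[1, ], v1[2, ], v1[3, ], "T1"))
    tr <- triangle_transform(t0, t1)
    resid <- sum((apply_transform(tr, t0$vertices) - t1$vertices)^2) / 3
    expect_lt(resid, 1e-18)
  }
})

test_that("triangle_transform refuses mismatched segments", {
  t0 <- build_triangle(maxilla_set())
  other <- build_triangle(landmark_set("p01", "T1", "dental_mandible",
                                       list(`46` = c(-27, 18, -92),
                                            LI = c(0, 48, -90),
                                            `36` = c(27, 18, -92))))
  expect_error(triangle_transform(t0, other), "segment mismatch")
})

test_that("to_clinical_metrics reports signed translations and angles", {
  t0 <- build_triangle(maxilla_set())

  m <- to_clinical_metrics(identity_transform(), t0)
  expect_equal(unlist(m[METRIC_PARAMETERS]), setNames(rep(0, 6), METRIC_PARAMETERS))

  # T1 shifted to the patient's left: positive LR
  m <- to_clinical_metrics(rigid_transform(diag(3), c(1.19, 0, 0)), t0)
  expect_equal(m$trans_LR, 1.19, tolerance = 1e-12)
  expect_equal(unname(unlist(m[c("pitch", "roll", "yaw", "trans_AP", "trans_UD")])),
               rep(0, 5), tolerance = 1e-12)

  # +4 deg pitch about the centroid plus 1 mm caudal shift
  R <- rotation_about_axis("LR", 4)
  ctr <- t0$centroid
  tr <- rigid_transform(R, ctr - as.numeric(R %*% ctr) + c(0, 0, -1))
  m <- to_clinical_metrics(tr, t0)
  expect_equal(m$pitch, 4, tolerance = 1e-9)
  expect_equal(m$trans_UD, -1, tolerance = 1e-9)
  expect_equal(unname(unlist(m[c("roll", "yaw", "trans_LR", "trans_AP")])),
               rep(0, 4), tolerance = 1e-9)
})

test_that("measure_patient returns zero metrics for identical plans", {
  t0 <- template_t0()
  t1 <- lapply(t0, function(s) { s$timepoint <- "T1"; s })
  m <- measure_patient(t0, t1)
  expect_equal(nrow(m), 3L)
  expect_lt(max(abs(as.matrix(m[, METRIC_PARAMETERS]))), 1e-9)
})

test_that("measure_patient errors when a segment is missing", {
  t0 <- template_t0()
  t1 <- lapply(t0, function(s) { s$timepoint <- "T1"; s })
  expect_error(measure_patient(t0[1:2], t1), "missing segment")
})

test_that("measure_patient recovers per-segment ground truth exactly (noiseless)", {
  truth <- list(dental_maxilla = c(-2.85, 0.05, -0.54, 0.34, -0.74, -0.82),
                dental_mandible = c(-1.63, 0.51, -1.52, 1.19, 0.72, 0.02),
                bony_mandible = c(-0.41, 0.31, -1.21, 0.76, 0.12, 0.08))
  t0 <- template_t0()
  t1 <- displace_t0(t0, truth)
  m <- measure_patient(t0, t1)
  for (seg in names(truth)) {
    got <- unlist(m[m$segment == seg, METRIC_PARAMETERS])
    expect_equal(unname(got), truth[[seg]], tolerance = 1e-6)
  }
})

test_that("registration restores metrics when T0 sits in a displaced frame", {
  truth <- list(dental_maxilla = c(1, -0.5, 2, 0.3, -1, 0.8),
                dental_mandible = c(-2, 1, 0, 1.2, 0.1, -0.4),
                bony_mandible = c(0.5, 0.2, -1, 0, 0.6, 0.1))
  t0 <- template_t0()
  t1 <- displace_t0(t0, truth)
  baseline <- measure_patient(t0, t1)

  g <- rigid_transform(clinical_rotation(5, -3, 7), c(4, -6, 2))
  t0_moved <- lapply(t0, function(s) transform_landmarks(invert_transform(g), s))
  corrected <- measure_patient(t0_moved, t1, registration = g)
  expect_equal(as.matrix(corrected[, METRIC_PARAMETERS]),
               as.matrix(baseline[, METRIC_PARAMETERS]), tolerance = 1e-6)
})

test_that("metrics are consistent under a common change of both plans' frame", {
  truth <- list(dental_maxilla = c(1, 0, -1, 0.5, 0.5, 0),
                dental_mandible = c(0, 2, 0, -1, 0, 1),
                bony_mandible = c(-1, 0, 1, 0, -0.5, 0.5))
  t0 <- template_t0()
  t1 <- displace_t0(t0, truth)
  base <- measure_patient(t0, t1)

  # a common translation of both plans relocates the segments but not
  # their relative displacement: all metrics are unchanged
  d <- rigid_transform(diag(3), c(-2, 5, 1))
  t0d <- lapply(t0, function(s) transform_landmarks(d, s))
  t1d <- lapply(t1, function(s) transform_landmarks(d, s))
  moved <- measure_patient(t0d, t1d)
  expect_equal(as.matrix(moved[, METRIC_PARAMETERS]),
               as.matrix(base[, METRIC_PARAMETERS]), tolerance = 1e-6)

  # a common rotation conjugates the segment transform: the rotation
  # magnitude (total rotation angle) is frame-independent
  g <- rigid_transform(clinical_rotation(-4, 6, 3), c(-2, 5, 1))
  t0g <- lapply(t0, function(s) transform_landmarks(g, s))
  t1g <- lapply(t1, function(s) transform_landmarks(g, s))
  conj <- measure_patient(t0g, t1g)
  angle_of <- function(m) {
    seg_rows <- function(df) {
      vapply(SEGMENTS, function(seg) {
        r <- df[df$segment == seg, ]
        R <- clinical_rotation(r$pitch, r$roll, r$yaw)
        acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
      }, numeric(1))
    }
    seg_rows(m)
  }
  expect_equal(angle_of(conj), angle_of(base), tolerance = 1e-6)
})

test_that("reversing the timepoints flips translations and small angles", {
  truth <- list(dental_maxilla = c(2, -1, 0.5, 1, -2, 0.3),
                dental_mandible = c(-0.5, 0.2, 1, 0, 1, -1),
                bony_mandible = c(0.3, 0.6, -0.2, -0.7, 0.4, 0.9))
  t0 <- template_t0()
  t1 <- displace_t0(t0, truth)
  fwd <- measure_patient(t0, t1)
  t0_as_t1 <- lapply(t0, function(s) { s$timepoint <- "T1"; s })
  t1_as_t0 <- lapply(t1, function(s) { s$timepoint <- "T0"; s })
  rev <- measure_patient(t1_as_t0, t0_as_t1)
  expect_equal(as.matrix(rev[, c("trans_LR", "trans_AP", "trans_UD")]),
               -as.matrix(fwd[, c("trans_LR", "trans_AP", "trans_UD")]),
               tolerance = 1e-9)
  # for small rotations the angle triple flips sign to first order; the
  # residual is the second-order Euler cross term (~angle^2 in radians)
  expect_equal(as.matrix(rev[, c("pitch", "roll", "yaw")]),
               -as.matrix(fwd[, c("pitch", "roll", "yaw")]),
               tolerance = 0.2)
})
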