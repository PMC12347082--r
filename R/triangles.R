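# Virtual triangles: three named landmarks act as a rigid proxy for a
# segment's 3D position and orientation, and the rigid transform between a
# segment's T0 and T1 triangles is converted into the six clinical metrics.

#' Build a virtual triangle from a landmark set
#'
#' The three landmarks of a segment span a virtual triangle that captures
#' the segment's 3D position and orientation. Vertices are kept in the
#' canonical (right-side, midline, left-side) order so that the triangle
#' carries orientation.
#'
#' @param landmarks A `landmark_set`.
#' @return An object of class `virtual_triangle` with fields `vertices`
#'   (3 x 3 matrix, rows in canonical order), `segment`, `patient_id`,
#'   `timepoint`, and `centroid`.
#' @export
build_triangle <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  v <- landmarks$coords  # already in canonical order
  a <- triangle_area(v)
  if (a <= 1e-6) {
    stop(sprintf("landmarks of segment '%s' are collinear (area %.3g mm^2)",
                 landmarks$segment, a), call. = FALSE)
  }
  structure(list(vertices = v, segment = landmarks$segment,
                 patient_id = landmarks$patient_id,
                 timepoint = landmarks$timepoint,
                 centroid = colMeans(v)),
            class = "virtual_triangle")
}

triangle_area <- function(v) {
  e1 <- v[2, ] - v[1, ]
  e2 <- v[3, ] - v[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  0.5 * sqrt(sum(cr^2))
}

#' @export
print.virtual_triangle <- function(x, ...) {
  cat(sprintf("<virtual_triangle> %s (%s, %s), area %.2f mm^2\n",
              x$segment, x$patient_id, x$timepoint, triangle_area(x$vertices)))
  invisible(x)
}

#' Rigid transform between two triangles of the same segment
#'
#' Kabsch superimposition on the three ordered vertex pairs; exact
#' (zero-residual) whenever the triangles are congruent, which holds by
#' construction when both were measured on the same rigid segment.
#'
#' @param t0,t1 `virtual_triangle` objects for the same segment at the two
#'   timepoints, expressed in the common registered frame.
#' @return A `rigid_transform` mapping the T0 triangle onto the T1 triangle.
#' @export
triangle_transform <- function(t0, t1) {
  stopifnot(inherits(t0, "virtual_triangle"), inherits(t1, "virtual_triangle"))
  if (t0$segment != t1$segment) {
    stop(sprintf("segment mismatch: '%s' vs '%s'", t0$segment, t1$segment),
         call. = FALSE)
  }
  kabsch_rigid(t0$vertices, t1$vertices)
}

#' Convert a segment's rigid transform into the six clinical metrics
#'
#' Angles come from [decompose_to_clinical_angles()]; translations are the
#' displacement of the reference (T0) triangle centroid under the
#' transform, reported on the canonical axes. Sign conventions: positive
#' LR means T1 lies further to the patient's left than T0, positive AP
#' more anterior, positive UD more cranial; positive pitch/roll/yaw are
#' anti-clockwise rotations about the +X/+Y/+Z axes.
#'
#' @param transform `rigid_transform` mapping T0 geometry onto T1.
#' @param reference the segment's T0 `virtual_triangle` (its centroid
#'   anchors the translation report).
#' @return A one-row data.frame of class `clinical_metrics` with columns
#'   `patient_id`, `segment`, `pitch`, `roll`, `yaw` (degrees), `trans_LR`,
#'   `trans_AP`, `trans_UD` (mm).
#' @export
to_clinical_metrics <- function(transform, reference) {
  stopifnot(inherits(transform, "rigid_transform"),
            inherits(reference, "virtual_triangle"))
  ang <- decompose_to_clinical_angles(transform$rotation)
  c0 <- reference$centroid
  d <- as.numeric(transform$rotation %*% c0) + transform$translation - c0
  out <- data.frame(patient_id = reference$patient_id,
                    segment = reference$segment,
                    pitch = ang$pitch, roll = ang$roll, yaw = ang$yaw,
                    trans_LR = d[1], trans_AP = d[2], trans_UD = d[3],
                    stringsAsFactors = FALSE)
  class(out) <- c("clinical_metrics", class(out))
  out
}

#' Measure one patient: three segments' clinical metrics
#'
#' Computes, for each of the three segments, the rigid transform between
#' the T0 and T1 virtual triangles and its six clinical metrics. If a
#' registration transform is supplied (from surface registration of the
#' bony maxilla, the reference segment that anchors the common frame), it
#' is applied to all T0 landmark sets first so that residual maxillary
#' frame differences do not masquerade as dental or mandibular movement.
#'
#' @param t0_landmarks,t1_landmarks lists of three `landmark_set` objects
#'   (one per segment) for the two timepoints.
#' @param registration optional `rigid_transform` mapping the T0 frame
#'   onto the T1 frame, or `NULL`.
#' @return A three-row `clinical_metrics` data.frame, one row per segment.
#' @export
measure_patient <- function(t0_landmarks, t1_landmarks, registration = NULL) {
  seg_of <- function(sets) vapply(sets, function(s) s$segment, character(1))
  t0_landmarks <- as.list(t0_landmarks)
  t1_landmarks <- as.list(t1_landmarks)
  s0 <- seg_of(t0_landmarks); s1 <- seg_of(t1_landmarks)
  for (seg in SEGMENTS) {
    if (!(seg %in% s0) || !(seg %in% s1)) {
      stop(sprintf("missing segment '%s' in T0 or T1 landmark sets", seg),
           call. = FALSE)
    }
  }
  rows <- lapply(SEGMENTS, function(seg) {
    l0 <- t0_landmarks[[match(seg, s0)]]
    l1 <- t1_landmarks[[match(seg, s1)]]
    if (!is.null(registration)) l0 <- transform_landmarks(registration, l0)
    tri0 <- build_triangle(l0)
    tri1 <- build_triangle(l1)
    to_clinical_metrics(triangle_transform(tri0, tri1), tri0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("clinical_metrics", "data.frame")
  out
}
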