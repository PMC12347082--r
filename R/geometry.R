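# Rigid-body mathematics: Kabsch registration, transform algebra, and the
# clinical pitch/roll/yaw decomposition.
#
# Canonical patient frame used throughout the package:
#   +X = patient left (transverse axis)
#   +Y = anterior     (sagittal axis)
#   +Z = cranial      (vertical axis)
# Euler factorization (fixed package convention, documented in the vignette):
#   R = Rz(yaw) %*% Rx(pitch) %*% Ry(roll)
# with positive angles anti-clockwise about the +axis (right-hand rule).

#' Canonical anatomical axes
#'
#' Unit vectors of the canonical patient frame in which all coordinates are
#' expressed: `+X` = patient left (transverse), `+Y` = anterior (sagittal),
#' `+Z` = cranial (vertical). Rotations about these axes are, respectively,
#' pitch, roll, and yaw; positive angles are anti-clockwise about the
#' positive axis by the right-hand rule.
#'
#' @format A named list of three numeric unit vectors: `LR`, `AP`, `UD`.
#' @export
CANONICAL_AXES <- list(
  LR = c(1, 0, 0),
  AP = c(0, 1, 0),
  UD = c(0, 0, 1)
)

#' @keywords internal
ROTATION_TOL <- 1e-9

#' @keywords internal
DEGENERACY_TOL <- 1e-6

as_point_matrix <- function(points, arg = "points") {
  if (is.matrix(points)) {
    m <- points
  } else if (is.data.frame(points)) {
    m <- as.matrix(points)
  } else if (is.list(points)) {
    m <- do.call(rbind, lapply(points, function(p) as.numeric(p)))
  } else {
    m <- matrix(as.numeric(points), ncol = 3, byrow = TRUE)
  }
  storage.mode(m) <- "double"
  if (ncol(m) != 3L) {
    stop(sprintf("`%s` must be an n x 3 matrix of coordinates", arg), call. = FALSE)
  }
  if (!all(is.finite(m))) {
    stop(sprintf("`%s` contains non-finite coordinates", arg), call. = FALSE)
  }
  m
}

#' Construct a rigid transform
#'
#' A rigid transform pairs a proper rotation (orthonormal, determinant +1)
#' with a translation in mm, acting as `x -> R x + t`.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric 3-vector, mm.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' identity_transform()
#' rigid_transform(rotation_about_axis("UD", 30), c(1, -2, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation))) {
    stop("`translation` must be a finite numeric 3-vector", call. = FALSE)
  }
  check_rotation(rotation)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() {
  rigid_transform(diag(3), c(0, 0, 0))
}

check_rotation <- function(R, tol = ROTATION_TOL) {
  if (!all(is.finite(R))) stop("rotation contains non-finite entries", call. = FALSE)
  ortho_err <- max(abs(crossprod(R) - diag(3)))
  if (ortho_err > tol) {
    stop(sprintf("rotation is not orthonormal (max deviation %.3g)", ortho_err),
         call. = FALSE)
  }
  d <- det(R)
  if (abs(d - 1) > tol) {
    stop(sprintf("rotation determinant is %.12f, not +1 (reflection or scaling)", d),
         call. = FALSE)
  }
  invisible(R)
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- decompose_to_clinical_angles(x$rotation)
  cat("<rigid_transform>\n")
  cat(sprintf("  pitch %.4f deg, roll %.4f deg, yaw %.4f deg\n",
              ang$pitch, ang$roll, ang$yaw))
  cat(sprintf("  translation (%.4f, %.4f, %.4f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform A `rigid_transform`.
#' @param points n x 3 matrix (or coercible) of coordinates in mm.
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- as_point_matrix(points)
  out <- m %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  dimnames(out) <- dimnames(m)
  out
}

#' Optimal rigid (Kabsch) alignment of corresponding point sets
#'
#' Finds the proper rigid transform (rotation + translation, no scaling,
#' no reflection) minimizing the sum of squared distances between
#' transformed source points and their corresponding targets. This is the
#' rigid Procrustes superimposition used to align one plan's geometry with
#' another's.
#'
#' @param source,target n x 3 matrices (or lists of 3-vectors) of
#'   corresponding points, n >= 3, source not collinear.
#' @return A `rigid_transform` mapping source onto target in the
#'   least-squares sense.
#' @examples
#' src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
#' kabsch_rigid(src, src + rep(c(2, 0, 0), each = 3))
#' @export
kabsch_rigid <- function(source, target) {
  S <- as_point_matrix(source, "source")
  T_ <- as_point_matrix(target, "target")
  if (nrow(S) != nrow(T_)) {
    stop("`source` and `target` must contain the same number of points",
         call. = FALSE)
  }
  if (nrow(S) < 3L) {
    stop("at least 3 corresponding points are required", call. = FALSE)
  }
  cs <- colMeans(S)
  ct <- colMeans(T_)
  S0 <- sweep(S, 2, cs)
  T0 <- sweep(T_, 2, ct)
  # collinearity: second-smallest singular value of the centred source
  sv <- svd(S0, nu = 0, nv = 0)$d
  if (sv[2] < DEGENERACY_TOL) {
    stop("source points are collinear (degenerate geometry)", call. = FALSE)
  }
  H <- crossprod(S0, T0)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` returns the transform applying `b` first and
#' then `a` (i.e. `x -> a(b(x))`); `invert_transform(a)` returns the unique
#' transform with `compose_transform(a, invert_transform(a))` the identity.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  R <- a$rotation %*% b$rotation
  # re-orthonormalise to keep long compositions within tolerance
  dec <- svd(R)
  R <- dec$u %*% t(dec$v)
  rigid_transform(R, as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(a) {
  stopifnot(inherits(a, "rigid_transform"))
  Rt <- t(a$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% a$translation))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Elementary rotation about a canonical axis
#'
#' @param axis `"LR"` (pitch axis, +X), `"AP"` (roll axis, +Y) or
#'   `"UD"` (yaw axis, +Z).
#' @param angle_deg rotation angle in degrees, positive anti-clockwise
#'   about the positive axis (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis = c("LR", "AP", "UD"), angle_deg) {
  axis <- match.arg(axis)
  a <- deg2rad(angle_deg)
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    LR = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    AP = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    UD = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Compose a rotation from clinical pitch/roll/yaw
#'
#' Builds the rotation `Rz(yaw) %*% Rx(pitch) %*% Ry(roll)` in the
#' canonical patient frame. This fixed factorization order is the package
#' convention; [decompose_to_clinical_angles()] is its exact inverse for
#' pitch in (-90, 90) degrees.
#'
#' @param pitch,roll,yaw angles in degrees (anti-clockwise positive about
#'   +X, +Y, +Z respectively).
#' @return 3x3 rotation matrix.
#' @export
clinical_rotation <- function(pitch = 0, roll = 0, yaw = 0) {
  rotation_about_axis("UD", yaw) %*%
    rotation_about_axis("LR", pitch) %*%
    rotation_about_axis("AP", roll)
}

#' Decompose a rotation into clinical pitch/roll/yaw
#'
#' Inverts the `Rz(yaw) Rx(pitch) Ry(roll)` factorization of
#' [clinical_rotation()]. Angles are reported in degrees in (-180, 180]:
#' pitch about the left-right axis, roll about the antero-posterior axis,
#' yaw about the vertical axis, each anti-clockwise positive. At gimbal
#' lock (|pitch| = 90 degrees) yaw and roll are not separately identifiable;
#' the convention roll = 0 is applied and the result is flagged.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @return A list with elements `pitch`, `roll`, `yaw` (degrees) and
#'   `gimbal_lock` (logical).
#' @export
decompose_to_clinical_angles <- function(rotation) {
  R <- matrix(as.numeric(rotation), 3, 3)
  check_rotation(R)
  sp <- max(-1, min(1, R[3, 2]))
  if (abs(abs(sp) - 1) <= ROTATION_TOL) {
    # |pitch| = 90: only yaw -/+ roll is determined; take roll = 0
    pitch <- rad2deg(asin(sp))
    yaw <- rad2deg(atan2(R[2, 1], R[1, 1]))
    return(list(pitch = pitch, roll = 0, yaw = yaw, gimbal_lock = TRUE))
  }
  pitch <- asin(sp)
  roll <- atan2(-R[3, 1], R[3, 3])
  yaw <- atan2(-R[1, 2], R[2, 2])
  list(pitch = rad2deg(pitch), roll = rad2deg(roll), yaw = rad2deg(yaw),
       gimbal_lock = FALSE)
}
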