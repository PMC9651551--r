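#' Rigid transform (rotation + translation)
#'
#' A proper rigid-body motion in 3D: an orthonormal rotation matrix with
#' determinant +1 and a translation in mm. Closed under composition and
#' inversion.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (mm).
#' @param validate check orthonormality and `det = +1` (tolerance 1e-8).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            validate = TRUE) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (validate) {
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
      stop("rotation is not orthonormal")
    if (abs(det(rotation) - 1) > 1e-8)
      stop("rotation must be proper (det = +1)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("rigid_transform: rotation %.4f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang * 180 / pi, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity rigid transform
#' @return a [rigid_transform()] with identity rotation and zero translation.
#' @export
rt_identity <- function() rigid_transform(validate = FALSE)

#' Compose rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`
#' (`(a o b)(v) = a(b(v))`).
#'
#' @param a,b [rigid_transform()] objects.
#' @return the composed [rigid_transform()].
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation,
                  validate = FALSE)
}

#' Invert a rigid transform
#' @param x a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
rt_invert <- function(x) {
  Rt <- t(x$rotation)
  rigid_transform(Rt, as.vector(-Rt %*% x$translation), validate = FALSE)
}

#' Apply a rigid transform to a point matrix
#' @param x a [rigid_transform()].
#' @param points n x 3 numeric matrix.
#' @return transformed n x 3 matrix.
#' @export
rt_apply <- function(x, points) {
  sweep(points %*% t(x$rotation), 2L, x$translation, "+")
}

# rotation angle (radians) of a rotation matrix
rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}

# exact rotation matrix about a coordinate axis, angle in degrees
axis_rotation <- function(axis, angle) {
  th <- angle * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

# rotation about an arbitrary unit axis (Rodrigues), angle in degrees
axis_angle_rotation <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
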