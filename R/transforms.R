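#' Rigid-body transform
#'
#' A proper rigid transform `x' = R x + t` in Cartesian angstrom space.
#' The rotation must be orthonormal with determinant +1 (tolerance 1e-8);
#' improper (reflecting) matrices are rejected.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!is_rotation_matrix(rotation)) {
    stop("'rotation' is not a proper rotation matrix (orthonormal, det = +1)")
  }
  if (length(translation) != 3L || any(!is.finite(translation))) {
    stop("'translation' must be a finite 3-vector")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Test whether a matrix is a proper rotation
#'
#' @param m matrix to test.
#' @param tol numeric tolerance on orthonormality and on `det(m) - 1`.
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation_matrix <- function(m, tol = 1e-8) {
  is.matrix(m) && all(dim(m) == c(3L, 3L)) && all(is.finite(m)) &&
    max(abs(crossprod(m) - diag(3))) < tol && abs(det(m) - 1) < tol
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(second, first) {
  stopifnot(inherits(second, "rigid_transform"), inherits(first, "rigid_transform"))
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) + second$translation)
}

#' Invert a rigid transform
#'
#' @param tf a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  rt <- t(tf$rotation)
  rigid_transform(rt, as.numeric(-rt %*% tf$translation))
}

#' Integer power of a rigid transform
#'
#' `transform_power(tf, k)` is `tf` composed with itself `k` times
#' (`k = 0` gives the identity).
#'
#' @param tf a `rigid_transform`.
#' @param k non-negative integer.
#' @return A `rigid_transform`.
#' @export
transform_power <- function(tf, k) {
  stopifnot(inherits(tf, "rigid_transform"), k >= 0, k == round(k))
  out <- rigid_transform()
  for (i in seq_len(k)) out <- compose_transform(tf, out)
  out
}

#' Rotation about an axis
#'
#' Rodrigues construction of the rotation matrix for a right-handed rotation
#' of `angle` degrees about `axis` (through the origin).
#'
#' @param axis length-3 direction (need not be normalized).
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("'axis' must be a nonzero vector")
  k <- axis / n
  th <- angle * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(R) {
  tr <- sum(diag(R))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Rotation axis of a rotation matrix
#'
#' The unit eigenvector for eigenvalue 1. For angles away from 0 and 180
#' degrees the axis is read off the skew-symmetric part; near 180 degrees
#' the symmetric part is used. For the identity (angle ~ 0) the axis is
#' undefined and `c(0, 0, 1)` is returned by convention.
#'
#' @param R 3x3 rotation matrix.
#' @return Unit 3-vector.
#' @export
rotation_axis <- function(R) {
  ang <- rotation_angle(R)
  if (ang < 1e-7) return(c(0, 0, 1))
  if (ang < 179.9) {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    return(v / sqrt(sum(v^2)))
  }
  # near 180 deg: axis from the dominant column of (R + I)/2
  M <- (R + diag(3)) / 2
  j <- which.max(diag(M))
  v <- M[, j]
  v / sqrt(sum(v^2))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform: rotation", sprintf("%.3f", rotation_angle(x$rotation)),
      "deg, translation", sprintf("(%.3f, %.3f, %.3f) A\n",
                                  x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}
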