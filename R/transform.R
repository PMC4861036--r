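#' Rigid spatial transform (3 rotations + 3 translations)
#'
#' Parameterized by Euler angles about the x, y and z axes (applied as
#' `R = Rz %*% Ry %*% Rx`), a translation vector, and a rotation center.
#' A point `p` maps to `R %*% (p - center) + center + translation`.
#' Rigid transforms preserve pairwise distances and volumes.
#'
#' @param rotation Numeric length-3 Euler angles (radians) about x, y, z.
#' @param translation Numeric length-3 offsets, mm.
#' @param center Numeric length-3 rotation center, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3,
            all(is.finite(c(rotation, translation, center))))
  structure(list(rotation = rotation, translation = translation,
                 center = center, matrix = euler_matrix(rotation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (%.4f, %.4f, %.4f) rad, trans (%.3f, %.3f, %.3f) mm\n",
    x$rotation[1], x$rotation[2], x$rotation[3],
    x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

euler_matrix <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

# Euler angles (x, y, z convention matching euler_matrix) from a rotation
# matrix; valid away from the |pitch| = 90 deg singularity, which rigid
# medical-image alignments never approach.
matrix_to_euler <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  b <- asin(sy)
  if (abs(cos(b)) < 1e-12) {
    a <- atan2(-R[1, 2], R[2, 2]); c <- 0
  } else {
    a <- atan2(R[3, 2], R[3, 3])
    c <- atan2(R[2, 1], R[1, 1])
  }
  c(a, b, c)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform].
#' @param points Numeric n x 3 matrix (or length-3 vector) of world
#'   coordinates, mm.
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, points) {
  pts <- matrix(as.numeric(points), ncol = 3)
  centered <- sweep(pts, 2, transform$center, "-")
  out <- centered %*% t(transform$matrix)
  sweep(out, 2, transform$center + transform$translation, "+")
}

#' Invert a rigid transform
#'
#' `transform_points(invert_transform(t), transform_points(t, p))`
#' reproduces `p` to floating-point precision.
#'
#' @param transform A [rigid_transform].
#' @return The inverse [rigid_transform].
#' @export
invert_transform <- function(transform) {
  Rinv <- t(transform$matrix)
  # p = Rinv %*% (q - c - d) + c = Rinv %*% (q - c) + c + (Rinv %*% (-d))
  rigid_transform(rotation = matrix_to_euler(Rinv),
                  translation = as.numeric(Rinv %*% (-transform$translation)),
                  center = transform$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `first`, then `second`.
#'
#' @param second,first [rigid_transform] objects.
#' @return A [rigid_transform] with `first`'s rotation center.
#' @export
compose_transforms <- function(second, first) {
  R <- second$matrix %*% first$matrix
  c1 <- first$center
  d <- as.numeric(transform_points(second, transform_points(first, c1))) - c1
  rigid_transform(rotation = matrix_to_euler(R), translation = d, center = c1)
}

is_identity_transform <- function(transform, tol = 1e-12) {
  all(abs(transform$rotation) < tol) && all(abs(transform$translation) < tol)
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' @param transform A [rigid_transform].
#' @param path File path.
#' @return `read_transform` returns a [rigid_transform].
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(rotation = transform$rotation, translation = transform$translation,
         center = transform$center),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotation, x$translation, x$center)
}
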