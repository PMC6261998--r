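## 3D rotation helpers shared by the phantom, multiview and orientation code.
## Conventions: lab frame is right-handed with x the illumination axis,
## y the (vertical) sample-tube axis and z the detection axis; z = 0 is the
## side nearest the detection objective.

#' Rotation matrix from axis and angle
#'
#' Builds the proper rotation matrix (Rodrigues formula) for a rotation of
#' `degrees` about `axis` (right-hand rule).
#'
#' @param axis numeric length-3 axis; need not be normalized.
#' @param degrees rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
#' @examples
#' rotation_axis_angle(c(0, 1, 0), 90)
rotation_axis_angle <- function(axis, degrees) {
  if (!is.numeric(axis) || length(axis) != 3L || !all(is.finite(axis))) {
    stop_invalid_parameter("`axis` must be a finite numeric 3-vector")
  }
  n <- sqrt(sum(axis^2))
  if (n == 0) stop_invalid_parameter("`axis` must be non-zero")
  a <- axis / n
  th <- degrees * pi / 180
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation taking one direction onto another
#'
#' Returns the minimal-angle proper rotation mapping unit(`from`) to
#' unit(`to`). For antiparallel inputs an arbitrary perpendicular axis is
#' used (the 180 degree rotation is not unique).
#'
#' @param from,to numeric length-3 directions.
#' @return A 3x3 rotation matrix `R` with `R %*% from` parallel to `to`.
#' @export
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t <- to / sqrt(sum(to^2))
  ax <- c(f[2] * t[3] - f[3] * t[2],
          f[3] * t[1] - f[1] * t[3],
          f[1] * t[2] - f[2] * t[1])
  d <- sum(f * t)
  if (sqrt(sum(ax^2)) < 1e-12) {
    if (d > 0) return(diag(3))
    ## antiparallel: rotate 180 degrees about any axis perpendicular to f
    perp <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- perp - sum(perp * f) * f
    return(rotation_axis_angle(ax, 180))
  }
  rotation_axis_angle(ax, atan2(sqrt(sum(ax^2)), d) * 180 / pi)
}

#' Test for a proper rotation matrix
#'
#' @param m a matrix.
#' @param tol numeric tolerance on orthonormality and the determinant.
#' @return `TRUE` if `m` is a 3x3 orthonormal matrix with determinant +1.
#' @export
is_rotation <- function(m, tol = 1e-8) {
  is.matrix(m) && all(dim(m) == c(3L, 3L)) && all(is.finite(m)) &&
    max(abs(crossprod(m) - diag(3))) <= tol &&
    abs(det(m) - 1) <= tol
}

check_rotation <- function(m, name = "rotation") {
  if (!is_rotation(m)) {
    stop_invalid_parameter(sprintf("`%s` must be a proper 3x3 rotation matrix", name))
  }
  invisible(m)
}
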