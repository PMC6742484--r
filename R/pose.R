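#' Rigid-body pose
#'
#' A pose is a position (nm, world frame) plus an orientation, stored as a
#' unit quaternion \code{c(w, x, y, z)}.  Points in the body frame are mapped
#' to the world frame by \code{p_world = R(q) \%*\% p_body + position}.
#'
#' @param position Numeric 3-vector, nm.
#' @param quaternion Numeric 4-vector \code{c(w, x, y, z)}; normalised on
#'   construction.
#' @return An object of class \code{"mt_pose"}.
#' @export
pose <- function(position = c(0, 0, 0), quaternion = c(1, 0, 0, 0)) {
  stopifnot(length(position) == 3, length(quaternion) == 4)
  n <- sqrt(sum(quaternion^2))
  if (n < 1e-12) stop("zero quaternion")
  structure(list(position = as.numeric(position),
                 quaternion = as.numeric(quaternion) / n),
            class = "mt_pose")
}

#' @rdname pose
#' @param rotation 3x3 rotation matrix (alternative to a quaternion).
#' @export
pose_from_matrix <- function(position, rotation) {
  pose(position, quat_from_matrix(rotation))
}

#' Rotation matrix of a pose or quaternion
#' @param q Unit quaternion \code{c(w,x,y,z)} or an \code{mt_pose}.
#' @return 3x3 rotation matrix (determinant +1).
#' @export
quat_to_matrix <- function(q) {
  if (inherits(q, "mt_pose")) q <- q$quaternion
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quat_to_matrix
#' @param R 3x3 rotation matrix.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

#' Quaternion product (Hamilton convention)
#' @param a,b Quaternions \code{c(w,x,y,z)}.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion of a rotation vector
#'
#' @param v Rotation vector (axis times angle, radians).
#' @export
quat_from_rotvec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-300) return(c(1, 0, 0, 0))
  c(cos(th / 2), sin(th / 2) * v / th)
}

#' Apply a pose to body-frame points
#' @param p An \code{mt_pose}.
#' @param x n x 3 matrix (or 3-vector) of body-frame points, nm.
#' @return n x 3 matrix of world-frame points.
#' @export
transform_points <- function(p, x) {
  x <- rbind(x)
  t(quat_to_matrix(p) %*% t(x) + p$position)
}

#' Uniform random unit quaternion
#' @param n Number of quaternions.
#' @return n x 4 matrix, rows are unit quaternions.
#' @export
random_quaternion <- function(n = 1) {
  m <- matrix(stats::rnorm(4 * n), ncol = 4)
  m / sqrt(rowSums(m^2))
}

# Kabsch: rotation + translation minimising ||R x + t - y||; used to derive
# mated poses from anchor correspondences.
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  h <- t(sweep(x, 2, cx)) %*% sweep(y, 2, cy)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = as.numeric(cy - R %*% cx))
}
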