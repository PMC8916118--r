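# Rotation and directional-statistics helpers shared by the generators and
# the subtomogram engine. Euler convention: ZXZ, intrinsic, degrees.

#' Rotation matrix from ZXZ Euler angles
#'
#' Intrinsic ZXZ convention: `R = Rz(phi) %*% Rx(theta) %*% Rz(psi)`,
#' angles in degrees. This is the convention used wherever the package
#' serializes particle orientations.
#'
#' @param phi,theta,psi Euler angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
euler_to_matrix <- function(phi, theta, psi) {
  rz <- function(a) {
    c <- cos(a); s <- sin(a)
    matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
  }
  rx <- function(a) {
    c <- cos(a); s <- sin(a)
    matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
  }
  d2r <- pi / 180
  rz(phi * d2r) %*% rx(theta * d2r) %*% rz(psi * d2r)
}

#' ZXZ Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]; angles returned in degrees with
#' `theta` in \[0, 180\].
#'
#' @param R 3 x 3 rotation matrix.
#' @return numeric vector `c(phi, theta, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  r2d <- 180 / pi
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct)
  if (abs(sin(theta)) < 1e-9) {
    # gimbal lock: fold everything into phi
    phi <- atan2(R[2, 1], R[1, 1])
    psi <- 0
  } else {
    phi <- atan2(R[1, 3], -R[2, 3])
    psi <- atan2(R[3, 1], R[3, 2])
  }
  c(phi = phi * r2d, theta = theta * r2d, psi = psi * r2d)
}

#' Geodesic angle between two rotations
#'
#' @param R1,R2 3 x 3 rotation matrices.
#' @return angle in degrees in \[0, 180\].
#' @export
rotation_distance <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

# uniformly random rotation matrix via a random unit quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# von Mises sampler (Best & Fisher 1979 rejection method), mean mu and
# concentration kappa, radians; kappa = 0 falls back to uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(max(-1, min(1, f)))
        break
      }
    }
  }
  out
}

# an arbitrary unit vector perpendicular to v
perpendicular_unit <- function(v) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- ref - sum(ref * v) * v
  p / sqrt(sum(p^2))
}

# rotate vector v by angle (radians) about unit axis k (Rodrigues)
rotate_about_axis <- function(v, k, angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  v * c_ + c(k[2] * v[3] - k[3] * v[2],
             k[3] * v[1] - k[1] * v[3],
             k[1] * v[2] - k[2] * v[1]) * s_ + k * sum(k * v) * (1 - c_)
}
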