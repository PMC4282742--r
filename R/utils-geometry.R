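# Small 3D geometry helpers shared across modules. All vectors are plain
# numeric length-3, rotation matrices are 3x3 with columns = axes.

DEG <- 180 / pi

deg2rad <- function(x) x / DEG
rad2deg <- function(x) x * DEG

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (!is.finite(n) || n < .Machine$double.eps) {
    stop("cannot normalize a zero-length vector", call. = FALSE)
  }
  v / n
}

vcross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Elementary rotations about lab axes, angle in degrees.
rot_x <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

rot_z <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Random rotation uniform on SO(3) (quaternion method).
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

clamp1 <- function(x) pmin(1, pmax(-1, x))
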