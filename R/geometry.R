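# Exact geometric primitives shared by detection, restraints and validation.

#' Euclidean distance between two points
#'
#' @param a,b Numeric length-3 coordinate vectors (angstrom).
#' @return Distance in angstrom.
#' @export
#' @examples
#' coord_distance(c(0, 0, 0), c(0, 0, 2.34))
coord_distance <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' Angle at a vertex
#'
#' Angle a-vertex-c in degrees, in [0, 180].
#'
#' @param a,vertex,c Numeric length-3 coordinate vectors (angstrom).
#' @return Angle in degrees.
#' @export
#' @examples
#' coord_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
coord_angle <- function(a, vertex, c) {
  u <- a - vertex
  v <- c - vertex
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("zero-length arm: a and c must differ from the vertex")
  }
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# Unit vector; errors on zero input.
unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise zero vector")
  v / n
}

# A deterministic unit vector perpendicular to u.
perp_vec <- function(u) {
  u <- unit_vec(u)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit_vec(cross3(u, ref))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix for angle theta (radians) about unit axis k (Rodrigues).
rotation_matrix <- function(axis, theta) {
  k <- unit_vec(axis)
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Random rigid motion (rotation + translation) from a seeded RNG stream;
# used by invariance tests and exported because it is handy for users
# checking their own pipelines.

#' Apply a rigid-body transformation to a structure
#'
#' Rotates all atomic coordinates by `rotation` and then translates by
#' `translation`.  Annotation records are untouched.  Useful for checking
#' that detection and validation are frame-independent.
#'
#' @param structure A [read_structure()] object.
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric length-3 vector (angstrom).
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(structure, "zn_structure"))
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  structure$atoms$x <- xyz[, 1] + translation[1]
  structure$atoms$y <- xyz[, 2] + translation[2]
  structure$atoms$z <- xyz[, 3] + translation[3]
  structure
}

# Seeded random rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
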