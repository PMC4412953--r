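# Small geometry helpers shared by the SASA, pocket, secondary-structure and
# construct-builder code. All coordinates are plain n x 3 matrices in Angstrom.

#' Evenly distributed points on the unit sphere
#'
#' Deterministic golden-section (Fibonacci) lattice used by the Shrake-Rupley
#' sampler.
#'
#' @param n Number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacciSphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  polar <- acos(1 - 2 * i / n)
  azim <- pi * (1 + sqrt(5)) * i
  cbind(sin(polar) * cos(azim), sin(polar) * sin(azim), cos(polar))
}

#' Rotation matrix about an axis
#'
#' @param axis Length-3 axis vector (need not be unit).
#' @param angle Rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotationMatrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c0 * diag(3) + s0 * ux + (1 - c0) * tcrossprod(u)
}

#' Uniform random rotation matrix
#'
#' @param seed Optional integer seed (local RNG state).
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
randomRotation <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  qr0 <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr0)
  d <- diag(qr.R(qr0))
  q <- q %*% diag(sign(d + (d == 0)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# Dihedral angle (degrees, in (-180, 180]) defined by four points.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Place a new atom D given reference atoms A-B-C, the bond length C-D, the
# angle B-C-D (deg) and the dihedral A-B-C-D (deg). Natural-extension
# reference frame construction.
.placeAtom <- function(a, b, c0, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- -dihedral * pi / 180  # sign matches the .dihedral convention
  bc <- c0 - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c0 + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Canonical orientation of a coordinate set: principal axes of the centred
# coordinates with signs fixed by third moments (falling back to the largest
# absolute projection when a third moment vanishes), right-handedness
# enforced. Rotating or translating the input leaves the returned coordinates
# unchanged, which makes lattice-sampled quantities rigid-motion invariant.
.canonicalCoords <- function(xyz) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  if (n < 2) return(x0)
  cv <- crossprod(x0) / n
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors
  for (k in 1:3) {
    p <- x0 %*% v[, k]
    s3 <- sum(p^3)
    s <- if (abs(s3) > 1e-8) sign(s3) else sign(p[which.max(abs(p))])
    if (s < 0) v[, k] <- -v[, k]
  }
  if (det(v) < 0) v[, 3] <- -v[, 3]
  x0 %*% v
}
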