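# Internal 3D geometry helpers shared by the fixture generator, the
# virtual-center construction and the descriptor code. All coordinates are
# plain numeric length-3 vectors or Lx3 matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
vec_angle <- function(a, b, c) {
  # angle at b (degrees), in [0, 180]
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' @noRd
vec_dihedral <- function(p1, p2, p3, p4) {
  # signed dihedral p1-p2-p3-p4 (degrees), IUPAC sign convention
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place a new atom D given three reference atoms a-b-c so that |D - c| = bond,
# angle(D, c, b) = ang (degrees) and dihedral(a, b, c, D) = tors (degrees).
# Standard internal-coordinate (NeRF) construction.
place_atom <- function(a, b, c, bond, ang, tors) {
  ang <- ang * pi / 180
  tors <- tors * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tors),
         -bond * sin(ang) * sin(tors))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Optimal rotation (Kabsch) superposing x onto y after centering; returns the
# rotation matrix R and translation so that x %*% R + t approximates y.
kabsch <- function(x, y) {
  n <- nrow(x)
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- x - rep(cx, each = n)
  y0 <- y - rep(cy, each = n)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = rot, t = cy - as.vector(cx %*% rot))
}

apply_rigid <- function(coords, rt) {
  coords %*% rt$R + rep(rt$t, each = nrow(coords))
}

# Random rigid transform (rotation from QR of a Gaussian matrix + translation)
random_rigid <- function(max_shift = 20) {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(R = rot, t = stats::runif(3, -max_shift, max_shift))
}
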