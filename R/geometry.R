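# Small geometric utilities shared across modules. All coordinates are
# n x 3 matrices in Angstrom; angles in radians unless stated otherwise.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors in degrees
#' @noRd
vec_angle_deg <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  ca <- max(-1, min(1, ca))
  acos(ca) * 180 / pi
}

# bond (pseudo) angle at bead i formed by beads (i-1, i, i+1)
bead_angle <- function(p0, p1, p2) {
  acos(max(-1, min(1, sum(unit(p0 - p1) * unit(p2 - p1)))))
}

# dihedral defined by four consecutive beads, in (-pi, pi]
bead_dihedral <- function(p0, p1, p2, p3) {
  b1 <- p1 - p0
  b2 <- p2 - p1
  b3 <- p3 - p2
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# rotation matrix about arbitrary unit axis (Rodrigues)
rotation_about_axis <- function(axis, theta) {
  u <- unit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# deterministic sequence of "generic" rotations used to escape degenerate
# projections; k = 0 is the identity
generic_rotation <- function(k) {
  if (k == 0) return(diag(3))
  ax <- (k * 2.399963229728653) %% (2 * pi)   # golden angle steps
  ay <- (k * 1.847759065022574) %% (2 * pi)
  rx <- rotation_about_axis(c(1, 0, 0), ax)
  ry <- rotation_about_axis(c(0, 1, 0), ay)
  ry %*% rx
}

radius_of_gyration <- function(xyz) {
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

# resample an ordered polyline to n points equally spaced in arc length
resample_arclength <- function(xyz, n) {
  seg <- sqrt(rowSums(diff(xyz)^2))
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = n)
  out <- matrix(0, n, 3)
  for (d in 1:3) out[, d] <- stats::approx(s, xyz[, d], xout = target)$y
  out
}
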