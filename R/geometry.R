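# Internal 3D geometry helpers shared by the chain builder, DSSP assignment
# and contact detection. All coordinates are nm; angles are radians unless a
# function name says degrees.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Angle A-B-C at vertex B, radians in [0, pi].
vec_angle <- function(a, b, cc) {
  u <- unitv(a - b)
  v <- unitv(cc - b)
  acos(max(-1, min(1, sum(u * v))))
}

## Signed dihedral A-B-C-D, radians in (-pi, pi], IUPAC sign convention.
dihedral <- function(a, b, cc, d) {
  b1 <- b - a
  b2 <- cc - b
  b3 <- d - cc
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x)
}

## Natural-extension reference frame (NeRF) placement: position atom D given
## positions of A, B, C, the bond length |C-D|, the angle B-C-D and the
## torsion A-B-C-D. The workhorse of internal-coordinate chain growth.
place_atom <- function(a, b, cc, bond, angle, torsion) {
  bc <- unitv(cc - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion), sin(angle) * sin(torsion))
  cc + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Least-squares plane through >=3 points (rows of xyz). Returns unit normal
## and centroid; stops with class "degenerate_plane" if points are collinear.
fit_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2L, ctr)
  sv <- svd(x)
  if (sv$d[2L] < 1e-8) {
    stop(structure(class = c("degenerate_plane", "error", "condition"),
                   list(message = "collinear atoms: no plane defined", call = NULL)))
  }
  list(normal = sv$v[, 3L], center = ctr)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## All pairwise Euclidean distances between rows of a and rows of b.
cdist <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
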