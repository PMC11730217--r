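## Low-level vector geometry shared by the chain builder, the sampler and
## the ensemble statistics.  All coordinates are Cartesian, in Angstrom;
## all angles are degrees unless a function says otherwise.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Map an angle in degrees to the half-open interval (-180, 180].
wrapAngle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y == -180] <- 180
  y
}

#' Dihedral angle of four points
#'
#' Computes the torsion angle defined by four points using the IUPAC sign
#' convention: looking from \code{b} towards \code{c}, a clockwise rotation
#' of the \code{a}-projection onto the \code{d}-projection is positive.
#' A planar cis arrangement gives 0 degrees, trans gives 180.
#'
#' @param a,b,c,d numeric 3-vectors (Angstrom).
#' @return Angle in degrees in the half-open interval (-180, 180].
#' @examples
#' dihedralAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180
#' @export
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined dihedral: three of the four points are collinear")
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrapAngle(rad2deg(atan2(-y, x)))
}

## Natural-extension reference frame (NeRF): place atom D bonded to C,
## given positions A, B, C, the bond length |CD|, the bond angle B-C-D and
## the dihedral A-B-C-D.  Inverse of dihedralAngle (round-trip tested).
nerfPlace <- function(a, b, c, bondLength, bondAngle, dihedral) {
  th <- deg2rad(bondAngle)
  ph <- deg2rad(dihedral)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bondLength * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Rotate the rows of `xyz` by `angle` degrees about the axis through
## `origin` with direction `axis` (Rodrigues rotation).
rotateAboutAxis <- function(xyz, origin, axis, angle) {
  k <- unitv(axis)
  th <- deg2rad(angle)
  ct <- cos(th)
  st <- sin(th)
  p <- sweep(xyz, 2L, origin)
  kdp <- drop(p %*% k)
  kxp <- cbind(k[2L] * p[, 3L] - k[3L] * p[, 2L],
               k[3L] * p[, 1L] - k[1L] * p[, 3L],
               k[1L] * p[, 2L] - k[2L] * p[, 1L])
  out <- p * ct + kxp * st + outer(kdp * (1 - ct), k)
  sweep(out, 2L, origin, `+`)
}

## Best-fit plane through points (rows of xyz): returns unit normal and the
## RMS out-of-plane residual.
fitPlane <- function(xyz) {
  ctr <- colMeans(xyz)
  p <- sweep(xyz, 2L, ctr)
  sv <- svd(p)
  normal <- sv$v[, 3L]
  residual <- sqrt(mean((p %*% normal)^2))
  list(center = ctr, normal = normal, residual = residual)
}
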