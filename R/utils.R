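# Small geometry helpers shared across modules.

vnorm <- function(x) sqrt(sum(x * x))

unit <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles into (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the principal interval (-180, 180].
#' @export
wrap_deg <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Dihedral angle of four points
#'
#' Signed dihedral (torsion) angle defined by four points, in degrees,
#' using the IUPAC sign convention (right-handed twist positive).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unit(b2))
  atan2(y, x) * 180 / pi
}

#' Consecutive C-alpha pseudo-dihedrals of a chain
#'
#' @param ca L x 3 matrix of C-alpha coordinates.
#' @return numeric vector of length L - 3 with the pseudo-dihedral (deg) of
#'   each consecutive C-alpha quadruple (i, i+1, i+2, i+3).
#' @export
pseudo_dihedrals <- function(ca) {
  L <- nrow(ca)
  if (L < 4) return(numeric(0))
  vapply(seq_len(L - 3), function(i) {
    dihedral_angle(ca[i, ], ca[i + 1, ], ca[i + 2, ], ca[i + 3, ])
  }, numeric(1))
}

# Rotation matrix about unit axis by angle (radians), Rodrigues form.
rotation_about <- function(axis, theta) {
  u <- unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Uniform random proper rotation (consumes RNG).
random_rotation <- function() {
  # quaternion from 4 normals, normalized
  q <- rnorm(4)
  q <- q / vnorm(q)
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc + a * d), 2 * (b * d - a * cc),
           2 * (b * cc - a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d + a * b),
           2 * (b * d + a * cc), 2 * (cc * d - a * b), a^2 - b^2 - cc^2 + d^2),
         3, 3)
}

# Circular-arc interpolation: n_seg equal chords of length `bond` joining P
# to Q, bulging toward `normal`.  Returns the n_seg - 1 interior points.
# Requires n_seg * bond > |Q - P|.
arc_points <- function(P, Q, n_seg, normal, bond = 3.8) {
  d <- vnorm(Q - P)
  if (n_seg * bond <= d) {
    stop("arc_points: ", n_seg, " chords of ", bond, " cannot span ", round(d, 2))
  }
  if (n_seg == 1) return(matrix(numeric(0), 0, 3))
  ex <- unit(Q - P)
  ny <- normal - sum(normal * ex) * ex
  if (vnorm(ny) < 1e-8) stop("arc_points: normal parallel to chord")
  ey <- unit(ny)
  # solve for total central angle Phi: sin(Phi/2) / sin(Phi/(2 n)) = d / bond
  ratio <- d / bond
  f <- function(phi) sin(phi / 2) - ratio * sin(phi / (2 * n_seg))
  phi <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-6), tol = 1e-12)$root
  R <- bond / (2 * sin(phi / (2 * n_seg)))
  M <- (P + Q) / 2
  C <- M - ey * (R * cos(phi / 2))
  # angular positions of P and Q around C in the (ex, ey) frame
  phi_p <- atan2(R * cos(phi / 2), -d / 2)
  pts <- matrix(0, n_seg - 1, 3)
  for (k in seq_len(n_seg - 1)) {
    a <- phi_p - k * phi / n_seg
    pts[k, ] <- C + R * (cos(a) * ex + sin(a) * ey)
  }
  pts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
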