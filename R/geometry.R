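# Geometry primitives: minimum-image distances, torsions, rigid motions,
# internal-coordinate atom placement. Coordinates are Angstrom throughout.

#' Minimum-image displacement in a cubic box
#'
#' @param d displacement vector/matrix (rows = vectors)
#' @param box_edge cubic box edge (Angstrom); `NULL` or `Inf` disables PBC
#' @return wrapped displacement of the same shape
#' @export
min_image <- function(d, box_edge = NULL) {
  if (is.null(box_edge) || !is.finite(box_edge)) return(d)
  d - box_edge * round(d / box_edge)
}

#' Minimum-image Euclidean distance between two points
#' @param p1,p2 numeric length-3 coordinates (Angstrom)
#' @param box_edge cubic box edge, `NULL` for no periodic wrapping
#' @return distance in Angstrom
#' @export
mi_dist <- function(p1, p2, box_edge = NULL) {
  d <- min_image(p2 - p1, box_edge)
  sqrt(sum(d * d))
}

# All pairwise minimum-image distances between two coordinate matrices.
mi_dist_matrix <- function(a, b, box_edge = NULL) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box_edge) && is.finite(box_edge)) {
    dx <- min_image(dx, box_edge)
    dy <- min_image(dy, box_edge)
    dz <- min_image(dz, box_edge)
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed torsion angle of four points
#'
#' IUPAC convention: cis = 0, trans = 180; result in (-180, 180] degrees.
#' Degenerate (collinear) geometry yields `NA` with attribute
#' `reason = "degenerate"`, never a silent number.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstrom)
#' @return angle in degrees, or `NA` for degenerate geometry
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2 * b2))
  if (nb2 < 1e-9 || sum(n1 * n1) < 1e-12 || sum(n2 * n2) < 1e-12) {
    return(structure(NA_real_, reason = "degenerate"))
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * (b2 / nb2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360   # map -180 -> 180: convention (-180, 180]
  ang
}

# Place an atom from internal coordinates (NeRF): given positions a-b-c,
# return d with |c-d| = bond, angle(b,c,d) = angle_deg, torsion(a,b,c,d) =
# torsion_deg.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n * n))
  if (nn < 1e-10) stop("place_atom: collinear reference atoms")
  n <- n / nn
  m <- cbind(bc, cross3(n, bc), n)
  c(m %*% d2) + c
}

# Random 3x3 rotation matrix (uniform over SO(3)) from three uniforms.
random_rotation <- function(u = runif(3)) {
  theta <- 2 * pi * u[1]; phi <- 2 * pi * u[2]; z <- u[3]
  v <- c(cos(phi) * sqrt(z), sin(phi) * sqrt(z), sqrt(1 - z))
  r <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)
  (2 * tcrossprod(v) - diag(3)) %*% r
}
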