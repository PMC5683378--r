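#' Build a labeled coordinate set
#'
#' A coordinate set is the package's flat container for labeled 3-D points:
#' a data frame with columns `elety` (atom name), `resi` (residue index
#' within the set), and `x`, `y`, `z` in Angstrom. It is the currency passed
#' between backbone extraction, superposition, grafting, density simulation
#' and the validation metrics.
#'
#' @param elety character vector of atom names (e.g. `"N"`, `"CA"`, `"C"`, `"O"`).
#' @param resi integer vector of residue indices, same length as `elety`.
#' @param xyz numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @return A `coord_set` data frame.
#' @export
coord_set <- function(elety, resi, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stopf("xyz must have 3 columns")
  if (nrow(xyz) != length(elety) || length(elety) != length(resi)) {
    stopf("elety, resi and xyz rows must have equal length")
  }
  if (nrow(xyz) == 0L) stopf("coordinate set must contain at least one point")
  if (!all(is.finite(xyz))) stopf("coordinates must be finite")
  out <- data.frame(
    elety = as.character(elety),
    resi = as.integer(resi),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  class(out) <- c("coord_set", "data.frame")
  out
}

#' Extract the coordinate matrix of a coordinate set
#' @param cs a `coord_set` (or any data frame with x/y/z columns).
#' @return numeric matrix, one row per atom.
#' @export
cs_xyz <- function(cs) {
  cbind(x = cs$x, y = cs$y, z = cs$z)
}

# Replace the coordinates of a coord_set, keeping labels.
cs_set_xyz <- function(cs, xyz) {
  cs$x <- xyz[, 1]; cs$y <- xyz[, 2]; cs$z <- xyz[, 3]
  cs
}

#' Rigid-body transform
#'
#' A proper rotation (3x3, det +1) plus translation, applied as
#' `x %*% t(R) + t`.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (Angstrom).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(R, t) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L))) stopf("R must be 3x3")
  if (abs(det(R) - 1) > 1e-6) stopf("R must be a proper rotation (det +1)")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf a `rigid_transform`.
#' @param xyz coordinate matrix (n x 3) or `coord_set`.
#' @return object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(tf, xyz) {
  if (inherits(xyz, "coord_set") || is.data.frame(xyz)) {
    return(cs_set_xyz(xyz, apply_transform(tf, cs_xyz(xyz))))
  }
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(tf$R), 2L, -tf$t)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$R)
  rigid_transform(Rt, -as.numeric(Rt %*% tf$t))
}

# Random rotation matrix (uniform via QR of Gaussian), used by fixtures/tests.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

vnorm <- function(v) sqrt(sum(v * v))

vangle_deg <- function(a, b) {
  na <- vnorm(a); nb <- vnorm(b)
  if (na == 0 || nb == 0) stopf("zero-length vector in angle computation")
  cosang <- sum(a * b) / (na * nb)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Dihedral angle of four points, degrees in (-180, 180].
torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  ang <- atan2(sum(cross3(n1, n2) * b2 / vnorm(b2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}
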