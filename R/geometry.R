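# Cartesian geometry: distances, dihedrals and their gradients, internal
# coordinate placement and least-squares superposition.

as_coord_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  storage.mode(p) <- "double"
  p
}

#' Euclidean distance between atoms
#'
#' @param a,b Coordinates: length-3 vectors or n x 3 matrices (rows are
#'   paired).
#' @return Distance(s) in the input units (Angstrom throughout the package).
#' @export
measure_distance <- function(a, b) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  stopifnot_finite(a, "a"); stopifnot_finite(b, "b")
  sqrt(rowSums((a - b)^2))
}

row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

#' Signed dihedral angle
#'
#' Standard IUPAC signed torsion defined by four points: the angle between
#' the plane through (p1, p2, p3) and the plane through (p2, p3, p4), viewed
#' along the p2-p3 axis. Reversing the atom order negates the value; the
#' result is invariant under rigid motion.
#'
#' @param p1,p2,p3,p4 Coordinates: length-3 vectors or n x 3 matrices.
#' @return Angle(s) in degrees, in `(-180, 180]`.
#' @export
measure_torsion <- function(p1, p2, p3, p4) {
  p1 <- as_coord_matrix(p1); p2 <- as_coord_matrix(p2)
  p3 <- as_coord_matrix(p3); p4 <- as_coord_matrix(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  if (any(rowSums(n1^2) < 1e-16) || any(rowSums(n2^2) < 1e-16)) {
    abort("degenerate dihedral: three consecutive atoms are collinear")
  }
  b2n <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(row_cross(n1, n2) * b2n)
  wrap_angle(rad2deg(atan2(y, x)))
}

# Cartesian gradient of the dihedral angle (radians per Angstrom) with
# respect to each of the four points. Returns a list of four n x 3 matrices.
torsion_gradient <- function(p1, p2, p3, p4) {
  p1 <- as_coord_matrix(p1); p2 <- as_coord_matrix(p2)
  p3 <- as_coord_matrix(p3); p4 <- as_coord_matrix(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
  b2len <- sqrt(rowSums(b2^2))
  g1 <- -n1 * (b2len / n1sq)
  g4 <- n2 * (b2len / n2sq)
  p <- rowSums(b1 * b2) / b2len^2
  q <- rowSums(b3 * b2) / b2len^2
  g2 <- -g1 * (1 + p) + g4 * q
  g3 <- g1 * p - g4 * (1 + q)
  list(g1, g2, g3, g4)
}

# Place a new atom D given three reference atoms A-B-C, the bond length
# C-D, the angle B-C-D (degrees) and the dihedral A-B-C-D (degrees).
# Standard internal-coordinate (NeRF) construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle); ph <- deg2rad(dihedral)
  d_local <- c(
    -bond * cos(th),
    bond * sin(th) * cos(ph),
    bond * sin(th) * sin(ph)
  )
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- cbind(bc, c(n[2] * bc[3] - n[3] * bc[2],
                   n[3] * bc[1] - n[1] * bc[3],
                   n[1] * bc[2] - n[2] * bc[1]), n)
  as.numeric(m %*% d_local + c)
}

# Least-squares (Kabsch) superposition of src onto dst (both n x 3).
# Returns rotation R, translation t (mapping x -> x %*% R + t), the
# transformed source and per-row residuals.
kabsch <- function(src, dst) {
  src <- as_coord_matrix(src); dst <- as_coord_matrix(dst)
  cs <- colMeans(src); cd <- colMeans(dst)
  s0 <- sweep(src, 2, cs); d0 <- sweep(dst, 2, cd)
  h <- crossprod(s0, d0)
  sv <- svd(h)
  sgn <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$u %*% diag(c(1, 1, sgn)) %*% t(sv$v)
  t <- cd - as.numeric(cs %*% r)
  fitted <- sweep(src %*% r, 2, t, "+")
  list(rotation = r, translation = t, fitted = fitted,
       residuals = sqrt(rowSums((fitted - dst)^2)))
}

#' RMSD between two structures
#'
#' Root-mean-square deviation over the atoms common to both structures
#' (matched by chain, residue number, insertion code and atom name), after
#' optimal least-squares superposition by default.
#'
#' @param model,reference Structure tables (see [read_structure()]).
#' @param superpose Superpose `model` onto `reference` first (default TRUE).
#' @return RMSD in Angstrom (length-1 numeric).
#' @export
rmsd_structures <- function(model, reference, superpose = TRUE) {
  common <- inner_join(
    model, reference,
    by = c("chain", "resno", "icode", "atom"), suffix = c("", ".ref")
  )
  if (nrow(common) == 0) abort("no common atoms between the two structures")
  p <- as.matrix(common[, c("x", "y", "z")])
  q <- as.matrix(common[, c("x.ref", "y.ref", "z.ref")])
  if (superpose) p <- kabsch(p, q)$fitted
  sqrt(mean(rowSums((p - q)^2)))
}
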