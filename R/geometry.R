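# Vector geometry shared by the torsion energy terms and the analysis suite.

#' Signed dihedral angle of four points
#'
#' Standard signed dihedral between the planes (p1, p2, p3) and
#' (p2, p3, p4), in degrees in (-180, 180]. For a peptide omega angle the
#' points are CA(i-1), C(i-1), N(i), CA(i): 180 deg is trans
#' (antiperiplanar), 0 deg is cis (synperiplanar).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
omega_angle <- function(p1, p2, p3, p4) {
  dihedral_angle(p1, p2, p3, p4)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1 * n1) < 1e-24 || sum(n2 * n2) < 1e-24) {
    stop("undefined dihedral: collinear points")
  }
  b2n <- b2 / sqrt(sum(b2 * b2))
  ang <- atan2(sum(cross3(n1, n2) * b2n), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Flag cis frames of an omega-angle series
#'
#' Classifies each frame as cis when the absolute omega angle is below the
#' symmetric separatrix of 90 degrees. Cis frames are typically excluded
#' from folded-fraction and transition statistics because cis-proline can
#' trap the chain in a non-native state.
#'
#' @param omega_series Angles in degrees in (-180, 180].
#' @param threshold Cis/trans separatrix in degrees (default 90).
#' @return Logical vector, `TRUE` for cis frames.
#' @export
cis_mask <- function(omega_series, threshold = 90) {
  abs(omega_series) < threshold
}

#' Backbone RMSD after optimal or fixed superposition
#'
#' Superposes the mobile frame onto the reference by least squares (Kabsch)
#' over `fit_sel`, then computes the RMSD over `rmsd_sel` without refitting.
#' With the defaults the two selections coincide (ordinary backbone RMSD,
#' e.g. over a trimmed residue range). For a ligand-in-receptor measurement,
#' pass the receptor atoms as `fit_sel` and the ligand atoms as `rmsd_sel`:
#' the alignment is then carried by the receptor and the ligand RMSD retains
#' its displacement within the binding site.
#'
#' @param coords,ref_coords Numeric matrices, one row per atom (x, y, z),
#'   equal dimensions.
#' @param fit_sel Row indices used for the superposition (default all).
#' @param rmsd_sel Row indices the RMSD is computed over (default `fit_sel`).
#' @return RMSD in the coordinate units (nm by convention).
#' @export
backbone_rmsd <- function(coords, ref_coords, fit_sel = NULL, rmsd_sel = NULL) {
  coords <- as.matrix(coords); ref_coords <- as.matrix(ref_coords)
  if (!all(dim(coords) == dim(ref_coords))) stop("selection mismatch")
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(coords))
  if (is.null(rmsd_sel)) rmsd_sel <- fit_sel
  if (max(c(fit_sel, rmsd_sel)) > nrow(coords)) stop("selection mismatch")

  x <- coords[fit_sel, , drop = FALSE]
  y <- ref_coords[fit_sel, , drop = FALSE]
  xc <- colMeans(x); yc <- colMeans(y)
  h <- t(sweep(x, 2, xc)) %*% sweep(y, 2, yc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(sweep(coords, 2, xc) %*% t(rot), 2, yc, `+`)
  diff <- moved[rmsd_sel, , drop = FALSE] - ref_coords[rmsd_sel, , drop = FALSE]
  sqrt(mean(rowSums(diff * diff)))
}
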